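#' Candidate reference genes by expression level and coefficient of variation
#'
#' Among genes whose mean log2 intensity meets \code{min_mean_log2}, returns
#' the \code{top_k} with the smallest coefficient of variation. By default the
#' CV is computed on the log2 scale (sd / mean of the log2 values across all
#' samples); \code{scale = "linear"} computes it on the untransformed
#' \code{2^y} values instead. Ties break deterministically by gene id.
#'
#' @param expr genes x samples log2 matrix
#' @param min_mean_log2 expression floor on the mean log2 intensity (default 10)
#' @param top_k number of candidates to return (default 20)
#' @param scale \code{"log2"} (default) or \code{"linear"}
#' @return character vector of candidate gene ids (may be shorter than
#'   \code{top_k}, with a warning, if few genes qualify)
#' @export
candidate_genes <- function(expr, min_mean_log2 = 10, top_k = 20,
                            scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  stopifnot(nrow(expr) > 0)
  means_log2 <- rowMeans(expr)
  qualifying <- means_log2 >= min_mean_log2
  x <- if (scale == "log2") expr else 2^expr
  mu <- rowMeans(x)
  cv <- apply(x, 1, stats::sd) / mu
  cand <- data.frame(gene = rownames(expr), cv = cv)[qualifying, ]
  if (nrow(cand) < top_k) {
    warning("only ", nrow(cand), " gene(s) meet the expression floor; ",
            "returning all of them")
  }
  cand <- cand[order(cand$cv, cand$gene), ]
  utils::head(cand$gene, top_k)
}

#' Stability scores for candidate reference genes
#'
#' Scores each candidate by how little it deviates from the candidate-panel
#' consensus, penalizing both systematic between-group bias and within-group
#' scatter. Each sample's candidate values are first centered by that sample's
#' mean across candidates (removing sample-level loading differences); per
#' gene, \code{delta} is the between-group difference of centered means,
#' \code{v_intra} the pooled within-group variance of centered values, and
#' \deqn{stability = |\delta| + \sqrt{v_{intra}}}
#' Lower is more stable; rank 1 is the best single reference gene.
#'
#' @param expr log2 matrix restricted to the candidate genes (>= 2 rows)
#' @param design a [study_design()]; grouping is by physiologic state
#' @return data.frame sorted by rank with columns \code{gene},
#'   \code{mean_log2}, \code{cv}, \code{delta}, \code{v_intra},
#'   \code{stability}, \code{rank}
#' @export
stability_scores <- function(expr, design) {
  if (nrow(expr) < 2) {
    stop("stability_single_candidate: need >= 2 candidates for centering",
         call. = FALSE)
  }
  expr <- expr[, design$sample, drop = FALSE]
  centered <- sweep(expr, 2, colMeans(expr))
  states <- design_states(design)
  in_a <- design$state == states[1]
  in_b <- design$state == states[2]
  mean_a <- rowMeans(centered[, in_a, drop = FALSE])
  mean_b <- rowMeans(centered[, in_b, drop = FALSE])
  delta <- mean_b - mean_a
  ss_a <- rowSums((centered[, in_a, drop = FALSE] - mean_a)^2)
  ss_b <- rowSums((centered[, in_b, drop = FALSE] - mean_b)^2)
  v_intra <- (ss_a + ss_b) / (sum(in_a) + sum(in_b) - 2)
  stability <- abs(delta) + sqrt(v_intra)
  out <- data.frame(gene = rownames(expr),
                    mean_log2 = rowMeans(expr),
                    cv = apply(expr, 1, stats::sd) / rowMeans(expr),
                    delta = delta, v_intra = v_intra, stability = stability,
                    stringsAsFactors = FALSE)
  out <- out[order(out$stability, out$gene), ]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Best pair of reference genes
#'
#' Over all pairs of candidates, finds the pair whose average profile has the
#' smallest stability score when scored alongside the other candidates.
#'
#' @inheritParams stability_scores
#' @return list with \code{pair} (two gene ids) and \code{stability}
#' @export
best_pair <- function(expr, design) {
  genes <- rownames(expr)
  if (length(genes) < 2) stop("stability_single_candidate", call. = FALSE)
  pairs <- utils::combn(genes, 2)
  best <- NULL
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    avg <- (expr[g1, , drop = FALSE] + expr[g2, , drop = FALSE]) / 2
    rownames(avg) <- ".pair"
    scored <- stability_scores(rbind(avg, expr[setdiff(genes, c(g1, g2)), ,
                                               drop = FALSE]), design)
    s <- scored$stability[scored$gene == ".pair"]
    if (is.null(best) || s < best$stability) {
      best <- list(pair = c(g1, g2), stability = s)
    }
  }
  best
}

#' Per-sample geometric-mean normalization constant
#'
#' For each sample, the geometric mean of the chosen reference genes'
#' untransformed intensities — equivalently \code{2^} the arithmetic mean of
#' their log2 values.
#'
#' @param expr genes x samples log2 matrix
#' @param chosen character vector of reference gene ids (all present in
#'   \code{expr})
#' @return named positive numeric vector over samples
#' @export
normalization_constant <- function(expr, chosen) {
  absent <- setdiff(chosen, rownames(expr))
  if (length(absent) > 0) {
    stop("normalization_gene_absent: ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  if (length(chosen) == 0) stop("normalization_empty", call. = FALSE)
  2^colMeans(expr[chosen, , drop = FALSE])
}
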