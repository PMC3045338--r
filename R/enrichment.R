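#' Right-tailed Fisher's exact test
#'
#' Hypergeometric upper-tail probability of drawing at least \code{k} members
#' of a \code{K}-gene set in a list of \code{n} genes sampled without
#' replacement from a background of \code{N}:
#' \deqn{p = \sum_{x=k}^{\min(K,n)} \frac{{K \choose x}{N-K \choose n-x}}{{N \choose n}}}
#'
#' @param k set members in the list (may be a vector)
#' @param K set members in the background
#' @param n list size
#' @param N background size
#' @return upper-tail probability in (0, 1], vectorized over \code{k}
#' @export
fisher_right <- function(k, K, n, N) {
  if (K > N || n > N || any(k > min(K, n)) || any(k < 0) || n < 0 || K < 0) {
    stop("fisher_bad_margins: require 0 <= k <= min(K, n), K <= N, n <= N",
         call. = FALSE)
  }
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Overrepresentation of a gene-set collection in a DE list
#'
#' Each set is intersected with the background (typically the tested-gene
#' universe; a whole-chip universe is equally valid — pass it as
#' \code{background}) and tested for overrepresentation in the
#' differentially-expressed list by the right-tailed Fisher's exact test.
#' Sets with no background member are skipped with a warning.
#'
#' @param sets named list of gene vectors (see [read_gmt()])
#' @param de_genes character vector, must be a subset of \code{background}
#' @param background character vector, the gene universe
#' @param q_mode passed to [q_values()] (default \code{"as_stated"})
#' @return data.frame sorted by ascending p (ties by set name) with columns
#'   \code{set}, \code{k}, \code{K}, \code{n}, \code{N}, \code{p}, \code{q}
#' @export
enrich_collection <- function(sets, de_genes, background,
                              q_mode = c("as_stated", "step_up")) {
  q_mode <- match.arg(q_mode)
  if (length(background) == 0) {
    stop("enrich_empty_background", call. = FALSE)
  }
  background <- unique(background)
  stray <- setdiff(de_genes, background)
  if (length(stray) > 0) {
    stop("enrich_de_not_in_background: ",
         paste(utils::head(stray, 5), collapse = ", "), call. = FALSE)
  }
  de_genes <- unique(de_genes)
  N <- length(background); n <- length(de_genes)
  rows <- lapply(names(sets), function(nm) {
    members <- intersect(sets[[nm]], background)
    if (length(members) == 0) {
      warning("set ", nm, " has no member in the background; skipped")
      return(NULL)
    }
    K <- length(members)
    k <- length(intersect(members, de_genes))
    data.frame(set = nm, k = k, K = K, n = n, N = N,
               p = fisher_right(k, K, n, N), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    return(data.frame(set = character(), k = integer(), K = integer(),
                      n = integer(), N = integer(), p = numeric(),
                      q = numeric()))
  }
  out$q <- q_values(out$p, mode = q_mode)
  out <- out[order(out$p, out$set), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Test a curated gene panel within one tissue
#'
#' A panel member counts as a positive test when its within-tissue
#' simple-effect p is below the panel cutoff — by the within-tissue p alone,
#' not the dual-threshold call. The panel is first resolved against the
#' background (the tested-gene universe); unresolved members are dropped with
#' a message. The resulting 2x2 margins (panel membership x positive test)
#' feed the right-tailed Fisher's exact test.
#'
#' @param panel character vector of panel gene ids
#' @param results \code{$results} of a [splitplot_fit()]
#' @param tissue one of the fitted tissues
#' @param cutoff positive-test threshold on the within-tissue p (default 0.01)
#' @return one-row data.frame with columns \code{set}, \code{k}, \code{K},
#'   \code{n}, \code{N}, \code{p}
#' @export
panel_test <- function(panel, results, tissue, cutoff = 0.01) {
  pcol <- paste0("p_simple_", tissue)
  if (!pcol %in% names(results)) {
    stop("panel_unknown_tissue: ", tissue, call. = FALSE)
  }
  background <- results$gene
  resolved <- intersect(panel, background)
  dropped <- length(setdiff(panel, background))
  if (dropped > 0) {
    message(dropped, " panel member(s) not in the tested-gene background; dropped")
  }
  if (length(resolved) == 0) {
    stop("panel_unresolved: no panel member in the background", call. = FALSE)
  }
  positive <- results$gene[results[[pcol]] < cutoff]
  k <- length(intersect(resolved, positive))
  data.frame(set = "panel", tissue = tissue, k = k, K = length(resolved),
             n = length(positive), N = length(background),
             p = fisher_right(k, length(resolved), length(positive),
                              length(background)),
             stringsAsFactors = FALSE)
}
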