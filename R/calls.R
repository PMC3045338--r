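#' Dual-threshold differential-expression calls
#'
#' A gene is called differentially expressed within a tissue when the overall
#' physiologic-state effect is significant (\code{p_state < alpha_state}) AND
#' the simple effect within that tissue passes \code{p_simple < alpha_simple}.
#' Both inequalities are strict. A weaker per-tissue "tendency" flag at
#' \code{alpha_tendency} is also recorded; it is used only by pattern coding,
#' where it protects against splitting a uniformly-responding gene across
#' patterns because one tissue narrowly missed the stringent cutoff.
#'
#' @param results the \code{$results} data.frame of a [splitplot_fit()]
#' @param alpha_state overall state-effect threshold (default 0.05)
#' @param alpha_simple within-tissue threshold (default 0.01)
#' @param alpha_tendency tendency threshold for pattern coding (default 0.05)
#' @return data.frame with columns \code{gene}, \code{de_<tissue>},
#'   \code{tendency_<tissue>}, \code{any_de}
#' @export
call_de <- function(results, alpha_state = 0.05, alpha_simple = 0.01,
                    alpha_tendency = 0.05) {
  tissues <- sub("^p_simple_", "",
                 grep("^p_simple_", names(results), value = TRUE))
  out <- data.frame(gene = results$gene, stringsAsFactors = FALSE)
  state_ok <- results$p_state < alpha_state
  any_de <- rep(FALSE, nrow(results))
  for (t in tissues) {
    p <- results[[paste0("p_simple_", t)]]
    out[[paste0("de_", t)]] <- state_ok & (p < alpha_simple)
    out[[paste0("tendency_", t)]] <- p < alpha_tendency
    any_de <- any_de | out[[paste0("de_", t)]]
  }
  out$any_de <- any_de
  out
}

#' Proportion of false positives
#'
#' Estimates the fraction of false rejections among the genes declared
#' significant at a given p-value cutoff:
#' \deqn{PFP = \frac{\alpha \times n_{tested}}{n_{detected}}}
#' i.e. the number of rejections expected by chance alone divided by the
#' number actually observed.
#'
#' @param alpha p-value cutoff used for detection
#' @param n_tested number of genes tested
#' @param n_detected number of genes with p below the cutoff (must be >= 1)
#' @return list with \code{alpha}, \code{n_tested}, \code{n_detected},
#'   \code{pfp} (full precision) and \code{pfp_2dp} (rounded to 2 decimals,
#'   the reporting convention)
#' @examples
#' pfp(0.05, 14129, 1924)$pfp_2dp  # 0.37
#' @export
pfp <- function(alpha, n_tested, n_detected) {
  stopifnot(alpha > 0, alpha < 1, n_tested >= 1)
  if (n_detected < 1) {
    stop("pfp_undefined: no genes detected below the cutoff", call. = FALSE)
  }
  value <- alpha * n_tested / n_detected
  list(alpha = alpha, n_tested = n_tested, n_detected = n_detected,
       pfp = value, pfp_2dp = round(value, 2))
}

#' PFP summary over the standard scopes
#'
#' One row for the overall state effect at each requested alpha, and one row
#' per tissue for the simple effect at \code{alpha_simple}. Per-tissue rows
#' count genes by the within-tissue p alone (not the dual-threshold call),
#' since the dual-threshold list is a subset of the within-tissue list and the
#' two tests address the same gene.
#'
#' @param results \code{$results} of a [splitplot_fit()]
#' @param alphas_state cutoffs for the overall state rows (default
#'   \code{c(0.05, 0.01)})
#' @param alpha_simple cutoff for per-tissue rows (default 0.01)
#' @return data.frame with columns scope, alpha, n_tested, n_detected, pfp
#' @export
pfp_summary <- function(results, alphas_state = c(0.05, 0.01),
                        alpha_simple = 0.01) {
  tissues <- sub("^p_simple_", "",
                 grep("^p_simple_", names(results), value = TRUE))
  n <- nrow(results)
  rows <- lapply(alphas_state, function(a) {
    k <- sum(results$p_state < a)
    data.frame(scope = "state", alpha = a, n_tested = n, n_detected = k,
               pfp = if (k >= 1) pfp(a, n, k)$pfp else NA_real_)
  })
  rows <- c(rows, lapply(tissues, function(t) {
    k <- sum(results[[paste0("p_simple_", t)]] < alpha_simple)
    data.frame(scope = t, alpha = alpha_simple, n_tested = n, n_detected = k,
               pfp = if (k >= 1) pfp(alpha_simple, n, k)$pfp else NA_real_)
  }))
  do.call(rbind, rows)
}

#' q-values from a vector of p-values
#'
#' The \code{"as_stated"} mode computes, for each p, the expected number of
#' chance positives (\code{p * m}) divided by the number of results with an
#' equal or lower p-value; ties share the rank \code{#\{j: p_j <= p_i\}}. The
#' \code{"step_up"} mode additionally enforces monotonicity by taking the
#' cumulative minimum from the largest p downwards, which is the standard
#' Benjamini-Hochberg adjusted p-value.
#'
#' @param pvals numeric vector of p-values in [0, 1]
#' @param mode \code{"as_stated"} (default) or \code{"step_up"}
#' @return numeric vector of q-values, same order as the input
#' @export
q_values <- function(pvals, mode = c("as_stated", "step_up")) {
  mode <- match.arg(mode)
  if (length(pvals) == 0) stop("q_values_empty", call. = FALSE)
  if (any(pvals < 0 | pvals > 1 | is.na(pvals))) {
    stop("q_values_bad_p: p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(pvals)
  ord <- order(pvals)
  p_sorted <- pvals[ord]
  # rank with ties = count of p <= p_i
  rank_sorted <- findInterval(p_sorted, p_sorted)
  q_sorted <- p_sorted * m / rank_sorted
  if (mode == "step_up") {
    q_sorted <- rev(cummin(rev(pmin(q_sorted, 1))))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}
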