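#' Tissue weights for pattern coding
#'
#' Each tissue carries a power-of-ten weight so that the signed sum over
#' tissues uniquely encodes per-tissue up/down/no-change. For the default
#' four-tissue design the weights are liver = 1000, duodenum = 100,
#' jejunum = 10, ileum = 1; in general the first tissue gets 10^(T-1) and so
#' on down to 1.
#'
#' @param tissues character vector of tissue levels, heaviest first
#' @return named integer vector of weights
#' @export
pattern_weights <- function(tissues) {
  stats::setNames(10^(rev(seq_along(tissues)) - 1), tissues)
}

#' Signed weighted-integer pattern codes
#'
#' For each gene called differentially expressed somewhere, the per-tissue
#' change is summarized as weight x tendency x direction, where tendency is 1
#' when the within-tissue p is below the tendency threshold (else 0) and
#' direction is +1 for an increased fold ratio, -1 for a decrease. The sum
#' over tissues is a signed integer that decodes uniquely back to the
#' per-tissue changes. Genes not differentially expressed in any tissue are
#' assigned code 0.
#'
#' @param calls output of [call_de()]
#' @param results \code{$results} of a [splitplot_fit()] (for fold ratios)
#' @return data.frame with columns \code{gene}, \code{pattern}, and per-tissue
#'   change columns \code{change_<tissue>} in \{-1, 0, +1\}
#' @examples
#' # a gene up in liver only encodes to 1000; down in duodenum only to -100
#' @export
pattern_code <- function(calls, results) {
  tissues <- sub("^tendency_", "",
                 grep("^tendency_", names(calls), value = TRUE))
  w <- pattern_weights(tissues)
  stopifnot(identical(calls$gene, results$gene))
  G <- nrow(calls)
  change <- matrix(0L, G, length(tissues),
                   dimnames = list(NULL, tissues))
  for (t in tissues) {
    m <- as.integer(calls[[paste0("tendency_", t)]])
    r <- results[[paste0("ratio_", t)]]
    s <- ifelse(r > 1, 1L, -1L)
    tie <- m == 1L & r == 1
    if (any(tie)) {
      warning(sum(tie), " gene(s) with fold ratio exactly 1 and a significant",
              " tendency in ", t, "; direction resolved as +1")
      s[tie] <- 1L
    }
    change[, t] <- m * s
  }
  change[!calls$any_de, ] <- 0L
  code <- as.integer(change %*% w)
  out <- data.frame(gene = calls$gene, pattern = code,
                    stringsAsFactors = FALSE)
  for (t in tissues) out[[paste0("change_", t)]] <- change[, t]
  out
}

#' Decode a pattern code back to per-tissue changes
#'
#' Inverse of the signed-base encoding: recovers the per-tissue values in
#' \{-1, 0, +1\} whose weighted sum equals the code.
#'
#' @param code integer pattern code
#' @param tissues tissue levels, heaviest first (default the rat study's four)
#' @return named integer vector over tissues
#' @export
decode_pattern <- function(code,
                           tissues = c("liver", "duodenum", "jejunum", "ileum")) {
  T_ <- length(tissues)
  grid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), T_)))
  codes <- as.integer(grid %*% pattern_weights(tissues))
  hit <- match(code, codes)
  if (is.na(hit)) {
    stop("pattern_unattainable: ", code, " is not a valid pattern code",
         call. = FALSE)
  }
  stats::setNames(grid[hit, ], tissues)
}

#' Group genes by named cross-tissue patterns
#'
#' The named groups are: up/down in all tissues, up/down in all parts of the
#' small intestine only, up/down in liver only, and down in duodenum only.
#' Any other nonzero code is reported under its integer code; code 0 (not
#' differentially expressed anywhere) is omitted.
#'
#' @param codes output of [pattern_code()]
#' @param tissues tissue levels, heaviest first
#' @return named list of gene id vectors
#' @export
assign_pattern_groups <- function(codes,
                                  tissues = c("liver", "duodenum", "jejunum", "ileum")) {
  w <- pattern_weights(tissues)
  all_code <- sum(w)
  si_code <- sum(w[-1])  # all tissues but the first (liver)
  named <- c("up in all tissues" = all_code,
             "down in all tissues" = -all_code,
             "up in all parts of small intestine" = si_code,
             "down in all parts of small intestine" = -si_code,
             "up in liver only" = unname(w[1]),
             "down in liver only" = -unname(w[1]),
             "down in duodenum only" = -unname(w[2]))
  groups <- list()
  for (nm in names(named)) {
    g <- codes$gene[codes$pattern == named[[nm]]]
    if (length(g) > 0) groups[[nm]] <- g
  }
  other <- setdiff(unique(codes$pattern), c(0, named))
  for (code in sort(other)) {
    groups[[as.character(code)]] <- codes$gene[codes$pattern == code]
  }
  groups
}
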