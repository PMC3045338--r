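#' Per-gene split-plot ANOVA over a multi-tissue two-state design
#'
#' Fits, gene by gene, the balanced split-plot (repeated-measures) ANOVA in
#' which physiologic state is the between-subject factor, tissue the
#' within-subject factor, and subjects are RNA pools nested in state. Because
#' every subject contributes one chip per tissue, measurements within a
#' subject share a random subject effect, giving the compound-symmetry
#' covariance structure: equal variances and equal pairwise covariances among
#' a subject's tissues. For this balanced layout the classical sums-of-squares
#' decomposition yields exact F-tests: the state main effect is tested against
#' pool-within-state, while tissue and the tissue x state interaction are
#' tested against the within-subject residual.
#'
#' Per tissue, the state contrast (simple effect) is tested with the combined
#' error mean square \eqn{MS_c = (MS_{pool} + (T-1) MS_{resid}) / T},
#' standard error \eqn{\sqrt{2 MS_c / P}} and Satterthwaite degrees of
#' freedom, because a between-state comparison at a fixed tissue mixes both
#' variance strata. Fold ratios are computed on the untransformed scale:
#' mean of \eqn{2^y} over treated samples divided by the control mean.
#' Method-of-moments variance components are
#' \eqn{\hat\sigma^2_{resid} = MS_{resid}} and
#' \eqn{\hat\sigma^2_{pool} = (MS_{pool} - MS_{resid}) / T}; the pool
#' component may be negative and is reported unmodified unless
#' \code{clamp_var_pool} is set (an unbounded estimate keeps the F-tests
#' exact).
#'
#' @param expr numeric matrix of log2 intensities, genes x samples, with
#'   column names matching \code{design$sample}
#' @param design a [study_design()]
#' @param clamp_var_pool if TRUE, negative pool variance estimates are set
#'   to 0 in the output (default FALSE)
#' @return An object of class \code{splitplot_fit}; see
#'   \code{\link{summary.splitplot_fit}}. Its \code{$results} data.frame has
#'   one row per gene with columns \code{gene}, \code{p_tissue},
#'   \code{p_state}, \code{p_interaction}, \code{p_simple_<tissue>},
#'   \code{ratio_<tissue>}, \code{var_pool}, \code{var_resid},
#'   \code{degenerate}.
#' @examples
#' sim <- simulate_study(simulation_config(seed = 1, n_genes = 50))
#' fit <- splitplot_fit(sim$expression, sim$design)
#' summary(fit)
#' @export
splitplot_fit <- function(expr, design, clamp_var_pool = FALSE) {
  if (is.null(dim(expr))) {
    expr <- matrix(expr, nrow = 1, dimnames = list("gene", names(expr)))
  }
  if (is.null(colnames(expr)) || !setequal(colnames(expr), design$sample)) {
    stop("fit_sample_mismatch: expression columns must match the design samples",
         call. = FALSE)
  }
  expr <- expr[, design$sample, drop = FALSE]

  tissues <- design_tissues(design)
  states <- design_states(design)
  T_ <- length(tissues); S_ <- 2L; P_ <- design_pools(design)
  N <- ncol(expr); G <- nrow(expr)
  stopifnot(N == T_ * S_ * P_)

  avg_mat <- function(f) {
    # N x nlevels averaging matrix
    M <- stats::model.matrix(~ f - 1)
    sweep(M, 2, colSums(M), "/")
  }
  state_f <- design$state
  tissue_f <- design$tissue
  subj_f <- design$subject
  cell_f <- interaction(design$tissue, design$state, lex.order = TRUE)

  m_state <- expr %*% avg_mat(state_f)      # G x S, cols in level order
  m_tissue <- expr %*% avg_mat(tissue_f)    # G x T
  m_subj <- expr %*% avg_mat(subj_f)        # G x (S*P)
  m_cell <- expr %*% avg_mat(cell_f)        # G x (T*S), tissue-major
  grand <- rowMeans(expr)

  subj_state <- match(sub("\\.[0-9]+$", "", levels(subj_f)), states)
  cell_tissue <- rep(seq_len(T_), each = S_)
  cell_state <- rep(seq_len(S_), times = T_)

  ss_state <- T_ * P_ * rowSums((m_state - grand)^2)
  ss_pool <- T_ * rowSums((m_subj - m_state[, subj_state, drop = FALSE])^2)
  ss_tissue <- S_ * P_ * rowSums((m_tissue - grand)^2)
  dev_cell <- m_cell - m_tissue[, cell_tissue, drop = FALSE] -
    m_state[, cell_state, drop = FALSE] + grand
  ss_inter <- P_ * rowSums(dev_cell^2)
  ss_total <- rowSums((expr - grand)^2)
  ss_resid <- pmax(ss_total - ss_state - ss_pool - ss_tissue - ss_inter, 0)

  df <- c(state = S_ - 1L, pool = S_ * (P_ - 1L), tissue = T_ - 1L,
          interaction = (T_ - 1L) * (S_ - 1L),
          residual = S_ * (P_ - 1L) * (T_ - 1L))

  ms_state <- ss_state / df[["state"]]
  ms_pool <- ss_pool / df[["pool"]]
  ms_tissue <- ss_tissue / df[["tissue"]]
  ms_inter <- ss_inter / df[["interaction"]]
  ms_resid <- ss_resid / df[["residual"]]

  f_p <- function(ms_num, ms_den, df1, df2) {
    p <- stats::pf(ms_num / ms_den, df1, df2, lower.tail = FALSE)
    zero_den <- ms_den <= 0
    p[zero_den & ms_num <= 0] <- 1
    p[zero_den & ms_num > 0] <- 0
    p
  }
  p_state <- f_p(ms_state, ms_pool, df[["state"]], df[["pool"]])
  p_tissue <- f_p(ms_tissue, ms_resid, df[["tissue"]], df[["residual"]])
  p_inter <- f_p(ms_inter, ms_resid, df[["interaction"]], df[["residual"]])
  degenerate <- ms_pool <= 0 | ms_resid <= 0

  # Simple effects: treated - control cell-mean difference per tissue,
  # combined error across the two variance strata, Satterthwaite df.
  ms_comb <- (ms_pool + (T_ - 1) * ms_resid) / T_
  se <- sqrt(2 * ms_comb / P_)
  a <- ms_pool; b <- (T_ - 1) * ms_resid
  df_sat <- (a + b)^2 / (a^2 / df[["pool"]] + b^2 / df[["residual"]])
  df_sat[a + b <= 0] <- df[["residual"]]

  p_simple <- matrix(NA_real_, G, T_, dimnames = list(rownames(expr), tissues))
  ratio <- matrix(NA_real_, G, T_, dimnames = list(rownames(expr), tissues))
  lin <- 2^expr
  for (ti in seq_len(T_)) {
    ctrl_col <- (ti - 1L) * S_ + 1L
    trt_col <- (ti - 1L) * S_ + 2L
    diff <- m_cell[, trt_col] - m_cell[, ctrl_col]
    tstat <- diff / se
    p <- 2 * stats::pt(abs(tstat), df_sat, lower.tail = FALSE)
    p[se == 0 & diff == 0] <- 1
    p[se == 0 & diff != 0] <- 0
    p_simple[, ti] <- p
    in_t <- design$tissue == tissues[ti]
    trt <- in_t & design$state == states[2]
    ctl <- in_t & design$state == states[1]
    ratio[, ti] <- rowMeans(lin[, trt, drop = FALSE]) /
      rowMeans(lin[, ctl, drop = FALSE])
  }

  var_pool <- (ms_pool - ms_resid) / T_
  if (clamp_var_pool) var_pool <- pmax(var_pool, 0)

  results <- data.frame(gene = rownames(expr),
                        p_tissue = p_tissue, p_state = p_state,
                        p_interaction = p_inter,
                        stringsAsFactors = FALSE)
  for (ti in seq_len(T_)) results[[paste0("p_simple_", tissues[ti])]] <- p_simple[, ti]
  for (ti in seq_len(T_)) results[[paste0("ratio_", tissues[ti])]] <- ratio[, ti]
  results$var_pool <- var_pool
  results$var_resid <- ms_resid
  results$degenerate <- degenerate
  rownames(results) <- NULL

  ss <- cbind(state = ss_state, pool_within_state = ss_pool,
              tissue = ss_tissue, interaction = ss_inter, residual = ss_resid)
  rownames(ss) <- rownames(expr)

  structure(list(results = results, ss = ss, df = df,
                 cell_means = m_cell, grand = grand,
                 design = design, tissues = tissues, states = states,
                 expr = expr),
            class = "splitplot_fit")
}

#' Balanced split-plot sums-of-squares decomposition for one gene
#'
#' Closed-form decomposition of the corrected total sum of squares into state,
#' pool-within-state, tissue, interaction and residual components. This is the
#' scalar (single-response) path; [splitplot_fit()] is the vectorized
#' equivalent over a whole matrix.
#'
#' @param y named numeric vector over the design's samples (log2 scale)
#' @param design a [study_design()]
#' @return list with components \code{ss} (named numeric of 5 sums of
#'   squares), \code{df} (named integer), \code{ss_total}
#' @export
decompose <- function(y, design) {
  if (is.null(names(y)) || !setequal(names(y), design$sample)) {
    stop("decompose_sample_mismatch: y must be named by the design samples",
         call. = FALSE)
  }
  y <- y[design$sample]
  T_ <- length(design_tissues(design)); S_ <- 2L; P_ <- design_pools(design)
  grand <- mean(y)
  m_state <- tapply(y, design$state, mean)
  m_tissue <- tapply(y, design$tissue, mean)
  m_subj <- tapply(y, design$subject, mean)
  m_cell <- tapply(y, list(design$tissue, design$state), mean)
  subj_state <- sub("\\.[0-9]+$", "", levels(design$subject))

  ss_state <- T_ * P_ * sum((m_state - grand)^2)
  ss_pool <- T_ * sum((m_subj - m_state[subj_state])^2)
  ss_tissue <- S_ * P_ * sum((m_tissue - grand)^2)
  ss_inter <- P_ * sum((m_cell - outer(m_tissue, rep(1, S_)) -
                          outer(rep(1, T_), m_state) + grand)^2)
  ss_total <- sum((y - grand)^2)
  ss_resid <- max(ss_total - ss_state - ss_pool - ss_tissue - ss_inter, 0)

  list(ss = c(state = ss_state, pool_within_state = unname(ss_pool),
              tissue = ss_tissue, interaction = ss_inter,
              residual = ss_resid),
       df = c(state = S_ - 1L, pool_within_state = S_ * (P_ - 1L),
              tissue = T_ - 1L, interaction = (T_ - 1L) * (S_ - 1L),
              residual = S_ * (P_ - 1L) * (T_ - 1L)),
       ss_total = ss_total)
}

#' Split-plot F-tests from a decomposition
#'
#' @param d output of [decompose()]
#' @return named numeric: \code{p_tissue}, \code{p_state},
#'   \code{p_interaction}
#' @export
f_tests <- function(d) {
  ms <- d$ss / d$df
  one <- function(num, den) {
    if (ms[den] <= 0) return(if (ms[num] <= 0) 1 else 0)
    stats::pf(ms[num] / ms[den], d$df[num], d$df[den], lower.tail = FALSE)
  }
  c(p_tissue = unname(one("tissue", "residual")),
    p_state = unname(one("state", "pool_within_state")),
    p_interaction = unname(one("interaction", "residual")))
}

#' Simple effect of state within one tissue (single gene)
#'
#' Two-sided test of the treated-minus-control difference within a tissue
#' using the combined error mean square and Satterthwaite degrees of freedom.
#'
#' @inheritParams decompose
#' @param tissue one of the design's tissue levels
#' @return two-sided p-value
#' @export
simple_effect <- function(y, design, tissue) {
  stopifnot(tissue %in% design_tissues(design))
  y <- y[design$sample]
  d <- decompose(y, design)
  T_ <- length(design_tissues(design)); P_ <- design_pools(design)
  ms_pool <- d$ss[["pool_within_state"]] / d$df[["pool_within_state"]]
  ms_resid <- d$ss[["residual"]] / d$df[["residual"]]
  states <- design_states(design)
  in_t <- design$tissue == tissue
  diff <- mean(y[in_t & design$state == states[2]]) -
    mean(y[in_t & design$state == states[1]])
  ms_comb <- (ms_pool + (T_ - 1) * ms_resid) / T_
  se <- sqrt(2 * ms_comb / P_)
  if (se == 0) return(if (diff == 0) 1 else 0)
  a <- ms_pool; b <- (T_ - 1) * ms_resid
  df_sat <- (a + b)^2 / (a^2 / d$df[["pool_within_state"]] +
                           b^2 / d$df[["residual"]])
  2 * stats::pt(abs(diff / se), df_sat, lower.tail = FALSE)
}

#' Method-of-moments variance components from a decomposition
#'
#' @param d output of [decompose()]
#' @param T_ number of tissues (within-subject measurements); defaults to
#'   \code{d$df[["tissue"]] + 1}
#' @return named numeric \code{var_pool}, \code{var_resid}; \code{var_pool}
#'   may be negative
#' @export
variance_components <- function(d, T_ = d$df[["tissue"]] + 1L) {
  ms_pool <- d$ss[["pool_within_state"]] / d$df[["pool_within_state"]]
  ms_resid <- d$ss[["residual"]] / d$df[["residual"]]
  c(var_pool = (ms_pool - ms_resid) / T_, var_resid = ms_resid)
}

#' Fold ratio within a tissue on the untransformed scale
#'
#' Mean of \code{2^y} over treated samples divided by the mean over control
#' samples, within the given tissue. The chips themselves are the samples.
#'
#' @inheritParams simple_effect
#' @return positive real
#' @export
fold_ratio <- function(y, design, tissue) {
  stopifnot(tissue %in% design_tissues(design))
  y <- y[design$sample]
  states <- design_states(design)
  in_t <- design$tissue == tissue
  mean(2^y[in_t & design$state == states[2]]) /
    mean(2^y[in_t & design$state == states[1]])
}

#' @export
print.splitplot_fit <- function(x, ...) {
  cat("Split-plot ANOVA fit:", nrow(x$results), "genes,",
      length(x$tissues), "tissues x 2 states x", design_pools(x$design),
      "pools\n")
  cat("  state contrast:", x$states[2], "-", x$states[1], "\n")
  cat("  df: state", x$df[["state"]], "| pool(state)", x$df[["pool"]],
      "| tissue", x$df[["tissue"]], "| interaction", x$df[["interaction"]],
      "| residual", x$df[["residual"]], "\n")
  invisible(x)
}

#' Summarize a split-plot fit
#'
#' @param object a \code{splitplot_fit}
#' @param alpha_state,alpha_simple thresholds echoed in the summary counts
#' @param ... unused
#' @export
summary.splitplot_fit <- function(object, alpha_state = 0.05,
                                  alpha_simple = 0.01, ...) {
  res <- object$results
  out <- list(n_genes = nrow(res),
              tissues = object$tissues,
              n_state = sum(res$p_state < alpha_state),
              n_simple = vapply(object$tissues, function(t)
                sum(res[[paste0("p_simple_", t)]] < alpha_simple), 0L),
              median_var_pool = stats::median(res$var_pool),
              median_var_resid = stats::median(res$var_resid),
              alpha_state = alpha_state, alpha_simple = alpha_simple)
  class(out) <- "summary.splitplot_fit"
  out
}

#' @export
print.summary.splitplot_fit <- function(x, ...) {
  cat("Split-plot ANOVA across", length(x$tissues), "tissues,",
      x$n_genes, "genes\n")
  cat("  genes with state p <", x$alpha_state, ":", x$n_state, "\n")
  for (t in x$tissues) {
    cat("  ", t, ": simple-effect p < ", x$alpha_simple, ": ",
        x$n_simple[[t]], "\n", sep = "")
  }
  cat("  median variance components: pool",
      signif(x$median_var_pool, 4), "| residual",
      signif(x$median_var_resid, 4), "\n")
  invisible(x)
}

#' Per-tissue log2 state effects
#'
#' @param object a \code{splitplot_fit}
#' @param ... unused
#' @return genes x tissues matrix of treated-minus-control log2 differences
#' @export
coef.splitplot_fit <- function(object, ...) {
  T_ <- length(object$tissues)
  idx_trt <- (seq_len(T_) - 1L) * 2L + 2L
  idx_ctl <- (seq_len(T_) - 1L) * 2L + 1L
  m <- object$cell_means[, idx_trt, drop = FALSE] -
    object$cell_means[, idx_ctl, drop = FALSE]
  colnames(m) <- object$tissues
  m
}

#' @export
fitted.splitplot_fit <- function(object, ...) {
  design <- object$design
  cell_idx <- (as.integer(design$tissue) - 1L) * 2L + as.integer(design$state)
  subj_means <- object$expr %*% {
    M <- stats::model.matrix(~ design$subject - 1)
    sweep(M, 2, colSums(M), "/")
  }
  state_of_subj <- match(sub("\\.[0-9]+$", "", levels(design$subject)),
                         design_states(design))
  subj_dev <- subj_means - (object$expr %*% {
    M <- stats::model.matrix(~ design$state - 1)
    sweep(M, 2, colSums(M), "/")
  })[, state_of_subj, drop = FALSE]
  f <- object$cell_means[, cell_idx, drop = FALSE] +
    subj_dev[, as.integer(design$subject), drop = FALSE]
  dimnames(f) <- dimnames(object$expr)
  f
}

#' @export
residuals.splitplot_fit <- function(object, ...) {
  object$expr - fitted(object)
}

#' Simulate expression matrices from a fitted model
#'
#' Parametric simulation from each gene's fitted cell means and its estimated
#' variance components (pool variance clamped at 0 for simulation).
#'
#' @param object a \code{splitplot_fit}
#' @param nsim number of simulated matrices
#' @param seed optional integer seed
#' @param ... unused
#' @return list of \code{nsim} genes x samples matrices
#' @export
simulate.splitplot_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  design <- object$design
  G <- nrow(object$expr)
  n_subj <- nlevels(design$subject)
  cell_idx <- (as.integer(design$tissue) - 1L) * 2L + as.integer(design$state)
  mu <- object$cell_means[, cell_idx, drop = FALSE]
  sd_pool <- sqrt(pmax(object$results$var_pool, 0))
  sd_resid <- sqrt(object$results$var_resid)
  lapply(seq_len(nsim), function(i) {
    pool_eff <- matrix(stats::rnorm(G * n_subj, sd = sd_pool), G, n_subj)
    y <- mu + pool_eff[, as.integer(design$subject), drop = FALSE] +
      matrix(stats::rnorm(G * ncol(mu), sd = sd_resid), G)
    dimnames(y) <- dimnames(object$expr)
    y
  })
}

#' Volcano plots of the per-tissue state response
#'
#' @param x a \code{splitplot_fit}
#' @param tissues tissues to plot (default all)
#' @param alpha_simple horizontal reference line (default 0.01)
#' @param ... passed to [plot()]
#' @export
plot.splitplot_fit <- function(x, tissues = x$tissues, alpha_simple = 0.01, ...) {
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(tissues)))
  on.exit(graphics::par(old))
  for (t in tissues) {
    r <- log2(x$results[[paste0("ratio_", t)]])
    p <- x$results[[paste0("p_simple_", t)]]
    graphics::plot(r, -log10(p), pch = 20, cex = 0.4,
                   xlab = "log2 fold ratio (treated/control)",
                   ylab = "-log10 simple-effect p", main = t, ...)
    graphics::abline(h = -log10(alpha_simple), col = "blue", lty = 2)
  }
  invisible(x)
}
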