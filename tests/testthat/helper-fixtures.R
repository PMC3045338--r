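# Small in-code fixtures shared across tests.

# A balanced design with arbitrary dimensions; tissue names default to the
# rat study's four when T = 4.
make_design <- function(T_ = 4, P_ = 4,
                        tissues = if (T_ == 4) {
                          c("liver", "duodenum", "jejunum", "ileum")
                        } else {
                          paste0("tis", seq_len(T_))
                        },
                        states = c("control", "lactating")) {
  grid <- expand.grid(pool = seq_len(P_), state = states, tissue = tissues,
                      stringsAsFactors = FALSE)
  grid$sample <- sprintf("%s_%s_p%d", grid$tissue, substr(grid$state, 1, 4),
                         grid$pool)
  study_design(grid[, c("sample", "tissue", "state", "pool")],
               tissues = tissues, states = states)
}

# Random expression matrix over a design.
make_expr <- function(design, n_genes = 10, seed = 1, sd = 0.5, mean = 8) {
  set.seed(seed)
  m <- matrix(stats::rnorm(n_genes * nrow(design), mean, sd), n_genes,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              design$sample))
  m
}

# A one-gene ANOVA result row with chosen p-values/ratios, for exercising the
# calling and pattern machinery without a fit.
make_result_row <- function(gene = "g1", p_state = 0.5, p_tissue = 0.5,
                            p_interaction = 0.5,
                            p_simple = c(liver = 0.5, duodenum = 0.5,
                                         jejunum = 0.5, ileum = 0.5),
                            ratio = c(liver = 1.5, duodenum = 1.5,
                                      jejunum = 1.5, ileum = 1.5)) {
  row <- data.frame(gene = gene, p_tissue = p_tissue, p_state = p_state,
                    p_interaction = p_interaction, stringsAsFactors = FALSE)
  for (t in names(p_simple)) row[[paste0("p_simple_", t)]] <- p_simple[[t]]
  for (t in names(ratio)) row[[paste0("ratio_", t)]] <- ratio[[t]]
  row$var_pool <- 0.1
  row$var_resid <- 0.1
  row$degenerate <- FALSE
  row
}

# Exhaustive hypergeometric upper tail by direct summation of binomial
# coefficients (independent of phyper).
enum_fisher_right <- function(k, K, n, N) {
  xs <- k:min(K, n)
  sum(choose(K, xs) * choose(N - K, n - xs)) / choose(N, n)
}

# aov() split-plot oracle: returns SS and p-values for one response vector.
aov_oracle <- function(y, design) {
  df <- data.frame(y = y[design$sample], tissue = design$tissue,
                   state = design$state, subject = design$subject)
  fit <- stats::aov(y ~ tissue * state + Error(subject), data = df)
  s <- summary(fit)
  between <- s[["Error: subject"]][[1]]
  within <- s[["Error: Within"]][[1]]
  rownames(between) <- trimws(rownames(between))
  rownames(within) <- trimws(rownames(within))
  list(ss = c(state = between["state", "Sum Sq"],
              pool_within_state = between["Residuals", "Sum Sq"],
              tissue = within["tissue", "Sum Sq"],
              interaction = within["tissue:state", "Sum Sq"],
              residual = within["Residuals", "Sum Sq"]),
       p = c(p_tissue = within["tissue", "Pr(>F)"],
             p_state = between["state", "Pr(>F)"],
             p_interaction = within["tissue:state", "Pr(>F)"]))
}
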