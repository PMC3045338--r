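test_that("degenerate and constructed responses decompose as expected", {
  d <- make_design(4, 4)

  # constant response: every component zero, degenerate p = 1
  y <- stats::setNames(rep(3, nrow(d)), d$sample)
  dec <- decompose(y, d)
  expect_equal(unname(dec$ss), rep(0, 5))
  expect_equal(unname(f_tests(dec)), rep(1, 3))
  fit <- splitplot_fit(rbind(g1 = y), d)
  expect_true(fit$results$degenerate)
  expect_equal(fit$results$p_state, 1)

  # pure subject offsets: only the pool component is nonzero
  offsets <- stats::setNames(seq_len(8), levels(d$subject))
  y2 <- stats::setNames(offsets[as.character(d$subject)] -
                          mean(offsets[as.character(d$subject)]), d$sample)
  # remove the state-mean part so the state SS is exactly zero
  sm <- tapply(y2, d$state, mean)
  y2 <- stats::setNames(as.numeric(y2 - sm[as.character(d$state)]), d$sample)
  dec2 <- decompose(y2, d)
  expect_equal(dec2$ss[["state"]], 0, tolerance = 1e-12)
  expect_equal(dec2$ss[["tissue"]], 0, tolerance = 1e-12)
  expect_equal(dec2$ss[["interaction"]], 0, tolerance = 1e-12)
  expect_equal(dec2$ss[["residual"]], 0, tolerance = 1e-12)
  expect_gt(dec2$ss[["pool_within_state"]], 0)
})

test_that("sums of squares conserve the corrected total and match the aov oracle", {
  set.seed(11)
  for (rep in 1:3) {
    for (T_ in c(2, 4)) {
      for (P_ in c(2, 4)) {
        d <- make_design(T_, P_)
        y <- stats::setNames(stats::rnorm(nrow(d)), d$sample)
        dec <- decompose(y, d)
        expect_equal(sum(dec$ss), dec$ss_total, tolerance = 1e-8)
        expect_equal(sum(dec$df), nrow(d) - 1)
        oracle <- aov_oracle(y, d)
        expect_equal(dec$ss, oracle$ss, tolerance = 1e-10)
        expect_equal(f_tests(dec), oracle$p, tolerance = 1e-10)
      }
    }
  }
})

test_that("the vectorized fit reproduces the per-gene path exactly", {
  d <- make_design(4, 3)
  expr <- make_expr(d, n_genes = 12, seed = 9)
  fit <- splitplot_fit(expr, d)
  for (g in c(1, 5, 12)) {
    y <- expr[g, ]
    dec <- decompose(y, d)
    expect_equal(unname(fit$ss[g, ]), unname(dec$ss), tolerance = 1e-12)
    p3 <- f_tests(dec)
    expect_equal(fit$results$p_state[g], p3[["p_state"]], tolerance = 1e-12)
    expect_equal(fit$results$p_tissue[g], p3[["p_tissue"]], tolerance = 1e-12)
    expect_equal(fit$results$p_interaction[g], p3[["p_interaction"]],
                 tolerance = 1e-12)
    for (t in design_tissues(d)) {
      expect_equal(fit$results[[paste0("p_simple_", t)]][g],
                   simple_effect(y, d, t), tolerance = 1e-12)
      expect_equal(fit$results[[paste0("ratio_", t)]][g],
                   fold_ratio(y, d, t), tolerance = 1e-12)
    }
    vc <- variance_components(dec)
    expect_equal(fit$results$var_pool[g], vc[["var_pool"]], tolerance = 1e-12)
    expect_equal(fit$results$var_resid[g], vc[["var_resid"]], tolerance = 1e-12)
  }
})

test_that("simple effects and fold ratios behave on constructed inputs", {
  d <- make_design(4, 4)
  set.seed(2)
  base <- stats::rnorm(nrow(d), 8, 0.4)
  y <- stats::setNames(base, d$sample)

  # shift every lactating sample by +1 log2: ratio exactly 2 in each tissue
  y2 <- y + (d$state == "lactating")
  for (t in design_tissues(d)) {
    expect_equal(fold_ratio(y2, d, t),
                 mean(2^y2[d$tissue == t & d$state == "lactating"]) /
                   mean(2^y2[d$tissue == t & d$state == "control"]),
                 tolerance = 1e-12)
  }
  y3 <- stats::setNames(rep(5, nrow(d)), d$sample)
  y3[d$tissue == "liver" & d$state == "lactating"] <-
    y3[d$tissue == "liver" & d$state == "lactating"] + 1
  expect_equal(fold_ratio(y3, d, "liver"), 2)
  expect_equal(fold_ratio(y3, d, "jejunum"), 1)

  # identical group means within a tissue under a mirrored response: p = 1
  ym <- y - stats::ave(y, paste(d$tissue, d$state))  # all cell means zero
  expect_equal(simple_effect(ym, d, "liver"), 1, tolerance = 1e-9)
})

test_that("variance components are method-of-moments and unclamped by default", {
  d <- make_design(4, 2)
  # craft MS_pool < MS_residual: strong within-subject scatter, equal subjects
  set.seed(4)
  y <- stats::setNames(stats::rnorm(nrow(d), sd = 1), d$sample)
  subj_means <- tapply(y, d$subject, mean)
  # remove between-subject spread
  y <- stats::setNames(as.numeric(y - subj_means[as.character(d$subject)]),
                       d$sample)
  dec <- decompose(y, d)
  vc <- variance_components(dec)
  expect_lt(vc[["var_pool"]], 0)
  fit_raw <- splitplot_fit(rbind(g1 = y), d)
  expect_equal(fit_raw$results$var_pool, vc[["var_pool"]], tolerance = 1e-12)
  fit_clamped <- splitplot_fit(rbind(g1 = y), d, clamp_var_pool = TRUE)
  expect_equal(fit_clamped$results$var_pool, 0)
})

test_that("power is monotone nondecreasing in effect size at fixed noise", {
  powers <- vapply(c(0.5, 1.0, 1.5), function(eff) {
    sim <- simulate_study(simulation_config(
      seed = 77, n_genes = 400, sigma_pool = 0.3, sigma_resid = 0.3,
      pattern_table = list(list(pattern = c(1L, 1L, 1L, 1L), effect = eff,
                                fraction = 0.5)),
      absent_fraction = 0, unannotated_fraction = 0, exons_per_gene = 1))
    fit <- splitplot_fit(sim$expression, sim$design)
    planted <- sim$truth$genes$pattern != 0
    mean(fit$results$p_state[planted] < 0.05)
  }, 0)
  expect_true(all(diff(powers) >= 0))
})

test_that("fit methods are mutually consistent", {
  d <- make_design(4, 4)
  sim <- simulate_study(simulation_config(seed = 13, n_genes = 30,
                                          exons_per_gene = 1))
  fit <- splitplot_fit(sim$expression, sim$design)

  # residuals + fitted reconstruct the data
  expect_equal(fitted(fit) + residuals(fit), fit$expr, tolerance = 1e-10)

  # coefficients are the per-tissue log2 state differences
  co <- coef(fit)
  g <- 3
  for (t in fit$tissues) {
    y <- fit$expr[g, ]
    dd <- fit$design
    expect_equal(co[g, t],
                 mean(y[dd$tissue == t & dd$state == "lactating"]) -
                   mean(y[dd$tissue == t & dd$state == "control"]),
                 tolerance = 1e-10)
  }

  # simulate() is reproducible and has the right shape
  s1 <- simulate(fit, nsim = 2, seed = 5)
  s2 <- simulate(fit, nsim = 2, seed = 5)
  expect_identical(s1, s2)
  expect_equal(dim(s1[[1]]), dim(fit$expr))

  out <- summary(fit)
  expect_s3_class(out, "summary.splitplot_fit")
  expect_equal(out$n_genes, 30)
})
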