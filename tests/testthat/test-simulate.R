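test_that("the generator is deterministic and substreams are independent", {
  cfg <- simulation_config(seed = 99, n_genes = 100, exons_per_gene = 2)
  s1 <- simulate_study(cfg)
  s2 <- simulate_study(cfg)
  expect_identical(s1$expression, s2$expression)
  expect_identical(s1$exons, s2$exons)
  expect_identical(s1$annotation, s2$annotation)
  expect_identical(s1$gene_sets[], s2$gene_sets[])
  expect_identical(s1$truth, s2$truth)

  # changing a downstream table's parameters leaves the expression draw alone
  cfg2 <- simulation_config(seed = 99, n_genes = 100, exons_per_gene = 3)
  s3 <- simulate_study(cfg2)
  expect_identical(s3$expression, s1$expression)

  expect_error(simulation_config(absent_fraction = 0.7,
                                 unannotated_fraction = 0.4),
               "config_fractions")
})

test_that("subject covariance across tissues is compound-symmetric by construction", {
  # strip gene-level and tissue-level heterogeneity so the covariance across
  # genes between two chips reflects only the pool and residual components
  cfg <- simulation_config(seed = 7, n_genes = 4000, sigma_pool = 0.5,
                           sigma_resid = 0.4, baseline_sd = 0,
                           tissue_effect_sd = 0, pattern_table = list(),
                           absent_fraction = 0, unannotated_fraction = 0,
                           exons_per_gene = 1)
  sim <- simulate_study(cfg)
  d <- sim$design
  subj <- levels(d$subject)[1]
  chips <- d$sample[d$subject == subj]
  other <- d$sample[d$subject == levels(d$subject)[5]][1]
  covs <- c()
  for (i in 1:3) {
    for (j in (i + 1):4) {
      covs <- c(covs, stats::cov(sim$expression[, chips[i]],
                                 sim$expression[, chips[j]]))
    }
  }
  # same-subject chips share sigma_pool^2; across subjects nothing
  expect_equal(mean(covs), 0.25, tolerance = 0.05)
  expect_lt(stats::sd(covs), 0.05)
  expect_lt(abs(stats::cov(sim$expression[, chips[1]],
                           sim$expression[, other])), 0.05)
  # total per-chip variance = pool + residual
  expect_equal(stats::var(sim$expression[, chips[1]]), 0.25 + 0.16,
               tolerance = 0.05)
})

test_that("variance components are recovered without material bias", {
  cfg <- simulation_config(seed = 12, n_genes = 3000, sigma_pool = sqrt(0.5),
                           sigma_resid = 0.5, pattern_table = list(),
                           absent_fraction = 0, unannotated_fraction = 0,
                           exons_per_gene = 1)
  sim <- simulate_study(cfg)
  fit <- splitplot_fit(sim$expression, sim$design)
  expect_equal(mean(fit$results$var_pool), 0.5, tolerance = 0.05)
  expect_equal(mean(fit$results$var_resid), 0.25, tolerance = 0.05)
})

test_that("perfect-information studies are fully recovered, and universes must match", {
  cfg <- simulation_config(seed = 3, n_genes = 300, sigma_pool = 0.02,
                           sigma_resid = 0.02,
                           # all-tissue patterns: with huge effects and tiny
                           # noise these are recovered exactly (single-tissue
                           # patterns keep a ~5% spurious-tendency floor in
                           # the other tissues, so they are not a clean limit)
                           pattern_table = list(
                             list(pattern = c(1L, 1L, 1L, 1L), effect = 3,
                                  fraction = 0.1),
                             list(pattern = c(-1L, -1L, -1L, -1L), effect = 3,
                                  fraction = 0.1)),
                           absent_fraction = 0.1, unannotated_fraction = 0.1,
                           exons_per_gene = 2)
  sim <- simulate_study(cfg)
  calls <- call_presence(sim$exons)
  expressed <- gene_expressed(calls, sim$design)
  annotated <- suppressMessages(
    gene_annotated(sim$annotation, genes = rownames(sim$expression)))
  report <- gene_filter_report(rownames(sim$expression), expressed, annotated)
  tested <- select_tested_genes(sim$expression, report)
  fit <- splitplot_fit(tested, sim$design)
  de <- call_de(fit$results)
  codes <- pattern_code(de, fit$results)
  enr <- enrich_collection(sim$gene_sets, de$gene[de$any_de], fit$results$gene)
  ev <- evaluate_against_truth(de, codes, enr, sim$truth)
  expect_equal(ev$pattern_recovery, 1.0)
  expect_equal(ev$per_tissue$tpr, rep(1, 4))
  expect_true(all(ev$per_tissue$fpr < 0.05))
  expect_equal(ev$planted_set_rank, 1L)

  # shuffled truth: outputs over a different universe are rejected
  truncated <- de[-1, ]
  expect_error(evaluate_against_truth(truncated, codes, enr, sim$truth),
               "truth_gene_mismatch")
})

test_that("under a shuffled gene labelling, recovery drops to chance", {
  cfg <- simulation_config(seed = 5, n_genes = 400, sigma_pool = 0.1,
                           sigma_resid = 0.1,
                           pattern_table = list(
                             list(pattern = c(1L, 1L, 1L, 1L), effect = 2,
                                  fraction = 0.25)),
                           absent_fraction = 0, unannotated_fraction = 0,
                           exons_per_gene = 1)
  sim <- simulate_study(cfg)
  fit <- splitplot_fit(sim$expression, sim$design)
  de <- call_de(fit$results)
  codes <- pattern_code(de, fit$results)
  ev <- evaluate_against_truth(de, codes, NULL, sim$truth)
  expect_gt(ev$pattern_recovery, 0.9)

  set.seed(1)
  shuffled <- de
  shuffled$gene <- sample(shuffled$gene)
  codes_sh <- codes
  codes_sh$gene <- shuffled$gene
  ev_sh <- evaluate_against_truth(shuffled, codes_sh, NULL, sim$truth)
  expect_lt(ev_sh$pattern_recovery, 0.5)
})
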