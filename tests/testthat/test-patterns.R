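test_that("worked pattern codes follow the weighted signed sum", {
  rows <- rbind(
    # up in liver only
    make_result_row("up_liver", p_state = 0.01,
                    p_simple = c(liver = 0.001, duodenum = 0.5, jejunum = 0.5,
                                 ileum = 0.5),
                    ratio = c(liver = 2, duodenum = 1.1, jejunum = 1.1,
                              ileum = 1.1)),
    # down in duodenum only
    make_result_row("down_duod", p_state = 0.01,
                    p_simple = c(liver = 0.5, duodenum = 0.001, jejunum = 0.5,
                                 ileum = 0.5),
                    ratio = c(liver = 1.1, duodenum = 0.4, jejunum = 1.1,
                              ileum = 1.1)),
    # up everywhere
    make_result_row("up_all", p_state = 0.001,
                    p_simple = c(liver = 0.001, duodenum = 0.002,
                                 jejunum = 0.003, ileum = 0.004),
                    ratio = c(liver = 2, duodenum = 2, jejunum = 2,
                              ileum = 2)),
    # up everywhere except down in ileum: the formula gives 1109
    make_result_row("mixed", p_state = 0.001,
                    p_simple = c(liver = 0.001, duodenum = 0.002,
                                 jejunum = 0.003, ileum = 0.004),
                    ratio = c(liver = 2, duodenum = 2, jejunum = 2,
                              ileum = 0.5)))
  calls <- call_de(rows)
  codes <- pattern_code(calls, rows)
  expect_equal(codes$pattern, c(1000L, -100L, 1111L, 1109L))

  # a tendency (p < 0.05) in a tissue that missed the stringent cutoff still
  # contributes to the code of a gene that is DE elsewhere
  row5 <- make_result_row("tend", p_state = 0.01,
                          p_simple = c(liver = 0.001, duodenum = 0.03,
                                       jejunum = 0.5, ileum = 0.5),
                          ratio = c(liver = 2, duodenum = 0.5, jejunum = 1.1,
                                    ileum = 1.1))
  codes5 <- pattern_code(call_de(row5), row5)
  expect_equal(codes5$pattern, 1000L - 100L)
})

test_that("genes not DE anywhere get code 0 regardless of tendencies", {
  row <- make_result_row("null", p_state = 0.5,
                         p_simple = c(liver = 0.001, duodenum = 0.001,
                                      jejunum = 0.001, ileum = 0.001),
                         ratio = c(liver = 2, duodenum = 2, jejunum = 2,
                                   ileum = 2))
  codes <- pattern_code(call_de(row), row)
  expect_equal(codes$pattern, 0L)
})

test_that("the code map is injective over all 81 combinations and decode inverts it", {
  tissues <- c("liver", "duodenum", "jejunum", "ileum")
  grid <- as.matrix(expand.grid(rep(list(c(-1L, 0L, 1L)), 4)))
  codes <- as.integer(grid %*% pattern_weights(tissues))
  expect_equal(length(unique(codes)), 81)
  for (i in seq_len(nrow(grid))) {
    expect_equal(unname(decode_pattern(codes[i], tissues)),
                 unname(grid[i, ]))
  }
  expect_equal(unname(decode_pattern(1000L)), c(1L, 0L, 0L, 0L))
  expect_equal(unname(decode_pattern(-100L)), c(0L, -1L, 0L, 0L))
  expect_error(decode_pattern(500L), "pattern_unattainable")
})

test_that("changing a non-significant tissue's ratio never changes the code", {
  base <- make_result_row("g", p_state = 0.01,
                          p_simple = c(liver = 0.001, duodenum = 0.5,
                                       jejunum = 0.5, ileum = 0.5),
                          ratio = c(liver = 2, duodenum = 1.5, jejunum = 1.5,
                                    ileum = 1.5))
  code0 <- pattern_code(call_de(base), base)$pattern
  for (r in c(0.2, 0.9, 3)) {
    alt <- base
    alt$ratio_jejunum <- r
    expect_equal(pattern_code(call_de(alt), alt)$pattern, code0)
  }
})

test_that("named pattern groups are assigned by exact code", {
  rows <- do.call(rbind, lapply(seq_len(4), function(i) {
    make_result_row(paste0("g", i), p_state = 0.001,
                    p_simple = c(liver = 0.001, duodenum = 0.001,
                                 jejunum = 0.001, ileum = 0.001),
                    ratio = c(liver = 0.5, duodenum = 0.5, jejunum = 0.5,
                              ileum = 0.5))
  }))
  # g1 down everywhere (-1111); g2 up in the small intestine only (111);
  # g3 an unnamed mixed code; g4 untouched copy of g1
  rows[2, c("ratio_duodenum", "ratio_jejunum", "ratio_ileum")] <- 2
  rows[2, "p_simple_liver"] <- 0.5
  rows[3, c("ratio_liver", "ratio_duodenum", "ratio_jejunum")] <- 2
  rows[3, "p_simple_ileum"] <- 0.06
  calls <- call_de(rows)
  codes <- pattern_code(calls, rows)
  groups <- assign_pattern_groups(codes)
  expect_equal(sort(groups[["down in all tissues"]]), c("g1", "g4"))
  expect_equal(groups[["up in all parts of small intestine"]], "g2")
  expect_equal(groups[["1110"]], "g3")
  expect_equal(assign_pattern_groups(codes[0, ]), list())
})

test_that("a significant tendency with ratio exactly 1 resolves to +1 with a warning", {
  row <- make_result_row("g", p_state = 0.01,
                         p_simple = c(liver = 0.001, duodenum = 0.5,
                                      jejunum = 0.5, ileum = 0.5),
                         ratio = c(liver = 1, duodenum = 1.2, jejunum = 1.2,
                                   ileum = 1.2))
  expect_warning(codes <- pattern_code(call_de(row), row), "ratio exactly 1")
  expect_equal(codes$pattern, 1000L)
})
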