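# Normalization and hypothesis-test statistics for tabulated experiments.

make_measurements <- function(basal_ratios, treated_ratios, hk = 10) {
  tibble::tibble(
    sample_id = sprintf("s%d", seq_len(length(basal_ratios) +
                                         length(treated_ratios))),
    condition = c(rep("basal", length(basal_ratios)),
                  rep("kd", length(treated_ratios))),
    target_abundance = c(basal_ratios, treated_ratios) * hk,
    housekeeping_abundance = hk
  )
}

test_that("relative expression normalizes to housekeeping then basal", {
  d <- make_measurements(c(1, 1), c(0.6, 0.8))
  res <- relative_expression(d, "kd")
  expect_equal(res$percent_change, 30)  # mean treated normalized = 0.7
  expect_equal(res$replicates$normalized[res$replicates$condition == "basal"],
               c(1, 1))

  same <- make_measurements(c(1, 1), c(1, 1))
  expect_equal(relative_expression(same, "kd")$percent_change, 0)
})

test_that("relative expression is invariant to global rescaling and order", {
  d <- make_measurements(c(1.2, 0.8, 1.0), c(0.5, 0.7))
  res <- relative_expression(d, "kd")
  scaled <- d
  scaled$target_abundance <- scaled$target_abundance * 10
  scaled$housekeeping_abundance <- scaled$housekeeping_abundance * 10
  expect_equal(relative_expression(scaled, "kd")$percent_change,
               res$percent_change)
  shuffled <- d[c(4, 1, 5, 3, 2), ]
  expect_equal(relative_expression(shuffled, "kd")$percent_change,
               res$percent_change)
  expect_error(relative_expression(
    dplyr::mutate(d, target_abundance = -target_abundance), "kd"
  ), "positive")
})

test_that("pooled t statistic matches the closed form", {
  res <- student_t_two_sample(c(1, 2, 3), c(2, 3, 4))
  # pooled s = 1, se = sqrt(2/3)
  expect_equal(res$t, -1 / sqrt(2 / 3), tolerance = 1e-10)
  expect_equal(res$df, 4)
  expect_equal(res$p_value, 2 * pt(-abs(res$t), df = 4), tolerance = 1e-12)
  expect_equal(round(res$p_value, 3), 0.288)

  ident <- student_t_two_sample(c(1, 2, 3), c(1, 2, 3))
  expect_equal(ident$t, 0)
  expect_equal(ident$p_value, 1)

  expect_error(student_t_two_sample(1, c(1, 2)), ">= 2")
})

test_that("t statistic flips sign under group swap, p unchanged", {
  set.seed(31)
  for (i in 1:20) {
    a <- rnorm(4); b <- rnorm(5, 0.5)
    ab <- student_t_two_sample(a, b)
    ba <- student_t_two_sample(b, a)
    expect_equal(ab$t, -ba$t, tolerance = 1e-12)
    expect_equal(ab$p_value, ba$p_value, tolerance = 1e-12)
  }
})

test_that("Mann-Whitney U: exact small-sample p and the U identity", {
  res <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 1 / 3)
  expect_equal(res$method, "exact")

  # U_a + U_b = n_a * n_b
  set.seed(13)
  for (i in 1:20) {
    a <- rnorm(sample(2:6, 1))
    b <- rnorm(sample(2:6, 1))
    expect_equal(mann_whitney_u(a, b)$U + mann_whitney_u(b, a)$U,
                 length(a) * length(b))
  }

  # identical multisets: tied, approximate route, p near 1
  tied <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(tied$method, "normal")
  expect_gt(tied$p_value, 0.9)
})

test_that("exact Mann-Whitney p equals enumeration for all n_a = n_b <= 4", {
  set.seed(17)
  for (n in 2:4) {
    for (i in 1:10) {
      x <- sample(seq(1, 100), 2 * n)  # distinct values, no ties
      a <- x[seq_len(n)]
      b <- x[-seq_len(n)]
      expect_equal(mann_whitney_u(a, b)$p_value, oracle_mann_whitney_p(a, b),
                   tolerance = 1e-12)
    }
  }
})

test_that("allele log2 fold-change pairs replicates and tests on log scale", {
  enr <- tibble::tibble(
    factor = "FOXTF",
    allele = rep(c("wildtype", "variant"), each = 3),
    replicate = rep(c("r1", "r2", "r3"), 2),
    enrichment = c(1, 2, 4, 2, 4, 8)  # variant exactly 2x per replicate
  )
  res <- allele_log2fc(enr, "FOXTF")
  expect_true(res$paired)
  expect_equal(res$log2fc$log2fc, c(1, 1, 1))
  expect_equal(res$mean_log2fc, 1)

  equal <- enr
  equal$enrichment <- rep(c(1, 2, 4), 2)
  res0 <- allele_log2fc(equal, "FOXTF")
  expect_equal(res0$mean_log2fc, 0)

  half <- enr
  half$enrichment <- c(2, 4, 8, 1, 2, 4)
  expect_equal(allele_log2fc(half, "FOXTF")$mean_log2fc, -1)

  # unpaired fallback: replicate ids do not match
  unpaired <- enr
  unpaired$replicate <- c("r1", "r2", "r3", "x1", "x2", "x3")
  resu <- allele_log2fc(unpaired, "FOXTF")
  expect_false(resu$paired)
  expect_equal(resu$log2fc$log2fc,
               log2(c(2, 4, 8) / mean(c(1, 2, 4))))

  expect_error(allele_log2fc(enr[enr$allele == "variant", ], "FOXTF"),
               "replicates per allele")
})

test_that("efficiency-expression correlation reproduces r and its t-transform p", {
  res <- efficiency_expression_correlation(c(1, 2, 3, 4), c(1, 3, 2, 4))
  expect_equal(res$r, 0.8)
  tstat <- 0.8 * sqrt(2 / (1 - 0.64))
  expect_equal(res$p_value, 2 * pt(-tstat, df = 2), tolerance = 1e-12)

  anti <- efficiency_expression_correlation(1:5, 5:1)
  expect_equal(anti$r, -1)
  expect_equal(anti$p_value, 0)

  expect_error(efficiency_expression_correlation(1:2, 1:2), ">= 3")
  expect_error(efficiency_expression_correlation(c(1, 1, 1), 1:3),
               "undefined")
})

test_that("BH adjustment delegates to the standard stepped-up procedure", {
  p <- c(0.01, 0.02, 0.9, 0.04)
  expect_equal(adjust_bh(p), stats::p.adjust(p, "BH"))
})
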