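test_that("ci_value is the signed fraction of 4S minus 2S DCOs", {
  expect_equal(ci_value(112, 178, 95), -17 / 385)
  expect_equal(ci_value(21, 21, 11), -10 / 53)
  for (k in c(1, 7, 40)) expect_equal(ci_value(k, 0, k), 0)
  expect_equal(ci_value(9, 0, 0), -1)
  expect_equal(ci_value(0, 0, 5), 1)
  expect_error(ci_value(0, 0, 0), "undefined")
  expect_error(ci_value(-1, 2, 0), "non-negative")
})

test_that("ci_value equals the mean of expanded per-DCO scores", {
  set.seed(101)
  for (i in 1:25) {
    n <- rmultinom(1, sample(1:200, 1), c(1, 2, 1) / 4)[, 1]
    if (sum(n) == 0) next
    scores <- rep(c(-1, 0, 1), n)
    expect_equal(ci_value(n[1], n[2], n[3]), mean(scores))
    expect_gte(ci_value(n[1], n[2], n[3]), -1)
    expect_lte(ci_value(n[1], n[2], n[3]), 1)
    # permutation of the DCOs changes nothing
    expect_equal(mean(sample(scores)), mean(scores))
  }
})

test_that("chi-square GOF against 1:2:1 matches an independent oracle", {
  got <- chi2_gof_121(55, 66, 48)
  expect_equal(got$chi2, 8.68, tolerance = 1e-3)
  expect_equal(round(got$p_value, 3), 0.013)
  exact <- chi2_gof_121(25, 50, 25)
  expect_equal(exact$chi2, 0)
  expect_equal(exact$p_value, 1)
  set.seed(202)
  for (i in 1:20) {
    n <- rmultinom(1, 20 + sample(1:300, 1), c(0.3, 0.4, 0.3))[, 1]
    got <- chi2_gof_121(n[1], n[2], n[3])
    ref <- pearson_oracle(n, c(1, 2, 1) / 4)
    expect_equal(got$chi2, unname(ref["stat"]))
    expect_equal(got$p_value, unname(ref["p"]))
  }
  expect_warning(chi2_gof_121(3, 6, 3), "expected count below 5")
})

test_that("signed-rank test drops zeros and matches the normal-approx oracle", {
  scores <- rep(c(-1L, 0L, 1L), c(21, 21, 11))
  expect_equal(wilcoxon_vs_zero(scores, "less"),
               signed_rank_oracle(scores, "less"))
  expect_equal(round(wilcoxon_vs_zero(scores, "less"), 3), 0.039)
  expect_equal(wilcoxon_vs_zero(scores),
               signed_rank_oracle(scores, "two.sided"))
  set.seed(303)
  for (i in 1:20) {
    s <- sample(c(-1L, 0L, 1L), sample(5:80, 1), replace = TRUE)
    if (all(s == 0)) next
    for (alt in c("two.sided", "less", "greater")) {
      expect_equal(wilcoxon_vs_zero(s, alt), signed_rank_oracle(s, alt))
    }
  }
  # symmetric scores: no evidence against zero
  expect_equal(wilcoxon_vs_zero(rep(c(-1L, 1L), 8)), 1)
  expect_true(is.na(wilcoxon_vs_zero(c(0L, 0L, 0L))))
  expect_error(wilcoxon_vs_zero(integer()), "non-empty")
  expect_error(wilcoxon_vs_zero(c(0.5, 1)), "only -1, 0")
})

test_that("Bonferroni multiplies by the family size and caps at one", {
  expect_equal(bonferroni(0.024, family = 5), 0.12)
  expect_equal(bonferroni(0.01, family = 1), 0.01)
  expect_equal(bonferroni(0.5, family = 10), 1)
  expect_equal(bonferroni(c(0.01, 0.02)), c(0.02, 0.04))
  expect_error(bonferroni(1.2), "\\[0, 1\\]")
})

test_that("group summaries assemble counts, CI value and both tests", {
  s <- summarize_counts(12, 29, 4, group = "chr2/spanning",
                        alternative = "less")
  expect_equal(s$n_dco, 45L)
  expect_equal(c(s$exp_2s, s$exp_3s, s$exp_4s), c(11.25, 22.5, 11.25))
  expect_equal(format_ci_value(s$ci_value), "-0.18")
  expect_equal(round(s$chi2_p, 3), 0.037)
  expect_equal(round(s$wilcoxon_p, 3), 0.024)

  single <- summarize_counts(0, 1, 0)
  expect_equal(single$ci_value, 0)
  expect_true(is.na(single$wilcoxon_p))

  dc <- tibble::tibble(strand_class = c("2S", "3S", "4S", "3S", NA),
                       ci_score = c(-1L, 0L, 1L, 0L, NA))
  g <- summarize_group(dc, "demo")
  expect_equal(c(g$n2s, g$n3s, g$n4s), c(1L, 2L, 1L)) # NA class ignored
  expect_equal(g$ci_value, 0)
  expect_warning(summarize_group(dc[0, ], "empty"), "skipped")
})

test_that("partitioned summaries adjust chromosome-level tests", {
  set.seed(7)
  dc <- tibble::tibble(
    chromosome = rep(c("c1", "c2"), each = 30),
    strand_class = sample(c("2S", "3S", "4S"), 60, TRUE, c(1, 2, 1) / 4),
    arm_relation = sample(c("same_arm", "spans_centromere"), 60, TRUE)
  )
  dc$ci_score <- c(`2S` = -1L, `3S` = 0L, `4S` = 1L)[dc$strand_class]
  genome <- ci_summary(dc, "genome")
  expect_equal(nrow(genome), 1)
  expect_equal(genome$n_dco, 60L)
  by_chr <- ci_summary(dc, "chromosome")
  expect_equal(nrow(by_chr), 2)
  expect_equal(by_chr$p_adjusted, pmin(1, by_chr$wilcoxon_p * 2))
  by_arm <- ci_summary(dc, "arm")
  expect_equal(sum(by_arm$n_dco), 60L)
  both <- ci_summary(dc, "chromosome_arm")
  fam <- dplyr::count(both, arm_relation)
  expect_equal(nrow(both), 4)
  # family size is the number of chromosome tests within each arm column
  expect_equal(both$p_adjusted,
               pmin(1, both$wilcoxon_p * 2))
})
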