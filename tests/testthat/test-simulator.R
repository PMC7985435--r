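test_that("identical configuration and seed give identical output", {
  a <- simulate_tetrads(n_tetrads = 8, strand_bias_r = 0.3,
                        genotyping_error_rate = 0.01, missing_rate = 0.02,
                        seed = 99)
  b <- simulate_tetrads(n_tetrads = 8, strand_bias_r = 0.3,
                        genotyping_error_rate = 0.01, missing_rate = 0.02,
                        seed = 99)
  expect_identical(a$dataset$genotypes, b$dataset$genotypes)
  expect_identical(a$truth, b$truth)
  c <- simulate_tetrads(n_tetrads = 8, strand_bias_r = 0.3, seed = 100)
  expect_false(identical(a$truth, c$truth))
})

test_that("every marker column segregates 2:2 before noise injection", {
  sim <- simulate_tetrads(n_tetrads = 12, seed = 5)
  expect_equal(nrow(sim$dataset$anomalies), 0)
  counts <- sim$dataset$genotypes |>
    dplyr::summarise(n_a = sum(allele == "A"), n = dplyr::n(),
                     .by = c(tetrad_id, chromosome, marker))
  expect_true(all(counts$n == 4))
  expect_true(all(counts$n_a == 2))
})

test_that("obligate CO leaves no bivalent empty; rates behave as configured", {
  sim <- simulate_tetrads(n_tetrads = 40, co_lambda = 0.8, obligate = TRUE,
                          seed = 21)
  per_biv <- dplyr::count(sim$truth, tetrad_id, chromosome)
  expect_equal(nrow(per_biv), 40 * 5) # every bivalent has >= 1 CO
  expect_true(all(per_biv$n >= 1))

  noisy <- simulate_tetrads(n_tetrads = 30, missing_rate = 0.1,
                            genotyping_error_rate = 0.05, seed = 22)
  g <- noisy$dataset$genotypes
  miss_rate <- mean(is.na(g$allele))
  expect_gt(miss_rate, 0.07); expect_lt(miss_rate, 0.13)
  # flipped calls break 2:2 in some columns -> anomalies appear
  expect_gt(nrow(noisy$dataset$anomalies), 0)
})

test_that("extreme strand bias gives the degenerate DCO types", {
  all2s <- simulate_tetrads(n_tetrads = 40, co_lambda = 3,
                            strand_bias_r = 1, seed = 31)
  t2 <- true_dco_types(all2s$truth)
  expect_true(all(t2$strand_class == "2S"))
  expect_equal(true_ci(all2s$truth), -1)

  all4s <- simulate_tetrads(n_tetrads = 40, co_lambda = 3,
                            strand_bias_r = 0, seed = 32)
  expect_equal(true_ci(all4s$truth), 1)
})

test_that("type frequencies follow r^2 : 2r(1-r) : (1-r)^2", {
  sim <- simulate_tetrads(n_tetrads = 600, co_lambda = 3,
                          strand_bias_r = 0.25, seed = 33)
  types <- true_dco_types(sim$truth)
  n <- nrow(types)
  freq <- table(factor(types$strand_class, c("2S", "3S", "4S"))) / n
  expect_gt(n, 2000)
  tol <- 4 / sqrt(n)
  expect_equal(unname(freq[["2S"]]), 0.0625, tolerance = tol / 0.0625)
  expect_equal(unname(freq[["3S"]]), 0.375, tolerance = tol / 0.375)
  expect_equal(unname(freq[["4S"]]), 0.5625, tolerance = tol / 0.5625)
  se <- sqrt(2 * 0.25 * 0.75 / n)
  expect_lt(abs(true_ci(sim$truth) - 0.5), 4 * se)
})

test_that("true DCO types derive from the recorded chromatid pairs", {
  truth <- tibble::tibble(
    tetrad_id = "T0001", chromosome = "chr1", co_index = 1:4,
    position_bp = c(1e6, 5e6, 9e6, 20e6),
    mat_strand = c(1L, 1L, 2L, 1L),
    pat_strand = c(1L, 1L, 1L, 2L)
  )
  types <- true_dco_types(truth)
  expect_equal(types$strand_class, c("2S", "3S", "4S"))
  expect_equal(types$ci_score, c(-1L, 0L, 1L))
  expect_equal(true_ci(truth), 0)
  # a single CO has no DCO
  expect_true(is.na(true_ci(truth[1, ])))
})

test_that("invalid configurations are rejected", {
  expect_error(simulate_tetrads(n_tetrads = 0), "at least 1")
  expect_error(simulate_tetrads(n_tetrads = 2, strand_bias_r = 1.2),
               "\\[0, 1\\]")
  expect_error(simulate_tetrads(n_tetrads = 2, missing_rate = 1), "rates")
  genome <- tibble::tibble(chromosome = "c1", length_bp = 1e6)
  expect_error(simulate_tetrads(n_tetrads = 2, genome = genome,
                                marker_positions = list(c1 = numeric())),
               "no markers")
})
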