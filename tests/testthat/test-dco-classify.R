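test_that("strand class follows the participant overlap", {
  expect_equal(classify_dco(c(2, 3), c(2, 3)),
               tibble::tibble(strand_class = "2S", ci_score = -1L))
  expect_equal(classify_dco(c(2, 3), c(3, 4)),
               tibble::tibble(strand_class = "3S", ci_score = 0L))
  expect_equal(classify_dco(c(1, 2), c(3, 4)),
               tibble::tibble(strand_class = "4S", ci_score = 1L))
  expect_error(classify_dco(c(2, 2), c(1, 3)), "distinct")
  expect_error(classify_dco(c(2, 3), c(1, NA)), "distinct")
})

test_that("classification is symmetric and relabeling-invariant", {
  pairs <- t(combn(4, 2))
  for (i in seq_len(nrow(pairs))) {
    for (j in seq_len(nrow(pairs))) {
      a <- pairs[i, ]; b <- pairs[j, ]
      expect_equal(classify_dco(a, b), classify_dco(b, a))
      perm <- sample(4)
      expect_equal(classify_dco(perm[a], perm[b])$strand_class,
                   classify_dco(a, b)$strand_class)
    }
  }
})

test_that("equally likely chromatid choices give the 1:2:1 type ratio", {
  # first CO uses maternal product 1 and paternal product 3; the second CO
  # picks one maternal and one paternal chromatid uniformly: 4 outcomes
  outcomes <- classify_dco(
    matrix(c(1, 3), nrow = 4, ncol = 2, byrow = TRUE),
    cbind(c(1, 1, 2, 2), c(3, 4, 3, 4))
  )
  expect_equal(sort(table(outcomes$strand_class)),
               sort(c(`2S` = 1, `3S` = 2, `4S` = 1)), ignore_attr = TRUE)
  expect_equal(table(outcomes$strand_class)[["3S"]], 2)
  expect_equal(mean(outcomes$ci_score), 0)
})

test_that("consecutive pairing produces k - 1 DCOs per bivalent", {
  ev <- detect_crossovers(strings_dataset(c("AABB", "ABAA", "BAAB", "BBBA")))
  expect_equal(nrow(ev), 3)
  dc <- pair_adjacent(ev)
  expect_equal(nrow(dc), 2)
  expect_equal(dc$mid1_bp, ev$midpoint_bp[1:2])
  expect_equal(dc$mid2_bp, ev$midpoint_bp[2:3])

  one <- detect_crossovers(strings_dataset(c("AA", "AB", "BA", "BB")))
  expect_equal(nrow(pair_adjacent(one)), 0)
  expect_error(pair_adjacent(ev[c(2, 1, 3), ]), "ordered")
})

test_that("DCOs touching ambiguous same-interval COs lose their class", {
  ds <- strings_dataset(c("ABA", "ABB", "BAB", "BAA"))
  # interval m1..m2 has all four products switching (two same-interval COs)
  ev <- detect_crossovers(ds)
  expect_equal(sum(ev$ambiguous), 2)
  dc <- pair_adjacent(ev)
  expect_true(any(is.na(dc$strand_class)))
  expect_true(all(exclusions(dc)$reason == "member_co_ambiguous"))
  # every consecutive pair is still present: k COs -> k - 1 rows
  expect_equal(nrow(dc), nrow(ev) - 1)
})

test_that("inter-CO distances round to the closest Mb, half up", {
  expect_equal(inter_co_distance_mb(1.5e6, 15.5e6), 14L)
  expect_equal(inter_co_distance_mb(0, 0.4e6), 0L)
  expect_equal(inter_co_distance_mb(0, 2.5e6), 3L)
  expect_equal(inter_co_distance_mb(1e6, 2.4e6), 1L)
  expect_error(inter_co_distance_mb(2e6, 1e6), "ordered")
})

test_that("arm relation splits same-arm from centromere-spanning DCOs", {
  dc <- tibble::tibble(chromosome = "c1",
                       mid1_bp = c(2e6, 2e6, 14e6, 15e6),
                       mid2_bp = c(5e6, 20e6, 15e6, 16e6))
  cen <- tibble::tibble(chromosome = "c1", centromere_bp = 15e6)
  out <- annotate_arm_relation(dc, cen)
  expect_equal(out$arm_relation,
               c("same_arm", "spans_centromere", "spans_centromere",
                 "same_arm"))
  expect_equal(annotate_arm_relation(dc)$arm_relation, rep("unknown", 4))
  other <- annotate_arm_relation(
    dplyr::mutate(dc, chromosome = "c9"), cen)
  expect_equal(other$arm_relation, rep("unknown", 4))
})

test_that("pairing identity holds on simulated data", {
  for (seed in 1:3) {
    sim <- simulate_tetrads(n_tetrads = 15, co_lambda = 2, seed = seed)
    ev <- detect_crossovers(sim$dataset)
    dc <- pair_adjacent(ev)
    n_bivalents <- nrow(dplyr::distinct(ev, tetrad_id, chromosome))
    expect_equal(nrow(dc), nrow(ev) - n_bivalents)
    # and for the simulator truth as well
    td <- true_dco_types(sim$truth)
    n_biv_true <- nrow(dplyr::distinct(sim$truth, tetrad_id, chromosome))
    expect_equal(nrow(td), nrow(sim$truth) - n_biv_true)
  }
})
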