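#' Mean CI value of a DCO group
#'
#' Each DCO scores -1 (2S), 0 (3S) or +1 (4S); the CI value of a group is
#' the mean score, `(n4s - n2s) / (n2s + n3s + n4s)`. It ranges from -1
#' (complete negative chromatid interference: all DCOs two-strand) through 0
#' (no interference) to +1 (complete positive: all four-strand).
#'
#' @param n2s,n3s,n4s Non-negative DCO type counts (vectorised).
#' @return Numeric vector of CI values in \[-1, 1\].
#' @examples
#' ci_value(112, 178, 95)   # -17/385, prints as -0.04
#' ci_value(21, 21, 11)     # -10/53,  prints as -0.19
#' @export
ci_value <- function(n2s, n3s, n4s) {
  n <- n2s + n3s + n4s
  if (any(c(n2s, n3s, n4s) < 0)) abort("counts must be non-negative")
  if (any(n < 1)) abort("CI value is undefined for an empty DCO group")
  (n4s - n2s) / n
}

#' Chi-square goodness-of-fit test against the 1:2:1 DCO ratio
#'
#' Pearson test of observed 2S:3S:4S counts against the random-chromatid
#' expectation (n/4, n/2, n/4), df = 2, upper-tail P. No continuity
#' correction and no minimum-expected-count guard is applied — published
#' group sizes go down to n = 11 — but a warning is raised when any expected
#' count is below 5.
#'
#' @inheritParams ci_value
#' @return A tibble with columns `chi2` and `p_value`, one row per triple.
#' @examples
#' chi2_gof_121(55, 66, 48)  # chi2 8.68, P = 0.013
#' chi2_gof_121(25, 50, 25)  # exact fit: chi2 0, P = 1
#' @export
chi2_gof_121 <- function(n2s, n3s, n4s) {
  n <- n2s + n3s + n4s
  if (any(n < 1)) abort("chi-square test needs at least one DCO")
  if (any(n < 20)) {
    warn("expected count below 5 in at least one group; chi-square P-values are approximate")
  }
  res <- mapply(function(a, b, c) {
    t <- suppressWarnings(chisq.test(c(a, b, c), p = c(1, 2, 1) / 4))
    c(unname(t$statistic), t$p.value)
  }, n2s, n3s, n4s)
  tibble(chi2 = res[1, ], p_value = res[2, ])
}

#' Wilcoxon signed-rank test of CI scores against zero
#'
#' Tests whether the per-DCO scores (-1/0/+1) are centred on zero. Zeros
#' (3S DCOs) are discarded before ranking, as in the classic signed-rank
#' procedure; with only ties remaining the exact distribution is
#' unavailable, so the tie-corrected normal approximation with continuity
#' correction is used (the convention under which the published P-values
#' are reproduced). If every score is zero the test is undefined and `NA`
#' is returned.
#'
#' @param scores Vector of per-DCO CI scores in \{-1, 0, +1\}.
#' @param alternative "two.sided" (default), "less" or "greater".
#' @param correct Apply the continuity correction (default TRUE).
#' @return A single P-value, or `NA_real_` when undefined.
#' @examples
#' wilcoxon_vs_zero(rep(c(-1, 0, 1), c(12, 29, 4)), "less")  # 0.024
#' wilcoxon_vs_zero(c(0, 0, 0))                              # NA
#' @export
wilcoxon_vs_zero <- function(scores,
                             alternative = c("two.sided", "less", "greater"),
                             correct = TRUE) {
  alternative <- arg_match(alternative)
  if (length(scores) == 0) abort("`scores` must be non-empty")
  if (!all(scores %in% c(-1L, 0L, 1L))) {
    abort("`scores` must contain only -1, 0 and +1")
  }
  nz <- scores[scores != 0]
  if (length(nz) == 0) return(NA_real_)
  suppressWarnings(
    wilcox.test(nz, mu = 0, exact = FALSE, correct = correct,
                alternative = alternative)$p.value
  )
}

#' Bonferroni multiple-testing correction
#'
#' Multiplies each P-value by the family size and caps at 1. The family is
#' the number of tests performed in the same table column (e.g. one test
#' per chromosome), which may exceed the number of P-values passed in.
#'
#' @param p_values Vector of probabilities in \[0, 1\].
#' @param family Family size; defaults to `length(p_values)`.
#' @return Adjusted P-values.
#' @examples
#' bonferroni(0.024, family = 5)  # 0.12: no longer significant
#' @export
bonferroni <- function(p_values, family = length(p_values)) {
  if (any(!is.na(p_values) & (p_values < 0 | p_values > 1))) {
    abort("P-values must lie in [0, 1]")
  }
  pmin(1, p_values * family)
}

#' Summarise one DCO group
#'
#' Computes the full CI summary for a set of classified DCOs: type counts,
#' expected 1:2:1 counts, mean CI value, the chi-square goodness-of-fit test
#' and the Wilcoxon signed-rank test. DCOs with `NA` strand class (dropped
#' as ambiguous) are ignored; an empty group yields a zero-row tibble with
#' a warning rather than an error.
#'
#' @param dcos DCO tibble from [pair_adjacent()] (needs `strand_class`).
#' @param group Label for the group (default "all").
#' @param alternative Sidedness for the Wilcoxon test.
#' @return A one-row tibble: `group`, `n_dco`, `n2s`, `n3s`, `n4s`,
#'   `exp_2s`, `exp_3s`, `exp_4s`, `ci_value`, `chi2`, `chi2_p`,
#'   `wilcoxon_p`, `p_adjusted` (`NA`; filled by [ci_summary()]).
#' @export
summarize_group <- function(dcos, group = "all", alternative = "two.sided") {
  dcos <- as_tibble(dcos) %>% filter(!is.na(.data$strand_class))
  if (nrow(dcos) == 0) {
    warn(paste0("group '", group, "' contains no classified DCOs; skipped"))
    return(summarize_counts(integer(), integer(), integer()))
  }
  summarize_counts(sum(dcos$strand_class == "2S"),
                   sum(dcos$strand_class == "3S"),
                   sum(dcos$strand_class == "4S"),
                   group = group, alternative = alternative)
}

#' Summarise DCO groups given as type-count triples
#'
#' Same summary as [summarize_group()] but starting from 2S/3S/4S counts
#' (e.g. a published table) instead of per-DCO records. Vectorised over
#' triples.
#'
#' @param n2s,n3s,n4s DCO type counts.
#' @param group Group labels (recycled).
#' @param alternative Sidedness for the Wilcoxon test.
#' @return A tibble, one row per triple (see [summarize_group()]).
#' @examples
#' summarize_counts(112, 178, 95, group = "genome")
#' @export
summarize_counts <- function(n2s, n3s, n4s, group = "all",
                             alternative = "two.sided") {
  if (length(n2s) == 0) {
    return(tibble(
      group = character(), n_dco = integer(), n2s = integer(),
      n3s = integer(), n4s = integer(), exp_2s = numeric(),
      exp_3s = numeric(), exp_4s = numeric(), ci_value = numeric(),
      chi2 = numeric(), chi2_p = numeric(), wilcoxon_p = numeric(),
      p_adjusted = numeric()
    ))
  }
  n <- n2s + n3s + n4s
  chi <- suppressWarnings(chi2_gof_121(n2s, n3s, n4s))
  wil <- purrr::pmap_dbl(list(n2s, n3s, n4s), function(a, b, c) {
    wilcoxon_vs_zero(rep(c(-1L, 0L, 1L), c(a, b, c)),
                     alternative = alternative)
  })
  tibble(
    group = rep_len(as.character(group), length(n)),
    n_dco = as.integer(n), n2s = as.integer(n2s), n3s = as.integer(n3s),
    n4s = as.integer(n4s),
    exp_2s = n / 4, exp_3s = n / 2, exp_4s = n / 4,
    ci_value = ci_value(n2s, n3s, n4s),
    chi2 = chi$chi2, chi2_p = chi$p_value,
    wilcoxon_p = wil, p_adjusted = NA_real_
  )
}

#' CI summaries over standard partitions of a DCO set
#'
#' Summarises classified DCOs genome-wide, per chromosome, by arm relation
#' (same arm vs centromere-spanning), or per chromosome within each arm
#' relation. For chromosome-level partitions the Wilcoxon P-values receive
#' a Bonferroni penalty with family size equal to the number of chromosome
#' tests in the same column (`p_adjusted`).
#'
#' @param dcos DCO tibble from [pair_adjacent()].
#' @param partition One of "genome", "chromosome", "arm", "chromosome_arm".
#' @param alternative Sidedness for the Wilcoxon test.
#' @return A tibble with one row per group (see [summarize_group()]), plus
#'   the partition columns.
#' @export
ci_summary <- function(dcos,
                       partition = c("genome", "chromosome", "arm",
                                     "chromosome_arm"),
                       alternative = "two.sided") {
  partition <- arg_match(partition)
  dcos <- as_tibble(dcos) %>% filter(!is.na(.data$strand_class))
  if (partition %in% c("arm", "chromosome_arm") &&
      !"arm_relation" %in% names(dcos)) {
    abort("partition by arm requires an `arm_relation` column (see annotate_arm_relation)")
  }
  keys <- switch(partition,
    genome = character(),
    chromosome = "chromosome",
    arm = "arm_relation",
    chromosome_arm = c("chromosome", "arm_relation")
  )
  counts <- dcos %>%
    group_by(across(all_of(keys))) %>%
    summarise(n2s = sum(.data$strand_class == "2S"),
              n3s = sum(.data$strand_class == "3S"),
              n4s = sum(.data$strand_class == "4S"),
              .groups = "drop")
  empty <- counts$n2s + counts$n3s + counts$n4s < 1
  if (any(empty)) {
    warn("dropping group(s) with no classified DCOs")
    counts <- counts[!empty, ]
  }
  label <- if (length(keys) == 0) {
    "genome"
  } else {
    do.call(paste, c(unname(as.list(counts[keys])), sep = "/"))
  }
  out <- summarize_counts(counts$n2s, counts$n3s, counts$n4s,
                          group = label, alternative = alternative)
  res <- dplyr::bind_cols(counts[keys], out)
  if ("chromosome" %in% keys) {
    fam_keys <- setdiff(keys, "chromosome")
    res <- res %>%
      group_by(across(all_of(fam_keys))) %>%
      mutate(p_adjusted = bonferroni(.data$wilcoxon_p, family = n())) %>%
      ungroup()
  } else {
    res$p_adjusted <- bonferroni(res$wilcoxon_p, family = 1)
  }
  res
}
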