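---
title: "Quantifying chromatid interference from tetrad genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying chromatid interference from tetrad genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
```

```{r setup, message = FALSE}
library(tetradci)
library(dplyr)
```

## The problem

A meiotic bivalent carries four chromatids: two maternal sisters and two
paternal sisters. Every crossover (CO) joins one maternal and one paternal
chromatid. When two adjacent COs occur on the same bivalent — a double
crossover (DCO) — the pair of chromatids used by the second CO may coincide
with the first CO's pair in both members (a two-strand DCO, 2S), in one
member (three-strand, 3S) or in neither (four-strand, 4S). If the chromatid
choice of the second CO is independent of the first, the three classes occur
in a 1:2:1 ratio. *Chromatid interference* (CI) is any departure from that
ratio: negative CI enriches 2S DCOs, positive CI enriches 4S DCOs. CI
matters beyond meiosis mechanics: genetic mapping functions assume its
absence, and negative CI biases genetic distances downward for well-separated
loci.

Tetrad data — the genotypes of all four products of a single meiosis — make
the chromatid assignment of every CO observable, so CI can be measured
directly.

## The CI value

Classically CI is assessed only by a goodness-of-fit test of the 2S:3S:4S
counts against 1:2:1, which gives a verdict but not a magnitude or
direction. This package also computes a signed summary statistic. Each
chromatid of the first CO contributes +0.5 if it is *not* reused by the
second CO and −0.5 if it is; summing over the first CO's two chromatids
scores a 2S DCO as −1, a 3S as 0 and a 4S as +1. The **CI value** of a
group of DCOs is the mean score,

$$\mathrm{CI} = \frac{n_{4S} - n_{2S}}{n_{2S} + n_{3S} + n_{4S}} \in [-1, 1],$$

with −1 complete negative CI (all 2S), 0 no CI and +1 complete positive CI
(all 4S). Under the 1:2:1 null its expectation is 0, so the statistic can be
tested against zero directly.

## Pipeline

The package is organised as a pipe-friendly tabular pipeline:

1. `read_tetrad_table()` / `tetrad_dataset()` — validate long-form tetrad
   genotypes against a marker map. Fully-called marker columns must
   segregate 2 A : 2 B; violating columns (putative gene conversions or
   genotyping errors) are flagged and withheld from detection but kept in
   the data.
2. `detect_crossovers()` — a CO is a complementary allele transition (one
   A→B and one B→A) in exactly two products between adjacent informative
   markers. Its position is the midpoint of the flanking markers, kept
   fractional. Intervals in which all four products switch carry two
   same-interval COs whose pairing marker data cannot resolve; both events
   are emitted flagged `ambiguous` and logged, never silently dropped.
3. `pair_adjacent()` — consecutive COs of a bivalent form DCOs (k COs give
   k − 1 DCOs), classified by participant overlap (`classify_dco()`),
   annotated with integer-Mb distance and centromere relation. DCOs
   touching ambiguous COs keep their row but lose their class, with a
   logged reason, so the pairing identity
   `n_DCO = n_CO − n_bivalents_with_a_CO` always holds on the full table.
4. `ci_summary()` — per group: counts, CI value, the χ² goodness-of-fit test
   against (n/4, n/2, n/4) and the Wilcoxon signed-rank test of the scores
   against zero, with a Bonferroni penalty across chromosome-level tests.
5. `bin_by_distance()` + `fit_ci_distance()` — CI as a function of physical
   inter-CO distance, fitted by weighted least squares with per-bin DCO
   counts as weights.

```{r example}
sim <- simulate_tetrads(n_tetrads = 120, strand_bias_r = 0.65, seed = 42)
dcos <- sim$dataset |>
  detect_crossovers() |>
  pair_adjacent(centromeres = sim$dataset$centromeres)
ci_summary(dcos, partition = "genome")
```

The simulated reuse probability 0.65 implies an expected CI value of
1 − 2 × 0.65 = −0.3; the genome-wide estimate above recovers it within
sampling error, and `true_ci(sim$truth)` gives the exact simulated value.

## Statistical conventions

* **χ² test**: Pearson statistic, df = 2, upper tail, no continuity
  correction and no minimum-count guard — published groups go down to
  n = 11, and the printed P-values (e.g. 0.013 for 55:66:48) are reproduced
  only without a guard. A warning notes expected counts below 5.
* **Wilcoxon signed-rank test**: zeros (3S DCOs) are discarded before
  ranking; with only ±1 scores left the exact distribution is unavailable,
  so the tie-corrected normal approximation with continuity correction is
  used. This is the convention under which the published one-sided values
  (0.024, 0.039, 0.021) are reproduced; the package default is two-sided,
  with `alternative` exposed, since the sidedness of reported values is a
  reporting choice rather than a property of the data.
* **Bonferroni**: the family is the number of chromosome-level tests in the
  same table column (5 for Arabidopsis, 10 for maize), passed as `family`,
  which may exceed the number of P-values at hand.
* **Display rounding** (`format_ci_value()`): CI values are rounded half-up
  to 3 decimals and shown at 2; values that would display as 0.00 are shown
  at 3 decimals ("−0.003") and exact zero as "0". The three-then-two step
  mirrors the reference tables, which evidently report from a 3-decimal
  working precision (their genome-wide maize entry is printed at 3
  decimals, and one same-arm cell is explained only by this path).
* **Rounding of distances**: "closest Mb" is ambiguous at .5; `round_half_up()`
  (half away from zero) is used and documented rather than banker's
  rounding.
* **Centromere boundary**: a DCO spans the centromere iff
  `mid1 < centromere ≤ mid2`. The equality case has probability zero in
  practice but is fixed for determinism.

## The simulator

`simulate_tetrads()` provides truth-labelled data for every stage. Its
generative model: per bivalent, a CO count from a Poisson distribution
(zero-truncated when `obligate = TRUE`, the default, reflecting the obligate
CO); CO positions uniform along the chromosome (no CO interference — CI,
not CO placement, is the object of study; a clustering option was
deliberately left out to keep the truth law closed-form); and a one-knob
chromatid-choice model: each CO reuses the previous CO's maternal chromatid
with probability `r = strand_bias_r` and, independently, its paternal
chromatid with probability `r`. That yields

$$P(2S) = r^2,\quad P(3S) = 2r(1-r),\quad P(4S) = (1-r)^2,
\qquad E[\mathrm{CI}] = 1 - 2r,$$

so `r = 0.5` is the no-CI null and the ends of the range give complete
negative (r = 1) and complete positive (r = 0) CI. Genotypes are derived by
tracing the four products through the ordered exchanges, which guarantees
2:2 segregation at every marker before noise; allele flips and missing
calls are injected last, independently per call.

Defaults emulate the Arabidopsis study conditions: 58 tetrads, five
chromosomes with Arabidopsis-like lengths and centromeres, markers every
500 kb, and `co_lambda = 1.4` (with the obligate rule, ≈1.86 COs per
bivalent, close to the 843 COs over 460 scorable bivalents of the PCR-marker
dataset), `r = 0.5`, no noise.

What the simulator does **not** emulate: CO interference (positions are
uniform, real inter-CO distances are overdispersed away from zero),
recombination landscapes (no telomeric skew), sister-chromatid exchange
(suppressed in meiosis), and structured genotyping error (errors are
independent flips). Passing tests on simulated data therefore validate the
detection/classification/statistics machinery, not the biological realism
of any particular dataset.

## Degenerate and edge inputs

* Markers with any missing call in a tetrad are skipped for that tetrad;
  detection bridges across them, so a CO is still found with wider flanking
  markers.
* A group with no classified DCOs is skipped with a warning, not an error;
  an all-zero score vector makes the Wilcoxon test undefined (`NA`).
* `fit_ci_distance()` requires two distinct occupied distances; empty bins
  are omitted rather than zero-filled since their regression weight would
  be zero.
* Same-interval CO pairs can also be *invisible* (both exchanges between
  the same two chromatids cancel at the markers) or appear as three-product
  changes (shared chromatid); the first is undetectable in principle from
  marker data, the second is excluded and logged.

## Problem sizes used in the checks

The package's own validation runs: exact fixtures from the published count
tables (every populated CI cell of both tables, instantaneous); a
pairing-identity sweep over
1,000 small simulated datasets; an oracle-equivalence run of >10⁴ DCOs
under dense markers and no noise (zero class mismatches required); a bias
sweep r ∈ {0.1, 0.25, 0.5, 0.75, 0.9} with >10⁴ DCOs per setting (estimates
within 4 standard errors of 1 − 2r); and a 10,000-replicate calibration of
the χ² test at n = 100 DCOs per group. These sizes keep the full suite
within a few minutes on one core while leaving Monte-Carlo error well below
the tested tolerances.

## Known limitations

* CO detection is midpoint-based; no refinement of CO position within the
  flanking interval is attempted, so Mb binning inherits marker resolution.
* The published regression coefficients for the real datasets cannot be
  re-derived without the original genotype deposits; the estimator is
  instead verified exactly against the closed-form weighted normal
  equations, and the shipped count tables cover all count-level statistics.
* Triple-and-higher CO chains are analysed only through their consecutive
  pairs; joint higher-order chromatid-choice patterns are out of scope.
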