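#' Arabidopsis-like genome layout for simulation
#'
#' Five chromosomes with lengths and centromere positions close to the
#' Arabidopsis thaliana nuclear genome, the organism of the reference
#' tetrad datasets. Used as the default genome of [simulate_tetrads()].
#'
#' @return A tibble with `chromosome`, `length_bp`, `centromere_bp`.
#' @export
sim_genome_arabidopsis <- function() {
  tibble(
    chromosome = paste0("chr", 1:5),
    length_bp = c(30.4e6, 19.7e6, 23.5e6, 18.6e6, 27.0e6),
    centromere_bp = c(15.1e6, 3.6e6, 13.8e6, 4.0e6, 11.2e6)
  )
}

#' Simulate tetrad genotype data with known chromatid choices
#'
#' Generates a fully synthetic, truth-labelled tetrad dataset under an
#' explicit model of meiotic recombination on a bivalent of four chromatids
#' (maternal strands 1-2 carrying allele "A", paternal strands 3-4 carrying
#' allele "B"):
#'
#' 1. Per tetrad and chromosome, the CO count is Poisson(`co_lambda`),
#'    zero-truncated when `obligate = TRUE` so every bivalent receives at
#'    least one CO (the obligate-CO rule).
#' 2. CO positions are uniform on the chromosome (no CO interference) and
#'    sorted.
#' 3. Each CO involves one maternal and one paternal strand. The first CO
#'    picks both uniformly; every subsequent CO reuses the previous CO's
#'    maternal strand with probability `strand_bias_r` and, independently,
#'    its paternal strand with probability `strand_bias_r`. This one-knob
#'    Markov model gives DCO type probabilities P(2S) = r^2,
#'    P(3S) = 2r(1-r), P(4S) = (1-r)^2 and hence an expected CI value of
#'    1 - 2r: r = 0.5 is the random 1:2:1 null, r = 1 complete negative CI,
#'    r = 0 complete positive CI.
#' 4. Product genotypes are obtained by tracing each chromatid through the
#'    ordered exchanges; every marker column therefore segregates 2:2
#'    before noise. Genotyping errors (allele flips) and missing calls are
#'    injected independently per call, last.
#'
#' Sister-chromatid exchange is not modelled (it is suppressed in meiosis).
#'
#' @param n_tetrads Number of tetrads (default 58, the size of the classic
#'   Arabidopsis marker dataset).
#' @param genome Tibble with `chromosome`, `length_bp` and optionally
#'   `centromere_bp`; defaults to [sim_genome_arabidopsis()].
#' @param marker_spacing Distance between evenly spaced markers in bp
#'   (default 5e5), ignored when `marker_positions` is given.
#' @param marker_positions Optional named list of marker position vectors,
#'   one per chromosome.
#' @param co_lambda Poisson rate of the CO count per bivalent (default 1.4,
#'   which with the obligate rule gives ~1.86 COs per bivalent, matching
#'   the per-bivalent CO average of the Arabidopsis reference data).
#' @param obligate Require at least one CO per bivalent (default TRUE).
#' @param strand_bias_r Chromatid reuse probability in \[0, 1\]
#'   (default 0.5, no chromatid interference).
#' @param genotyping_error_rate,missing_rate Per-call probabilities in
#'   \[0, 1) of an allele flip / a missing call (defaults 0).
#' @param seed Optional integer seed; identical configuration and seed give
#'   identical output.
#' @return A `tetrad_sim` list: `dataset` (a [tetrad_dataset()]), `truth`
#'   (one row per true CO: `tetrad_id`, `chromosome`, `co_index`,
#'   `position_bp`, `mat_strand`, `pat_strand`) and `config`.
#' @seealso [true_dco_types()], [true_ci()] for the simulator ground truth;
#'   [detect_crossovers()] for recovering the COs from the genotypes.
#' @examples
#' sim <- simulate_tetrads(n_tetrads = 5, seed = 1)
#' sim$dataset
#' head(sim$truth)
#' @export
simulate_tetrads <- function(n_tetrads = 58,
                             genome = sim_genome_arabidopsis(),
                             marker_spacing = 5e5,
                             marker_positions = NULL,
                             co_lambda = 1.4,
                             obligate = TRUE,
                             strand_bias_r = 0.5,
                             genotyping_error_rate = 0,
                             missing_rate = 0,
                             seed = NULL) {
  genome <- as_tibble(genome)
  check_columns(genome, c("chromosome", "length_bp"), "genome")
  if (n_tetrads < 1) abort("`n_tetrads` must be at least 1")
  if (strand_bias_r < 0 || strand_bias_r > 1) {
    abort("`strand_bias_r` must lie in [0, 1]")
  }
  if (genotyping_error_rate < 0 || genotyping_error_rate >= 1 ||
      missing_rate < 0 || missing_rate >= 1) {
    abort("error and missing rates must lie in [0, 1)")
  }
  if (!is.null(seed)) set.seed(seed)

  tetrad_ids <- sprintf("T%04d", seq_len(n_tetrads))
  geno_parts <- vector("list", nrow(genome))
  marker_parts <- vector("list", nrow(genome))
  truth_parts <- vector("list", nrow(genome))

  for (ci in seq_len(nrow(genome))) {
    chrom <- genome$chromosome[ci]
    len <- genome$length_bp[ci]
    mpos <- if (!is.null(marker_positions)) {
      sort(marker_positions[[chrom]])
    } else {
      seq(marker_spacing, len, by = marker_spacing)
    }
    if (length(mpos) == 0) {
      abort(paste0("no markers on chromosome ", chrom))
    }
    mnames <- sprintf("%s_m%04d", chrom, seq_along(mpos))
    sim <- sim_one_chromosome(n_tetrads, len, mpos, co_lambda, obligate,
                              strand_bias_r)

    alleles <- sim$alleles
    n_calls <- length(alleles)
    if (genotyping_error_rate > 0) {
      flip <- runif(n_calls) < genotyping_error_rate
      alleles[flip] <- ifelse(alleles[flip] == "A", "B", "A")
    }
    if (missing_rate > 0) {
      alleles[runif(n_calls) < missing_rate] <- NA_character_
    }

    m <- length(mpos)
    geno_parts[[ci]] <- tibble(
      tetrad_id = rep(rep(tetrad_ids, each = 4L), times = m),
      product_id = rep(rep(1:4, n_tetrads), times = m),
      chromosome = chrom,
      marker = rep(mnames, each = 4L * n_tetrads),
      allele = as.vector(alleles)
    )
    marker_parts[[ci]] <- tibble(chromosome = chrom, marker = mnames,
                                 position_bp = mpos)
    truth_parts[[ci]] <- sim$truth %>%
      mutate(tetrad_id = tetrad_ids[.data$tetrad], chromosome = chrom) %>%
      select("tetrad_id", "chromosome", "co_index", "position_bp",
             "mat_strand", "pat_strand")
  }

  centromeres <- if ("centromere_bp" %in% names(genome)) {
    genome %>% select("chromosome", "centromere_bp")
  }
  dataset <- tetrad_dataset(
    bind_rows(geno_parts), bind_rows(marker_parts), centromeres,
    provenance = sprintf("simulated (r = %g, lambda = %g, seed = %s)",
                         strand_bias_r, co_lambda,
                         if (is.null(seed)) "none" else seed)
  )
  structure(
    list(dataset = dataset, truth = bind_rows(truth_parts),
         config = list(n_tetrads = n_tetrads, genome = genome,
                       marker_spacing = marker_spacing,
                       co_lambda = co_lambda, obligate = obligate,
                       strand_bias_r = strand_bias_r,
                       genotyping_error_rate = genotyping_error_rate,
                       missing_rate = missing_rate, seed = seed)),
    class = "tetrad_sim"
  )
}

#' @export
print.tetrad_sim <- function(x, ...) {
  cat("<tetrad_sim> r = ", x$config$strand_bias_r, ", ",
      nrow(x$truth), " true COs\n", sep = "")
  print(x$dataset)
  invisible(x)
}

# Simulate one chromosome for all tetrads. Returns the 4*n_tetrads x M
# allele matrix (rows: tetrad-major, product-minor) and the CO truth table.
sim_one_chromosome <- function(n_tetrads, len, mpos, co_lambda, obligate,
                               r) {
  n_co <- if (obligate) {
    qpois(runif(n_tetrads, ppois(0, co_lambda), 1), co_lambda)
  } else {
    rpois(n_tetrads, co_lambda)
  }
  k <- sum(n_co)
  tet <- rep(seq_len(n_tetrads), n_co)
  pos <- runif(k) * len
  ord <- order(tet, pos)
  tet <- tet[ord]; pos <- pos[ord]
  first <- !duplicated(tet)

  # strand choice: first CO uniform; later COs flip the previous maternal
  # (resp. paternal) strand with probability 1 - r, independently
  draw_strands <- function() {
    bits <- as.integer(runif(k) >= r)        # 1 = flip relative to previous
    bits[first] <- as.integer(runif(sum(first)) < 0.5)
    cs <- cumsum(bits)
    offset <- rep(cs[first] - bits[first], n_co[n_co > 0])
    ((cs - offset) %% 2L) + 1L
  }
  mat_strand <- draw_strands()
  pat_strand <- draw_strands()

  m <- length(mpos)
  # segment index of each marker: markers strictly beyond a CO position
  # feel that exchange
  alleles <- matrix(NA_character_, nrow = 4L * n_tetrads, ncol = m)
  letter <- c("A", "A", "B", "B")
  pos_by_tet <- split(seq_len(k), tet)
  for (t in seq_len(n_tetrads)) {
    ids <- pos_by_tet[[as.character(t)]]
    rows <- (t - 1L) * 4L + 1:4
    kk <- length(ids)
    if (is.null(ids) || kk == 0L) {
      alleles[rows, ] <- letter
      next
    }
    # occupancy of the four products across the kk + 1 segments
    occ <- matrix(0L, 4L, kk + 1L)
    cur <- 1:4
    occ[, 1L] <- cur
    for (j in seq_len(kk)) {
      s1 <- mat_strand[ids[j]]
      s2 <- 2L + pat_strand[ids[j]]
      i1 <- which(cur == s1); i2 <- which(cur == s2)
      cur[c(i1, i2)] <- cur[c(i2, i1)]
      occ[, j + 1L] <- cur
    }
    seg <- findInterval(mpos, pos[ids]) + 1L
    alleles[rows, ] <- letter[occ[, seg]]
  }

  truth <- tibble(
    tetrad = tet,
    co_index = stats::ave(tet, tet, FUN = seq_along),
    position_bp = pos,
    mat_strand = mat_strand,
    pat_strand = pat_strand
  )
  list(alleles = alleles, truth = truth)
}

#' Derive true DCO types from simulator ground truth
#'
#' Recomputes, from the recorded chromatid pair of every simulated CO, the
#' strand class of each consecutive CO pair: shared maternal and paternal
#' strand — 2S; one shared — 3S; none — 4S.
#'
#' @param truth Truth tibble from [simulate_tetrads()].
#' @return A tibble with one row per true DCO: `tetrad_id`, `chromosome`,
#'   `co_index` (of the first CO), `position1_bp`, `position2_bp`,
#'   `strand_class`, `ci_score`.
#' @export
true_dco_types <- function(truth) {
  truth <- as_tibble(truth)
  check_columns(truth, c("tetrad_id", "chromosome", "position_bp",
                         "mat_strand", "pat_strand"), "truth")
  truth %>%
    arrange(.data$tetrad_id, .data$chromosome, .data$position_bp) %>%
    group_by(.data$tetrad_id, .data$chromosome) %>%
    mutate(shared = (.data$mat_strand == lag(.data$mat_strand)) +
             (.data$pat_strand == lag(.data$pat_strand)),
           position1_bp = lag(.data$position_bp)) %>%
    ungroup() %>%
    filter(!is.na(.data$shared)) %>%
    mutate(strand_class = c("4S", "3S", "2S")[.data$shared + 1L],
           ci_score = 1L - as.integer(.data$shared),
           co_index = .data$co_index - 1L) %>%
    select("tetrad_id", "chromosome", "co_index",
           "position1_bp", position2_bp = "position_bp",
           "strand_class", "ci_score")
}

#' True mean CI value of a simulation
#'
#' Mean CI score over the true DCOs of a simulator run — the oracle the
#' detection pipeline's estimate is compared against. With many DCOs it
#' approaches the closed form `1 - 2r` of the strand-choice model.
#'
#' @param truth Truth tibble from [simulate_tetrads()].
#' @return Mean CI value, or `NA_real_` when the truth contains no DCO.
#' @export
true_ci <- function(truth) {
  types <- true_dco_types(truth)
  if (nrow(types) == 0) return(NA_real_)
  mean(types$ci_score)
}
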