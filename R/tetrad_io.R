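#' Assemble and validate a tetrad dataset
#'
#' Bundles long-form tetrad genotypes with a marker map (and optional
#' centromere positions) into a validated `tetrad_dataset`. Validation
#' enforces the tetrad structure — exactly four meiotic products per tetrad
#' per chromosome, every marker known to the map with a consistent physical
#' position, strictly increasing marker positions — and flags marker columns
#' whose called alleles violate 2:2 segregation (possible gene conversion or
#' genotyping error). Flagged columns are retained in the data, never
#' dropped; downstream crossover detection skips them.
#'
#' @param genotypes Tibble with columns `tetrad_id`, `product_id` (1-4),
#'   `chromosome`, `marker`, `allele` ("A", "B" or `NA`) and optionally
#'   `position_bp`.
#' @param markers Tibble with columns `chromosome`, `marker`, `position_bp`
#'   (1-based base pairs, strictly increasing within a chromosome).
#' @param centromeres Optional tibble with columns `chromosome`,
#'   `centromere_bp`.
#' @param provenance Free-text description of where the data came from.
#' @return A `tetrad_dataset`: a list with elements `genotypes`, `markers`,
#'   `centromeres`, `anomalies` (flagged marker columns) and `provenance`.
#' @seealso [read_tetrad_table()] to build one from TSV files,
#'   [detect_crossovers()] for the next pipeline stage.
#' @export
tetrad_dataset <- function(genotypes, markers, centromeres = NULL,
                           provenance = "") {
  genotypes <- as_tibble(genotypes)
  markers <- as_tibble(markers)
  check_columns(genotypes, c("tetrad_id", "product_id", "chromosome",
                             "marker", "allele"), "genotypes")
  check_columns(markers, c("chromosome", "marker", "position_bp"),
                "marker map")

  markers <- markers %>%
    mutate(chromosome = as.character(.data$chromosome),
           marker = as.character(.data$marker),
           position_bp = as.numeric(.data$position_bp)) %>%
    arrange(.data$chromosome, .data$position_bp)
  bad_pos <- markers %>%
    group_by(.data$chromosome) %>%
    filter(duplicated(.data$position_bp) | .data$position_bp < 1) %>%
    ungroup()
  if (nrow(bad_pos) > 0) {
    abort(paste0("marker positions must be >= 1 bp and strictly increasing; ",
                 "offending chromosome(s): ",
                 paste(unique(bad_pos$chromosome), collapse = ", ")))
  }

  genotypes <- genotypes %>%
    mutate(tetrad_id = as.character(.data$tetrad_id),
           product_id = as.integer(.data$product_id),
           chromosome = as.character(.data$chromosome),
           marker = as.character(.data$marker),
           allele = as.character(.data$allele))
  bad_allele <- setdiff(unique(genotypes$allele), c("A", "B", NA))
  if (length(bad_allele) > 0) {
    abort(paste0("alleles must be 'A', 'B' or NA; found: ",
                 paste(bad_allele, collapse = ", ")))
  }

  # every genotype row must reference a mapped marker, at the mapped position
  unknown <- genotypes %>%
    dplyr::anti_join(markers, by = c("chromosome", "marker"))
  if (nrow(unknown) > 0) {
    abort(paste0("genotypes reference marker(s) absent from the map: ",
                 paste(unique(paste0(unknown$chromosome, ":", unknown$marker)),
                       collapse = ", ")))
  }
  if ("position_bp" %in% names(genotypes)) {
    clash <- genotypes %>%
      left_join(markers, by = c("chromosome", "marker"),
                suffix = c("", ".map")) %>%
      filter(!is.na(.data$position_bp),
             .data$position_bp != .data$position_bp.map)
    if (nrow(clash) > 0) {
      abort(paste0("genotype positions disagree with the marker map for: ",
                   paste(unique(paste0(clash$chromosome, ":", clash$marker)),
                         collapse = ", ")))
    }
    genotypes$position_bp <- NULL
  }

  if (vctrs::vec_duplicate_any(
        genotypes[c("tetrad_id", "product_id", "chromosome", "marker")])) {
    abort("duplicated genotype call(s) for the same tetrad/product/marker")
  }

  n_products <- genotypes %>%
    distinct(.data$tetrad_id, .data$chromosome, .data$product_id) %>%
    dplyr::count(.data$tetrad_id, .data$chromosome)
  if (any(n_products$n != 4L) ||
      !all(genotypes$product_id %in% 1:4)) {
    off <- n_products %>% filter(.data$n != 4L)
    abort(paste0("each tetrad must have exactly 4 products (ids 1-4) per ",
                 "chromosome; offending tetrad(s): ",
                 paste(utils::head(unique(off$tetrad_id), 5), collapse = ", ")))
  }

  # complete the product x marker grid with missing calls so that column
  # counts always match the marker map
  grid <- genotypes %>%
    distinct(.data$tetrad_id, .data$chromosome) %>%
    left_join(markers, by = "chromosome", relationship = "many-to-many") %>%
    tidyr::crossing(product_id = 1:4) %>%
    select("tetrad_id", "chromosome", "marker", "product_id")
  genotypes <- grid %>%
    left_join(genotypes,
              by = c("tetrad_id", "chromosome", "marker", "product_id")) %>%
    left_join(markers, by = c("chromosome", "marker")) %>%
    select("tetrad_id", "product_id", "chromosome", "marker",
           "position_bp", "allele") %>%
    arrange(.data$tetrad_id, .data$chromosome, .data$position_bp,
            .data$product_id)

  wide <- genotypes %>%
    tidyr::pivot_wider(names_from = "product_id", values_from = "allele",
                       names_prefix = "p")
  al <- as.matrix(wide[, c("p1", "p2", "p3", "p4")])
  anomalous <- rowSums(!is.na(al)) == 4L & rowSums(al == "A", na.rm = TRUE) != 2L
  anomalies <- wide[anomalous, c("tetrad_id", "chromosome", "marker",
                                 "position_bp")]

  if (!is.null(centromeres)) {
    centromeres <- as_tibble(centromeres)
    check_columns(centromeres, c("chromosome", "centromere_bp"),
                  "centromere table")
    centromeres <- centromeres %>%
      mutate(chromosome = as.character(.data$chromosome),
             centromere_bp = as.numeric(.data$centromere_bp))
  }

  structure(
    list(genotypes = genotypes, markers = markers,
         centromeres = centromeres, anomalies = anomalies,
         provenance = provenance),
    class = "tetrad_dataset"
  )
}

#' @export
print.tetrad_dataset <- function(x, ...) {
  n_tet <- dplyr::n_distinct(x$genotypes$tetrad_id)
  n_chr <- dplyr::n_distinct(x$markers$chromosome)
  cat("<tetrad_dataset> ", n_tet, " tetrad(s), ", n_chr, " chromosome(s), ",
      nrow(x$markers), " markers\n", sep = "")
  if (nrow(x$anomalies) > 0) {
    cat("  ", nrow(x$anomalies),
        " marker column(s) flagged as segregation anomalies\n", sep = "")
  }
  if (!is.null(x$centromeres)) cat("  centromere positions configured\n")
  if (nzchar(x$provenance)) cat("  provenance: ", x$provenance, "\n", sep = "")
  invisible(x)
}

#' Read a tetrad genotype table and marker map from TSV files
#'
#' The genotype file is long-form TSV with header columns `tetrad_id`,
#' `product_id` (1-4), `chromosome`, `marker`, `position_bp`, `allele`
#' ("A", "B" or NA). The marker map TSV has columns `chromosome`, `marker`,
#' `position_bp`; the optional centromere TSV has `chromosome`,
#' `centromere_bp`.
#'
#' @param path Path to the genotype TSV.
#' @param map_path Path to the marker map TSV.
#' @param centromere_path Optional path to a centromere TSV.
#' @return A validated [tetrad_dataset()].
#' @export
read_tetrad_table <- function(path, map_path, centromere_path = NULL) {
  genotypes <- read_tsv_strict(
    path, c("tetrad_id", "product_id", "chromosome", "marker", "allele"),
    readr::cols(tetrad_id = "c", product_id = "i", chromosome = "c",
                marker = "c", position_bp = "d", allele = "c"))
  markers <- read_tsv_strict(
    map_path, c("chromosome", "marker", "position_bp"),
    readr::cols(chromosome = "c", marker = "c", position_bp = "d"))
  centromeres <- if (!is.null(centromere_path)) {
    read_tsv_strict(centromere_path, c("chromosome", "centromere_bp"),
                    readr::cols(chromosome = "c", centromere_bp = "d"))
  }
  tetrad_dataset(genotypes, markers, centromeres,
                 provenance = paste0("read from ", path))
}

read_tsv_strict <- function(path, required, col_types = NULL) {
  if (!file.exists(path)) abort(paste0("file not found: ", path))
  df <- suppressWarnings(
    readr::read_tsv(path, show_col_types = FALSE, col_types = col_types,
                    na = c("", "NA"), progress = FALSE)
  )
  probs <- readr::problems(df)
  if (nrow(probs) > 0) {
    abort(paste0("malformed row in ", path, " at line ", probs$row[1],
                 ": ", probs$expected[1], " expected, got ",
                 probs$actual[1]))
  }
  check_columns(df, required, path)
  df
}

#' Write / read a CI summary table
#'
#' Serialises the output of [ci_summary()] as TSV with one row per DCO group:
#' observed type counts, expected 1:2:1 counts, the mean CI value and both
#' test P-values (raw and Bonferroni-adjusted). `read_summary_table()` reads
#' the same layout back.
#'
#' @param summaries Tibble as returned by [ci_summary()]; must be non-empty.
#' @param path Output file path.
#' @return `write_summary_table()` returns `path` invisibly;
#'   `read_summary_table()` returns the summary tibble.
#' @export
write_summary_table <- function(summaries, path) {
  summaries <- as_tibble(summaries)
  if (nrow(summaries) == 0) abort("no summaries to write")
  check_columns(summaries,
                c("group", "n_dco", "n2s", "n3s", "n4s", "ci_value",
                  "chi2", "chi2_p", "wilcoxon_p", "p_adjusted"),
                "summary table")
  out <- summaries %>%
    mutate(expected_counts = paste(.data$n_dco / 4, .data$n_dco / 2,
                                   .data$n_dco / 4, sep = ":")) %>%
    select("group", "n_dco", "n2s", "n3s", "n4s", "expected_counts",
           "ci_value", "chi2", "chi2_p", "wilcoxon_p", "p_adjusted")
  readr::write_tsv(out, path)
  invisible(path)
}

#' @rdname write_summary_table
#' @export
read_summary_table <- function(path) {
  read_tsv_strict(path, c("group", "n_dco", "n2s", "n3s", "n4s",
                          "expected_counts", "ci_value", "chi2", "chi2_p",
                          "wilcoxon_p", "p_adjusted"))
}

#' Write a tetrad dataset to TSV files
#'
#' Inverse of [read_tetrad_table()]: writes the long-form genotype table and
#' marker map (and centromere table when present) so that reading them back
#' reproduces the dataset.
#'
#' @param dataset A [tetrad_dataset()].
#' @param path Genotype TSV path.
#' @param map_path Marker map TSV path.
#' @param centromere_path Optional centromere TSV path.
#' @return `path`, invisibly.
#' @export
write_tetrad_table <- function(dataset, path, map_path,
                               centromere_path = NULL) {
  stopifnot(inherits(dataset, "tetrad_dataset"))
  readr::write_tsv(dataset$genotypes, path)
  readr::write_tsv(dataset$markers, map_path)
  if (!is.null(centromere_path)) {
    if (is.null(dataset$centromeres)) abort("dataset has no centromere table")
    readr::write_tsv(dataset$centromeres, centromere_path)
  }
  invisible(path)
}
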