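#' Published DCO type counts for Arabidopsis and maize male meiosis
#'
#' Observed 2S:3S:4S double-crossover counts from published tetrad studies
#' of male meiosis: a PCR-marker tetrad dataset for Arabidopsis thaliana
#' (385 DCOs over 5 chromosomes) and a single-microspore sequencing tetrad
#' dataset for Zea mays (684 DCOs over 10 chromosomes). Counts are given
#' per chromosome and pooled ("total"), each split by region: whole
#' chromosome, both COs on the same arm, or the DCO spanning the
#' centromere. `ci_printed` is the CI value as printed in the source
#' tables (see [format_ci_value()] for the display convention).
#'
#' These tables are reference fixtures: they let the CI statistics be
#' recomputed from published counts without access to the raw genotype
#' files.
#'
#' @param species "arabidopsis" or "maize".
#' @return A tibble with columns `chromosome`, `region`, `n2s`, `n3s`,
#'   `n4s`, `ci_printed`.
#' @examples
#' counts <- ci_reference_counts("arabidopsis")
#' counts |>
#'   dplyr::filter(chromosome == "total", region == "whole") |>
#'   dplyr::mutate(ci = ci_value(n2s, n3s, n4s))
#' @export
ci_reference_counts <- function(species = c("arabidopsis", "maize")) {
  species <- arg_match(species)
  path <- system.file("extdata", paste0(species, "_dco_counts.tsv"),
                      package = "tetradci", mustWork = TRUE)
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE,
                  col_types = readr::cols(
                    chromosome = "c", region = "c", n2s = "i", n3s = "i",
                    n4s = "i", ci_printed = "c"
                  ))
}
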