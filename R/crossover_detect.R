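#' Detect crossovers from tetrad genotypes
#'
#' A crossover (CO) is a reciprocal exchange between one maternal and one
#' paternal chromatid, visible in tetrad data as complementary allele
#' transitions (one A to B, one B to A) in exactly two of the four meiotic
#' products between adjacent informative markers. Detection walks each
#' tetrad x chromosome along its informative markers — fully called columns
#' obeying 2:2 segregation — and emits one `CrossoverEvent` per interval in
#' which exactly two products switch allele. The CO position is the midpoint
#' of the flanking marker positions (fractional base pairs are retained).
#'
#' Irregular intervals are never silently dropped; they are recorded in the
#' exclusion log (see [exclusions()]):
#' \describe{
#'   \item{`non_reciprocal_single`}{one product switches — a putative gene
#'     conversion or genotyping error, not a CO.}
#'   \item{`triple_change`}{three products switch — inconsistent with
#'     reciprocal exchange under 2:2 segregation.}
#'   \item{`same_interval_pair`}{all four products switch — two COs share the
#'     interval. Both are emitted with `ambiguous = TRUE` (marker data cannot
#'     order them), and downstream DCO classification drops pairs touching
#'     them.}
#' }
#'
#' @param dataset A [tetrad_dataset()], or a genotype tibble (in which case
#'   `markers` must be supplied).
#' @param markers Marker map tibble; ignored when `dataset` is a
#'   `tetrad_dataset`.
#' @return A tibble of crossover events ordered by tetrad, chromosome and
#'   midpoint, with columns `tetrad_id`, `chromosome`, `left_marker`,
#'   `right_marker`, `left_bp`, `right_bp`, `midpoint_bp`, `product_a`,
#'   `product_b` (`product_a < product_b`) and `ambiguous`. The exclusion
#'   log is attached as an attribute.
#' @examples
#' geno <- tidyr::crossing(tetrad_id = "t1", product_id = 1:4,
#'                         marker = c("m1", "m2", "m3")) |>
#'   dplyr::mutate(chromosome = "c1",
#'                 allele = c("A", "A", "A", "A", "B", "B",
#'                            "B", "A", "A", "B", "B", "B"))
#' map <- tibble::tibble(chromosome = "c1", marker = c("m1", "m2", "m3"),
#'                       position_bp = c(1e6, 2e6, 3e6))
#' detect_crossovers(tetrad_dataset(geno, map))
#' @export
detect_crossovers <- function(dataset, markers = NULL) {
  if (!inherits(dataset, "tetrad_dataset")) {
    if (is.null(markers)) {
      abort("supply a tetrad_dataset, or a genotype tibble plus `markers`")
    }
    dataset <- tetrad_dataset(dataset, markers)
  }
  g <- dataset$genotypes

  wide <- g %>%
    tidyr::pivot_wider(names_from = "product_id", values_from = "allele",
                       names_prefix = "p")
  al <- as.matrix(wide[, c("p1", "p2", "p3", "p4")])
  n_called <- rowSums(!is.na(al))
  n_a <- rowSums(al == "A", na.rm = TRUE)
  wide$informative <- n_called == 4L & n_a == 2L

  inf <- wide %>%
    filter(.data$informative) %>%
    arrange(.data$tetrad_id, .data$chromosome, .data$position_bp) %>%
    group_by(.data$tetrad_id, .data$chromosome) %>%
    mutate(left_marker = lag(.data$marker),
           left_bp = lag(.data$position_bp),
           q1 = lag(.data$p1), q2 = lag(.data$p2),
           q3 = lag(.data$p3), q4 = lag(.data$p4)) %>%
    ungroup() %>%
    filter(!is.na(.data$left_marker))

  if (nrow(inf) == 0) {
    return(set_exclusions(empty_events(), empty_exclusion_log()))
  }

  cur <- as.matrix(inf[, c("p1", "p2", "p3", "p4")])
  prev <- as.matrix(inf[, c("q1", "q2", "q3", "q4")])
  changed <- cur != prev
  n_changed <- rowSums(changed)

  base <- tibble(
    tetrad_id = inf$tetrad_id, chromosome = inf$chromosome,
    left_marker = inf$left_marker, right_marker = inf$marker,
    left_bp = inf$left_bp, right_bp = inf$position_bp,
    midpoint_bp = (inf$left_bp + inf$position_bp) / 2
  )

  a2b <- prev == "A" & cur == "B"
  reciprocal <- n_changed == 2L & rowSums(a2b) == 1L

  ev2 <- base[reciprocal, ] %>%
    mutate(product_a = max.col(changed[reciprocal, , drop = FALSE],
                               ties.method = "first"),
           product_b = max.col(changed[reciprocal, , drop = FALSE],
                               ties.method = "last"),
           ambiguous = FALSE)

  four <- n_changed == 4L
  ev4 <- if (any(four)) {
    ab <- a2b[four, , drop = FALSE]
    ba <- (prev == "B" & cur == "A")[four, , drop = FALSE]
    b4 <- base[four, ]
    # two same-interval COs: pair each A->B product with a B->A product
    e1 <- b4 %>% mutate(
      product_a = pmin(max.col(ab, "first"), max.col(ba, "first")),
      product_b = pmax(max.col(ab, "first"), max.col(ba, "first")),
      ambiguous = TRUE)
    e2 <- b4 %>% mutate(
      product_a = pmin(max.col(ab, "last"), max.col(ba, "last")),
      product_b = pmax(max.col(ab, "last"), max.col(ba, "last")),
      ambiguous = TRUE)
    bind_rows(e1, e2)
  } else {
    NULL
  }

  events <- bind_rows(ev2, ev4) %>%
    arrange(.data$tetrad_id, .data$chromosome, .data$midpoint_bp,
            .data$product_a)

  excl_idx <- which(n_changed %in% c(1L, 3L) |
                      (n_changed == 2L & !reciprocal))
  log <- if (length(excl_idx) > 0) {
    tibble(
      tetrad_id = base$tetrad_id[excl_idx],
      chromosome = base$chromosome[excl_idx],
      detail = paste0("interval ", base$left_marker[excl_idx], "..",
                      base$right_marker[excl_idx]),
      reason = case_when(
        n_changed[excl_idx] == 1L ~ "non_reciprocal_single",
        n_changed[excl_idx] == 3L ~ "triple_change",
        TRUE ~ "non_complementary_pair"
      )
    )
  } else {
    empty_exclusion_log()
  }
  if (any(four)) {
    log <- bind_rows(log, tibble(
      tetrad_id = base$tetrad_id[four],
      chromosome = base$chromosome[four],
      detail = paste0("interval ", base$left_marker[four], "..",
                      base$right_marker[four]),
      reason = "same_interval_pair"
    ))
  }

  set_exclusions(events, log)
}

empty_events <- function() {
  tibble(
    tetrad_id = character(), chromosome = character(),
    left_marker = character(), right_marker = character(),
    left_bp = numeric(), right_bp = numeric(), midpoint_bp = numeric(),
    product_a = integer(), product_b = integer(), ambiguous = logical()
  )
}

#' Midpoint of two flanking marker positions
#'
#' Marker data does not localise a crossover beyond its flanking interval,
#' so the CO position is estimated as the arithmetic mean of the two
#' adjacent recombinant marker positions. Fractional base pairs are kept;
#' rounding happens only at Mb binning.
#'
#' @param left_bp,right_bp Flanking marker positions in base pairs, with
#'   `left_bp < right_bp` elementwise.
#' @return Numeric vector of midpoints.
#' @examples
#' co_midpoint(1e6, 2e6)  # 1500000
#' co_midpoint(3, 4)      # 3.5
#' @export
co_midpoint <- function(left_bp, right_bp) {
  if (any(left_bp >= right_bp)) {
    abort("`left_bp` must be strictly less than `right_bp`")
  }
  (left_bp + right_bp) / 2
}
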