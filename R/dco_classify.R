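#' Classify a double crossover by its shared chromatids
#'
#' Two adjacent COs on the same bivalent form a double crossover (DCO). The
#' number of meiotic products the two COs have in common determines the
#' strand class: both shared — two-strand (2S); one shared — three-strand
#' (3S); none shared — four-strand (4S). Each class carries a CI score of
#' -1, 0 and +1 respectively: a chromatid of the first CO scores -0.5 if it
#' is reused by the second CO and +0.5 if it is not, and the DCO score is
#' the sum over the first CO's two chromatids. Random chromatid choice
#' yields classes in a 1:2:1 ratio and a mean score of 0.
#'
#' @param first_participants,second_participants The two products involved
#'   in each CO: length-2 vectors for a single DCO, or two-column matrices
#'   (one row per DCO) for many.
#' @return A tibble with columns `strand_class` ("2S"/"3S"/"4S") and
#'   `ci_score` (-1/0/+1), one row per DCO.
#' @examples
#' classify_dco(c(2, 3), c(2, 3))  # 2S, -1
#' classify_dco(c(2, 3), c(3, 4))  # 3S,  0
#' classify_dco(c(1, 2), c(3, 4))  # 4S, +1
#' @export
classify_dco <- function(first_participants, second_participants) {
  f <- as_pair_matrix(first_participants, "first_participants")
  s <- as_pair_matrix(second_participants, "second_participants")
  if (nrow(f) != nrow(s)) abort("participant inputs differ in length")
  shared <- (f[, 1] == s[, 1]) + (f[, 1] == s[, 2]) +
    (f[, 2] == s[, 1]) + (f[, 2] == s[, 2])
  tibble(
    strand_class = c("4S", "3S", "2S")[shared + 1L],
    ci_score = 1L - as.integer(shared)
  )
}

as_pair_matrix <- function(x, what) {
  m <- if (is.matrix(x)) x else matrix(x, nrow = 1)
  if (ncol(m) != 2 || any(is.na(m)) || any(m[, 1] == m[, 2])) {
    abort(paste0("`", what, "` must be pairs of two distinct products"))
  }
  m
}

#' Pair adjacent crossovers into double crossovers
#'
#' Walks the position-ordered COs of each tetrad x chromosome and forms one
#' DCO per consecutive pair, so k COs yield k - 1 DCOs (a sliding window,
#' not disjoint pairs). Each DCO is classified with [classify_dco()],
#' annotated with its integer-Mb inter-CO distance
#' ([inter_co_distance_mb()]) and, when centromere positions are supplied,
#' its arm relation ([annotate_arm_relation()]).
#'
#' Pairs in which either CO is flagged `ambiguous` (same-interval CO pairs,
#' whose chromatid pairing marker data cannot resolve) keep their row but
#' get `NA` strand class and score, and are recorded in the exclusion log.
#'
#' @param events Crossover tibble from [detect_crossovers()], ordered by
#'   midpoint within each tetrad x chromosome.
#' @param centromeres Optional tibble with `chromosome`, `centromere_bp`.
#' @return A tibble with one row per consecutive CO pair: `tetrad_id`,
#'   `chromosome`, `mid1_bp`, `mid2_bp`, participant columns, `strand_class`,
#'   `ci_score`, `arm_relation` and `distance_mb`. Exclusions are attached
#'   as an attribute (see [exclusions()]).
#' @export
pair_adjacent <- function(events, centromeres = NULL) {
  events <- as_tibble(events)
  check_columns(events, c("tetrad_id", "chromosome", "midpoint_bp",
                          "product_a", "product_b"), "events")
  if (!"ambiguous" %in% names(events)) events$ambiguous <- FALSE

  unsorted <- events %>%
    group_by(.data$tetrad_id, .data$chromosome) %>%
    summarise(bad = is.unsorted(.data$midpoint_bp), .groups = "drop") %>%
    filter(.data$bad)
  if (nrow(unsorted) > 0) {
    abort("events must be ordered by midpoint within each tetrad x chromosome")
  }

  paired <- events %>%
    group_by(.data$tetrad_id, .data$chromosome) %>%
    mutate(mid2_bp = lead(.data$midpoint_bp),
           p2a = lead(.data$product_a), p2b = lead(.data$product_b),
           amb2 = lead(.data$ambiguous)) %>%
    ungroup() %>%
    filter(!is.na(.data$mid2_bp)) %>%
    rename(mid1_bp = "midpoint_bp", p1a = "product_a", p1b = "product_b",
           amb1 = "ambiguous")

  if (nrow(paired) == 0) {
    out <- tibble(
      tetrad_id = character(), chromosome = character(),
      mid1_bp = numeric(), mid2_bp = numeric(),
      p1a = integer(), p1b = integer(), p2a = integer(), p2b = integer(),
      strand_class = character(), ci_score = integer(),
      arm_relation = character(), distance_mb = integer()
    )
    return(set_exclusions(out, empty_exclusion_log()))
  }

  cls <- classify_dco(cbind(paired$p1a, paired$p1b),
                      cbind(paired$p2a, paired$p2b))
  unresolved <- paired$amb1 | paired$amb2
  cls$strand_class[unresolved] <- NA_character_
  cls$ci_score[unresolved] <- NA_integer_

  dcos <- paired %>%
    mutate(strand_class = cls$strand_class,
           ci_score = cls$ci_score,
           distance_mb = inter_co_distance_mb(.data$mid1_bp,
                                              .data$mid2_bp)) %>%
    select("tetrad_id", "chromosome", "mid1_bp", "mid2_bp",
           "p1a", "p1b", "p2a", "p2b", "strand_class", "ci_score",
           "distance_mb") %>%
    annotate_arm_relation(centromeres)

  log <- if (any(unresolved)) {
    tibble(
      tetrad_id = paired$tetrad_id[unresolved],
      chromosome = paired$chromosome[unresolved],
      detail = paste0("DCO at ", paired$mid1_bp[unresolved], "..",
                      paired$mid2_bp[unresolved]),
      reason = "member_co_ambiguous"
    )
  } else {
    empty_exclusion_log()
  }
  set_exclusions(dcos, log)
}

#' Annotate whether a DCO spans the centromere
#'
#' DCOs are split into those whose two COs lie on the same chromosome arm
#' and those that span the centromere: a DCO spans iff
#' `mid1_bp < centromere_bp <= mid2_bp`. Without a centromere position for
#' the chromosome the relation is `"unknown"`.
#'
#' @param dcos DCO tibble with `chromosome`, `mid1_bp`, `mid2_bp`.
#' @param centromeres Optional tibble with `chromosome`, `centromere_bp`.
#' @return `dcos` with an `arm_relation` column
#'   ("same_arm" / "spans_centromere" / "unknown").
#' @export
annotate_arm_relation <- function(dcos, centromeres = NULL) {
  dcos <- as_tibble(dcos)
  dcos$arm_relation <- NULL
  if (is.null(centromeres)) {
    dcos$arm_relation <- "unknown"
    return(dcos)
  }
  check_columns(centromeres, c("chromosome", "centromere_bp"),
                "centromere table")
  dcos %>%
    left_join(as_tibble(centromeres) %>%
                mutate(chromosome = as.character(.data$chromosome)),
              by = "chromosome") %>%
    mutate(arm_relation = case_when(
      is.na(.data$centromere_bp) ~ "unknown",
      .data$mid1_bp < .data$centromere_bp &
        .data$centromere_bp <= .data$mid2_bp ~ "spans_centromere",
      TRUE ~ "same_arm"
    )) %>%
    select(-"centromere_bp")
}

#' Inter-CO distance in integer megabases
#'
#' The physical distance between the two CO midpoints of a DCO, rounded to
#' the closest Mb integer with .5 rounding up ([round_half_up()]).
#'
#' @param mid1_bp,mid2_bp Ordered CO midpoints in base pairs
#'   (`mid1_bp <= mid2_bp`).
#' @return Integer vector of distances in Mb.
#' @examples
#' inter_co_distance_mb(1.5e6, 15.5e6)  # 14
#' inter_co_distance_mb(0, 2.5e6)       # 3 (half rounds up)
#' @export
inter_co_distance_mb <- function(mid1_bp, mid2_bp) {
  if (any(mid2_bp < mid1_bp)) abort("midpoints must be ordered")
  as.integer(round_half_up((mid2_bp - mid1_bp) / 1e6))
}
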