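#' Round half away from zero
#'
#' Plain decimal rounding where .5 always rounds away from zero, unlike
#' [base::round()]'s round-half-even. Inter-CO distances and displayed CI
#' values use this rule so that results are reproducible from the printed
#' tables.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places (default 0).
#' @return Numeric vector of the same length.
#' @examples
#' round_half_up(2.5)   # 3, where round(2.5) == 2
#' round_half_up(-0.125, 2)
#' @export
round_half_up <- function(x, digits = 0) {
  scale <- 10^digits
  sign(x) * floor(abs(x) * scale + 0.5) / scale
}

#' Format a CI value the way the reference tables print it
#'
#' Values are rounded half-up to 3 decimals and displayed at 2 decimals;
#' non-zero values that would display as "0.00" are shown at 3 decimals, and
#' an exact zero prints as "0". This reproduces published table cells such as
#' "-0.04", "-0.003" and "0".
#'
#' @param x Numeric vector of CI values in \[-1, 1\].
#' @return Character vector.
#' @examples
#' format_ci_value(c(-17/385, -2/684, 0, 3/86))
#' @export
format_ci_value <- function(x) {
  v3 <- round_half_up(x, 3)
  out <- sprintf("%.2f", round_half_up(v3, 2))
  small <- abs(v3) < 0.005 & v3 != 0
  out[small] <- sprintf("%.3f", v3[small])
  out[v3 == 0] <- "0"
  out
}

# shared column checks -------------------------------------------------------

check_columns <- function(df, cols, what) {
  missing <- setdiff(cols, names(df))
  if (length(missing) > 0) {
    abort(paste0(
      what, " is missing required column(s): ",
      paste(missing, collapse = ", ")
    ))
  }
  invisible(df)
}

# attach / retrieve an exclusion log kept alongside a result tibble ----------

set_exclusions <- function(x, log) {
  attr(x, "exclusions") <- log
  x
}

#' Retrieve the exclusion log of a detection or classification result
#'
#' [detect_crossovers()] and [pair_adjacent()] never silently drop irregular
#' intervals or ambiguous events; each exclusion is recorded with a reason
#' code and carried on the result as an attribute.
#'
#' @param x A tibble returned by [detect_crossovers()] or [pair_adjacent()].
#' @return A tibble with one row per excluded record and a `reason` column,
#'   or an empty tibble when nothing was excluded.
#' @export
exclusions <- function(x) {
  log <- attr(x, "exclusions")
  if (is.null(log)) {
    return(tibble(
      tetrad_id = character(), chromosome = character(),
      detail = character(), reason = character()
    ))
  }
  log
}

empty_exclusion_log <- function() {
  tibble(
    tetrad_id = character(), chromosome = character(),
    detail = character(), reason = character()
  )
}
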