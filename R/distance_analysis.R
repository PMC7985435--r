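#' Bin DCOs by integer-Mb inter-CO distance
#'
#' Groups classified DCOs by their integer-Mb distance (`distance_mb`, see
#' [inter_co_distance_mb()]) and returns the DCO count and mean CI score
#' per occupied bin. Bins with no DCOs are omitted, not zero-filled: the
#' count-weighted regression would give them zero weight anyway.
#'
#' @param dcos DCO tibble from [pair_adjacent()] with `distance_mb` and
#'   `ci_score`; rows with `NA` score are ignored.
#' @return A tibble with columns `distance_mb`, `n_dco`, `mean_ci`, ordered
#'   by distance. Empty input yields an empty profile.
#' @export
bin_by_distance <- function(dcos) {
  dcos <- as_tibble(dcos) %>% filter(!is.na(.data$ci_score))
  check_columns(dcos, c("distance_mb", "ci_score"), "dcos")
  dcos %>%
    group_by(distance_mb = as.integer(.data$distance_mb)) %>%
    summarise(n_dco = dplyr::n(), mean_ci = mean(.data$ci_score),
              .groups = "drop") %>%
    arrange(.data$distance_mb)
}

#' Weighted regression of CI on inter-CO distance
#'
#' Fits mean CI per distance bin against distance (Mb) by weighted least
#' squares, with the number of DCOs per bin as weights, so sparsely
#' populated bins do not dominate the trend. The coefficient of
#' determination is the weighted R-squared, computed on the weighted sums
#' of squares around the weighted mean.
#'
#' @param profile Distance profile from [bin_by_distance()] (columns
#'   `distance_mb`, `n_dco`, `mean_ci`), with at least two distinct
#'   distances.
#' @return A `ci_distance_fit` object. Use [tidy()] for coefficients,
#'   [glance()] for `intercept`, `slope`, `r_squared` and the slope test,
#'   [zero_crossing()] for the distance at which the fitted CI changes
#'   sign, and [autoplot()] to draw the profile with the fitted line and
#'   95% confidence band.
#' @examples
#' prof <- tibble::tibble(distance_mb = c(1, 5, 10),
#'                        n_dco = c(30, 20, 10),
#'                        mean_ci = c(-0.2, -0.1, 0.1))
#' glance(fit_ci_distance(prof))
#' @export
fit_ci_distance <- function(profile) {
  profile <- as_tibble(profile)
  check_columns(profile, c("distance_mb", "n_dco", "mean_ci"), "profile")
  if (dplyr::n_distinct(profile$distance_mb) < 2) {
    abort("degenerate fit: need at least 2 distinct distances")
  }
  fit <- lm(mean_ci ~ distance_mb, data = profile, weights = n_dco)
  structure(list(fit = fit, profile = profile), class = "ci_distance_fit")
}

#' @export
print.ci_distance_fit <- function(x, ...) {
  g <- glance(x)
  cat("<ci_distance_fit> ", nrow(x$profile), " bins, ",
      sum(x$profile$n_dco), " DCOs\n", sep = "")
  cat(sprintf("  intercept %.4f, slope %.5f per Mb, weighted R^2 %.4f\n",
              g$intercept, g$slope, g$r_squared))
  zc <- zero_crossing(x)
  if (!is.na(zc)) cat(sprintf("  fitted CI crosses 0 at %.1f Mb\n", zc))
  invisible(x)
}

#' @rdname fit_ci_distance
#' @param x A `ci_distance_fit`.
#' @param ... Unused.
#' @export
tidy.ci_distance_fit <- function(x, ...) {
  s <- summary(x$fit)$coefficients
  tibble(
    term = c("intercept", "distance_mb"),
    estimate = s[, 1], std_error = s[, 2],
    statistic = s[, 3], p_value = s[, 4]
  )
}

#' @rdname fit_ci_distance
#' @export
glance.ci_distance_fit <- function(x, ...) {
  s <- summary(x$fit)
  tibble(
    intercept = unname(coef(x$fit)[1]),
    slope = unname(coef(x$fit)[2]),
    r_squared = s$r.squared,
    slope_p = s$coefficients[2, 4],
    n_bins = nrow(x$profile),
    n_dco = sum(x$profile$n_dco)
  )
}

#' Distance at which the fitted CI trend crosses zero
#'
#' Solves `intercept + slope * d = 0` for the fitted regression line; the
#' crossing separates distances with fitted negative CI from fitted
#' positive CI.
#'
#' @param object A `ci_distance_fit`, or a numeric intercept.
#' @param slope Slope, when `object` is given as a numeric intercept.
#' @return Distance in Mb, or `NA` when the slope is zero.
#' @examples
#' zero_crossing(-0.1598, 0.0115)  # ~13.9 Mb
#' @export
zero_crossing <- function(object, slope = NULL) {
  if (inherits(object, "ci_distance_fit")) {
    co <- coef(object$fit)
    intercept <- unname(co[1]); slope <- unname(co[2])
  } else {
    intercept <- object
    if (is.null(slope)) abort("supply a slope")
  }
  if (slope == 0) return(NA_real_)
  -intercept / slope
}

#' @rdname fit_ci_distance
#' @param object A `ci_distance_fit`.
#' @export
autoplot.ci_distance_fit <- function(object, ...) {
  prof <- object$profile
  grid <- tibble(distance_mb = seq(min(prof$distance_mb),
                                   max(prof$distance_mb), length.out = 100))
  pred <- predict(object$fit, newdata = grid, se.fit = TRUE)
  grid$fit <- pred$fit
  grid$lo <- pred$fit - 1.96 * pred$se.fit
  grid$hi <- pred$fit + 1.96 * pred$se.fit
  ggplot2::ggplot(prof, ggplot2::aes(x = .data$distance_mb)) +
    ggplot2::geom_ribbon(data = grid,
                         ggplot2::aes(ymin = .data$lo, ymax = .data$hi),
                         fill = "grey80", alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$fit),
                       colour = "steelblue") +
    ggplot2::geom_hline(yintercept = 0, linetype = "dashed",
                        colour = "grey40") +
    ggplot2::geom_point(ggplot2::aes(y = .data$mean_ci,
                                     size = .data$n_dco), alpha = 0.8) +
    ggplot2::scale_size_area(name = "DCOs") +
    ggplot2::labs(x = "inter-CO distance (Mb)", y = "mean CI value") +
    ggplot2::theme_minimal()
}

#' Bar plot of observed vs expected DCO type counts
#'
#' Draws observed 2S/3S/4S counts per group against the 1:2:1 expectation,
#' the visual companion of [ci_summary()].
#'
#' @param summary Tibble from [ci_summary()] / [summarize_counts()].
#' @return A ggplot object.
#' @export
plot_dco_counts <- function(summary) {
  long <- summary %>%
    select("group", "n2s", "n3s", "n4s",
           "exp_2s", "exp_3s", "exp_4s") %>%
    tidyr::pivot_longer(-"group", names_to = c("kind", "type"),
                        names_pattern = "(n|exp)_?([234]s)",
                        values_to = "count") %>%
    mutate(kind = if_else(.data$kind == "n", "observed", "expected"),
           type = toupper(.data$type))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$type, y = .data$count,
                                     fill = .data$kind)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::facet_wrap(~group, scales = "free_y") +
    ggplot2::labs(x = "DCO strand class", y = "count", fill = NULL) +
    ggplot2::theme_minimal()
}
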