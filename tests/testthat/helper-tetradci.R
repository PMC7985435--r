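# Build a one-chromosome tetrad dataset from four allele strings, e.g.
# strings_dataset(c("AAA", "ABB", "BAA", "BBB")). "N" encodes a missing call.
strings_dataset <- function(strings, positions = NULL, chromosome = "c1",
                            centromere = NULL, tetrad_id = "t1") {
  stopifnot(length(strings) == 4)
  m <- nchar(strings[1])
  if (is.null(positions)) positions <- seq_len(m) * 1e6
  markers <- tibble::tibble(
    chromosome = chromosome,
    marker = paste0("m", seq_len(m)),
    position_bp = positions
  )
  calls <- do.call(rbind, strsplit(strings, ""))
  calls[calls == "N"] <- NA
  geno <- tidyr::crossing(product_id = 1:4, marker = markers$marker) |>
    dplyr::mutate(tetrad_id = tetrad_id, chromosome = chromosome,
                  allele = as.vector(t(calls)))
  cen <- if (!is.null(centromere)) {
    tibble::tibble(chromosome = chromosome, centromere_bp = centromere)
  }
  tetrad_dataset(geno, markers, cen)
}

# Independent Pearson chi-square oracle for arbitrary expected proportions.
pearson_oracle <- function(obs, p) {
  e <- sum(obs) * p
  stat <- sum((obs - e)^2 / e)
  c(stat = stat, p = stats::pchisq(stat, df = length(obs) - 1,
                                   lower.tail = FALSE))
}

# Independent signed-rank oracle: zeros dropped, tie-corrected normal
# approximation, continuity correction.
signed_rank_oracle <- function(scores, alternative = "two.sided") {
  x <- scores[scores != 0]
  if (length(x) == 0) return(NA_real_)
  r <- rank(abs(x))
  w <- sum(r[x > 0])
  n <- length(x)
  e <- n * (n + 1) / 4
  ties <- table(abs(x))
  v <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  cc <- switch(alternative,
               two.sided = sign(w - e) * 0.5, less = -0.5, greater = 0.5)
  z <- (w - e - cc) / sqrt(v)
  switch(alternative,
         two.sided = min(1, 2 * stats::pnorm(-abs(z))),
         less = stats::pnorm(z),
         greater = stats::pnorm(z, lower.tail = FALSE))
}

# Closed-form weighted least squares via the 2x2 normal equations.
wls_oracle <- function(x, y, w) {
  sw <- sum(w); sx <- sum(w * x); sy <- sum(w * y)
  sxx <- sum(w * x^2); sxy <- sum(w * x * y)
  det <- sw * sxx - sx^2
  b <- (sw * sxy - sx * sy) / det
  a <- (sy - b * sx) / sw
  fitted <- a + b * x
  ybar <- sy / sw
  r2 <- 1 - sum(w * (y - fitted)^2) / sum(w * (y - ybar)^2)
  c(intercept = a, slope = b, r_squared = r2)
}
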