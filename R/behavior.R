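#' Instantaneous finger-tapping frequency
#'
#' One frequency per inter-tap interval: `F(t) = 1 / (m_t - m_{t-1})`.
#'
#' @param tap_times Strictly increasing tap times in seconds.
#' @return Numeric vector of length `length(tap_times) - 1` (empty, with a
#'   warning, for fewer than two taps).
#' @export
tap_frequency <- function(tap_times) {
  if (length(tap_times) < 2) {
    warning("fewer than 2 taps: no inter-tap intervals")
    return(numeric(0))
  }
  dt <- diff(tap_times)
  if (any(dt == 0)) stop("duplicate tap events (zero inter-tap interval)")
  if (any(dt < 0)) stop("tap times must be strictly increasing")
  1 / dt
}

#' Histogram of instantaneous tapping frequency
#'
#' @param freqs Instantaneous frequencies (Hz), e.g. pooled across melodies
#'   and participants.
#' @param bin_width Bin width in Hz (default 0.1).
#' @param f_max Upper edge (default 8 Hz).
#' @return Data frame with bin centres (`frequency`) and `count`.
#' @export
tap_histogram <- function(freqs, bin_width = 0.1, f_max = 8) {
  breaks <- seq(0, f_max, by = bin_width)
  freqs <- freqs[freqs >= 0 & freqs <= f_max]
  h <- graphics::hist(freqs, breaks = breaks, plot = FALSE)
  data.frame(frequency = h$mids, count = h$counts)
}

# shared machinery for the polynomial fits
poly_fit <- function(x, y, degree) {
  fit <- stats::lm(y ~ stats::poly(x, degree, raw = TRUE))
  coefs <- stats::coef(fit)
  names(coefs) <- paste0("b", 0:degree)
  # noise-free inputs are legitimate here; summary.lm warns on perfect fits
  s <- suppressWarnings(summary(fit))
  r2 <- if (stats::var(y) == 0) 0 else s$r.squared          # flat response
  adj <- if (stats::var(y) == 0) 0 else s$adj.r.squared
  out <- list(coefficients = coefs,
              r_squared = r2,
              adjusted_r_squared = adj,
              degree = degree,
              fitted = stats::fitted(fit),
              residuals = stats::residuals(fit),
              x = x, y = y)
  if (degree == 2) {
    a <- coefs[["b2"]]; b <- coefs[["b1"]]
    out$vertex <- if (a != 0) -b / (2 * a) else NA_real_
    out$curvature <- sign(a)
  }
  class(out) <- "groove_fit"
  out
}

#' Quadratic fit of ratings (or model output) against syncopation
#'
#' Least-squares degree-2 polynomial, reporting the adjusted r-squared
#' (penalized for the 3 coefficients), the abscissa of the extremum
#' (`vertex`) and the curvature sign (an inverted U has curvature -1 and an
#' interior vertex).
#'
#' @param x Predictor (e.g. degree of syncopation), at least 4 distinct
#'   values.
#' @param y Response (e.g. mean groove ratings).
#' @return A `groove_fit` object.
#' @export
fit_quadratic <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(unique(x)) < 4) stop("need at least 4 distinct x values")
  poly_fit(x, y, 2L)
}

#' Linear fit reporting Pearson's r-squared
#'
#' @param x Predictor with nonzero variance, at least 3 points.
#' @param y Response.
#' @return A `groove_fit` object whose `r_squared` is the squared Pearson
#'   correlation.
#' @export
fit_linear <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::var(x) == 0) stop("zero variance in x")
  poly_fit(x, y, 1L)
}

#' @export
print.groove_fit <- function(x, ...) {
  cat(sprintf("<groove_fit> degree %d: r^2 = %.4g, adjusted r^2 = %.4g\n",
              x$degree, x$r_squared, x$adjusted_r_squared))
  if (!is.null(x$vertex))
    cat(sprintf("  vertex at x = %.4g (curvature %s)\n", x$vertex,
                if (x$curvature < 0) "negative: inverted U" else "positive"))
  print(signif(x$coefficients, 5))
  invisible(x)
}

#' @export
coef.groove_fit <- function(object, ...) object$coefficients

#' Write a fit result to JSON
#' @param fit A `groove_fit`.
#' @param path File path.
#' @export
write_fit_json <- function(fit, path) {
  doc <- list(coefficients = as.list(fit$coefficients),
              r_squared = fit$r_squared,
              adjusted_r_squared = fit$adjusted_r_squared)
  if (!is.null(fit$vertex)) {
    doc$vertex <- fit$vertex
    doc$curvature <- fit$curvature
  }
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read behavioural tables from CSV
#'
#' `read_ratings_csv` expects columns `participant`, `melody`, `condition`,
#' `rating`; `read_taps_csv` expects `participant`, `stimulus`, `time`.
#'
#' @param path CSV file.
#' @param scale_max Upper bound of the Likert scale for validation
#'   (default 7).
#' @return A data frame (`read_taps_csv` returns a list of `tap_times`
#'   vectors split by participant x stimulus).
#' @export
read_ratings_csv <- function(path, scale_max = 7) {
  d <- utils::read.csv(path)
  need <- c("participant", "melody", "condition", "rating")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  if (any(d$rating < 1 | d$rating > scale_max))
    stop("ratings outside the declared 1-", scale_max, " scale")
  d
}

#' @rdname read_ratings_csv
#' @export
read_taps_csv <- function(path) {
  d <- utils::read.csv(path)
  need <- c("participant", "stimulus", "time")
  if (!all(need %in% names(d))) stop("missing columns: ",
                                     paste(setdiff(need, names(d)), collapse = ", "))
  split(d$time, interaction(d$participant, d$stimulus, drop = TRUE))
}

#' Per-melody mean ratings (aggregation used before the quadratic fit)
#'
#' @param ratings Data frame with `melody` and `rating` columns.
#' @return Data frame with one row per melody and its mean rating.
#' @export
mean_ratings <- function(ratings) {
  agg <- stats::aggregate(rating ~ melody, data = ratings, FUN = mean)
  agg[order(agg$melody), ]
}
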