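#' Morlet wavelet time-frequency decomposition
#'
#' Complex wavelet coefficients at each requested frequency, computed by FFT
#' convolution with a unit-energy Gaussian-envelope (Morlet) wavelet.  The
#' mother wavelet has a 3-s FWHM temporal envelope at 1 Hz
#' (`fwhm_tc` at `fc`), scaled by `fc/f` at analysis frequency `f`; the
#' Gaussian standard deviation is `sd = FWHM / (2*sqrt(2*log(2)))`.
#' Coefficients within one FWHM of either signal edge are flagged.
#'
#' @param x Real time series.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies (all below Nyquist).
#' @param fc,fwhm_tc Mother-wavelet central frequency (Hz) and temporal FWHM
#'   (s); defaults 1 and 3.
#' @return A `morlet_tfr`: list with complex `coef` (`length(freqs)` x
#'   `length(x)`), `power`, `phase`, `freqs`, `fs`, `time`, and logical
#'   `edge` (`freq` x `time`) marking edge-contaminated samples.
#' @export
morlet_tfr <- function(x, fs, freqs, fc = 1, fwhm_tc = 3) {
  if (any(freqs >= fs / 2)) stop("analysis frequency above Nyquist")
  n <- length(x)
  sd1 <- fwhm_tc / (2 * sqrt(2 * log(2)))
  if (n / fs < 2 * fwhm_tc * fc / min(freqs))
    stop("signal shorter than twice the wavelet FWHM at the lowest frequency")
  nu <- (seq_len(n) - 1) * fs / n
  nu[nu > fs / 2] <- nu[nu > fs / 2] - fs
  X <- stats::fft(x)
  coef <- matrix(0 + 0i, nrow = length(freqs), ncol = n)
  edge <- matrix(FALSE, nrow = length(freqs), ncol = n)
  tt <- (seq_len(n) - 1) / fs
  for (i in seq_along(freqs)) {
    f <- freqs[i]
    sdf <- sd1 * fc / f
    A <- 1 / sqrt(sdf * sqrt(pi))                  # unit-energy amplitude
    K <- A * sdf * sqrt(2 * pi) * exp(-2 * pi^2 * sdf^2 * (nu - f)^2)
    coef[i, ] <- stats::fft(X * K, inverse = TRUE) / n
    fw <- fwhm_tc * fc / f
    edge[i, ] <- tt < fw | tt > (max(tt) - fw)
  }
  structure(list(coef = coef, power = Mod(coef)^2, phase = Arg(coef),
                 freqs = freqs, fs = fs, time = tt, edge = edge),
            class = "morlet_tfr")
}

#' Time-averaged Morlet power spectra of many signals at once
#'
#' Fast path for stationary segments: by Parseval's identity the
#' time-averaged wavelet power of a signal equals
#' `sum(|X(nu)|^2 * K(nu)^2) / n^2`, needing one FFT per signal and one
#' matrix product, with no per-time coefficients.  Averages over the whole
#' provided segment, so pass the analysis window (e.g. 0.5-16 s) only.
#'
#' @param X Numeric matrix, one signal per column.
#' @param fs Sampling rate in Hz.
#' @param freqs Analysis frequencies.
#' @param fc,fwhm_tc Wavelet parameters as in [morlet_tfr()].
#' @return Matrix `ncol(X)` x `length(freqs)` of mean wavelet power.
#' @export
morlet_power_avg <- function(X, fs, freqs, fc = 1, fwhm_tc = 3) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (any(freqs >= fs / 2)) stop("analysis frequency above Nyquist")
  sd1 <- fwhm_tc / (2 * sqrt(2 * log(2)))
  nu <- (seq_len(n) - 1) * fs / n
  nu[nu > fs / 2] <- nu[nu > fs / 2] - fs
  K2 <- vapply(freqs, function(f) {
    sdf <- sd1 * fc / f
    A <- 1 / sqrt(sdf * sqrt(pi))
    (A * sdf * sqrt(2 * pi) * exp(-2 * pi^2 * sdf^2 * (nu - f)^2))^2
  }, numeric(n))
  P2 <- Mod(stats::mvfft(X))^2
  crossprod(P2, K2) / n^2
}

#' Time-averaged power of a trial time-frequency cube
#'
#' Means the power over the analysis window per trial, location and
#' frequency, excluding edge-flagged samples.
#'
#' @param cube A `tf_cube` (see [as_tf_cube()]).
#' @param window Time window in seconds (default `c(0.5, 16)`).
#' @return Array `trial` x `location` x `frequency`.
#' @export
time_avg_power <- function(cube, window = c(0.5, 16)) {
  stopifnot(inherits(cube, "tf_cube"))
  keep <- cube$time >= window[1] & cube$time <= window[2]
  if (!any(keep)) stop("empty analysis window")
  d <- dim(cube$power)                      # trial x loc x freq x time
  out <- array(NA_real_, d[1:3])
  for (fi in seq_len(d[3])) {
    ok <- keep & !cube$edge[fi, ]
    if (!any(ok)) ok <- keep                # fall back if FWHM swallows window
    block <- cube$power[, , fi, ok, drop = FALSE]
    out[, , fi] <- apply(block, c(1, 2), mean)
  }
  dimnames(out) <- NULL
  attr(out, "freqs") <- cube$freqs
  out
}

#' Assemble a trial time-frequency cube
#'
#' @param power Array `trial` x `location` x `frequency` x `time` of wavelet
#'   power (non-negative).
#' @param phase Matching array of phases in `(-pi, pi]` (optional).
#' @param freqs Frequency grid in Hz.
#' @param fs Sampling rate of the time axis.
#' @param time Time axis in seconds (relative to stimulus onset).
#' @param edge Logical `frequency` x `time` matrix of edge-flagged samples
#'   (defaults to none).
#' @return An object of class `tf_cube`.
#' @export
as_tf_cube <- function(power, phase = NULL, freqs, fs, time,
                       edge = NULL) {
  stopifnot(length(dim(power)) == 4, length(freqs) == dim(power)[3],
            length(time) == dim(power)[4])
  if (is.null(edge))
    edge <- matrix(FALSE, nrow = length(freqs), ncol = length(time))
  structure(list(power = power, phase = phase, freqs = freqs, fs = fs,
                 time = time, edge = edge), class = "tf_cube")
}

#' @export
print.tf_cube <- function(x, ...) {
  d <- dim(x$power)
  cat(sprintf("<tf_cube> %d trials x %d locations x %d frequencies (%.3g-%.3g Hz) x %d samples\n",
              d[1], d[2], d[3], min(x$freqs), max(x$freqs), d[4]))
  invisible(x)
}

#' Remove the aperiodic 1/f component by cross-location z-scoring
#'
#' For each frequency (and trial, if present), power is z-scored across
#' locations, so any spectral profile common to all locations -- in
#' particular the 1/f decay -- is removed exactly, and the per-frequency
#' distribution over locations has mean 0 and standard deviation 1.
#'
#' @param power Matrix `location` x `frequency`, or array
#'   `trial` x `location` x `frequency`.
#' @return Z-scored object of the same shape.
#' @export
rectify_1f <- function(power) {
  zs <- function(m) {
    if (nrow(m) < 2) stop("need at least 2 locations")
    mu <- colMeans(m)
    sd <- apply(m, 2, stats::sd)
    bad <- which(sd == 0)
    if (length(bad)) {
      f <- attr(power, "freqs")
      lab <- if (!is.null(f)) paste(signif(f[bad], 4), collapse = ", ")
             else paste(bad, collapse = ", ")
      stop("zero cross-location variance at frequency ", lab)
    }
    sweep(sweep(m, 2, mu), 2, sd, "/")
  }
  if (is.matrix(power)) {
    out <- zs(power)
  } else if (length(dim(power)) == 3) {
    out <- power
    for (tr in seq_len(dim(power)[1])) out[tr, , ] <- zs(power[tr, , ])
  } else stop("power must be location x frequency or trial x location x frequency")
  attr(out, "freqs") <- attr(power, "freqs")
  out
}

#' Dominant frequency per location
#'
#' The grid frequency of maximal (1/f-rectified) power within `band`; ties
#' are broken toward the lower frequency.
#'
#' @param z Matrix `location` x `frequency` of z-scored power.
#' @param freqs Frequency grid (taken from `attr(z, "freqs")` if missing).
#' @param band Analysis band in Hz (default `c(1, 45)`).
#' @return Numeric vector of per-location dominant frequencies (class
#'   `dominant_frequency_map`).
#' @export
dominant_frequency <- function(z, freqs = attr(z, "freqs"),
                               band = c(1, 45)) {
  stopifnot(is.matrix(z), length(freqs) == ncol(z))
  inband <- which(freqs >= band[1] & freqs <= band[2])
  if (!length(inband)) stop("band outside the frequency grid")
  sub <- z[, inband, drop = FALSE]
  idx <- apply(sub, 1, which.max)          # which.max takes the first (lower) tie
  structure(freqs[inband[idx]], band = band, class = "dominant_frequency_map")
}

#' Polynomial fit of the dominant-frequency map along each spatial dimension
#'
#' Fits, independently for each coordinate (x, y, z), a degree-`order`
#' polynomial of dominant frequency against the vertex coordinate, reporting
#' the adjusted r-squared per dimension.  Coordinates are standardized
#' internally for conditioning; reported coefficients are converted back to
#' original mm units.
#'
#' @param map A `dominant_frequency_map` (or plain vector, one value per
#'   vertex).
#' @param coords Matrix `vertex` x 3 of mm coordinates (columns x, y, z).
#' @param order Polynomial order (default 5).
#' @return A list of class `spatial_gradient_fit` with one `groove_fit` per
#'   dimension plus an `adjusted_r_squared` summary vector.
#' @export
fit_spatial_gradient <- function(map, coords, order = 5) {
  y <- as.numeric(map)
  coords <- as.matrix(coords)
  stopifnot(nrow(coords) == length(y), ncol(coords) == 3)
  if (length(y) < order + 2) stop("need at least order + 2 vertices")
  dims <- c("X", "Y", "Z")
  fits <- lapply(1:3, function(d) {
    x <- coords[, d]
    mu <- mean(x); s <- stats::sd(x)
    if (s == 0) stop("rank-deficient fit: coordinate ", dims[d], " is constant")
    u <- (x - mu) / s
    fit <- poly_fit(u, y, order)
    # convert standardized-coordinate coefficients to original mm units:
    # y = sum_k b_k ((x - mu)/s)^k  =>  coefficient of x^j is
    # sum_{k>=j} b_k choose(k, j) (-mu)^(k-j) / s^k
    b <- fit$coefficients
    raw <- vapply(0:order, function(j) {
      sum(vapply(j:order, function(k)
        b[[paste0("b", k)]] * choose(k, j) * (-mu)^(k - j) / s^k, numeric(1)))
    }, numeric(1))
    names(raw) <- paste0("b", 0:order)
    fit$coefficients_mm <- raw
    fit$coordinate <- dims[d]
    fit$coordinate_range <- range(x)
    fit
  })
  names(fits) <- dims
  structure(list(fits = fits,
                 adjusted_r_squared = vapply(fits, `[[`, numeric(1),
                                             "adjusted_r_squared")),
            class = "spatial_gradient_fit")
}

#' @export
print.spatial_gradient_fit <- function(x, ...) {
  cat("<spatial_gradient_fit> adjusted r^2 per dimension:\n")
  print(signif(x$adjusted_r_squared, 4))
  invisible(x)
}

#' Evaluate a fitted spatial-gradient polynomial over a coordinate range
#'
#' @param fit A `spatial_gradient_fit`.
#' @param dim `"X"`, `"Y"` or `"Z"`.
#' @param n Number of evaluation points.
#' @return Data frame with mm `coordinate` and `fitted` dominant frequency.
#' @export
gradient_curve <- function(fit, dim = c("Y", "X", "Z"), n = 100) {
  dim <- match.arg(dim)
  f <- fit$fits[[dim]]
  x <- seq(f$coordinate_range[1], f$coordinate_range[2], length.out = n)
  b <- f$coefficients_mm
  yhat <- rowSums(vapply(seq_along(b), function(k) b[k] * x^(k - 1),
                         numeric(n)))
  data.frame(coordinate = x, fitted = yhat)
}
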