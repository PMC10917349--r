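#' Equivalent-rectangular-bandwidth (ERB) scale helpers
#'
#' @param f Frequency in Hz.
#' @return `erb_bandwidth`: the ERB of the auditory filter centred at `f`;
#'   `erb_space`: `n` centre frequencies equally spaced on the ERB-rate scale.
#' @keywords internal
erb_bandwidth <- function(f) 24.7 * (4.37 * f / 1000 + 1)

erb_rate <- function(f) 21.4 * log10(4.37 * f / 1000 + 1)
erb_rate_inv <- function(e) (10^(e / 21.4) - 1) * 1000 / 4.37

#' @param f_lo,f_hi Band edges in Hz.
#' @param n Number of channels.
#' @rdname erb_bandwidth
#' @keywords internal
erb_space <- function(f_lo, f_hi, n) {
  erb_rate_inv(seq(erb_rate(f_lo), erb_rate(f_hi), length.out = n))
}

#' Broadband temporal envelope via a gammatone cochlear filterbank
#'
#' Decomposes the audio into `n_bands` gammatone channels (4th order, centre
#' frequencies on an ERB scale from `f_lo` to `min(f_hi, 0.9*Nyquist)`),
#' takes the magnitude of the analytic signal in each band, and sums the
#' magnitudes across bands.  Filtering is done by FFT convolution with unit
#' peak-gain frequency responses.
#'
#' @param audio Real vector (mono; at least 1 s of samples).
#' @param sample_rate Sampling rate in Hz.
#' @param n_bands Number of cochlear channels (default 32).
#' @param f_lo,f_hi Filterbank edge frequencies (defaults 80 Hz and 8 kHz).
#' @return An `envelope_signal`: non-negative numeric vector with attributes
#'   `sample_rate`, `band_count` and `center_frequencies`.
#' @export
cochlear_envelope <- function(audio, sample_rate, n_bands = 32,
                              f_lo = 80, f_hi = 8000) {
  if (n_bands < 1) stop("n_bands must be >= 1")
  if (length(audio) < sample_rate) stop("need at least 1 s of audio")
  f_hi <- min(f_hi, 0.45 * sample_rate)
  if (sample_rate < 2 * f_hi) stop("sample_rate below twice the top filter frequency")
  cf <- erb_space(f_lo, f_hi, n_bands)
  n <- length(audio)
  X <- stats::fft(audio)
  fr <- (seq_len(n) - 1) * sample_rate / n
  env <- numeric(n)
  order <- 4
  for (b in seq_len(n_bands)) {
    bw <- 1.019 * erb_bandwidth(cf[b])
    # analytic gammatone magnitude response (positive frequencies only):
    # |H(f)| = [1 + ((f - cf)/bw)^2]^(-order/2), peak gain 1
    H <- numeric(n)
    pos <- fr <= sample_rate / 2
    H[pos] <- (1 + ((fr[pos] - cf[b]) / bw)^2)^(-order / 2)
    half <- which(fr > 0 & fr < sample_rate / 2)
    Hfull <- H
    Hfull[half] <- 2 * H[half]       # analytic: double positive frequencies
    band <- stats::fft(X * Hfull, inverse = TRUE) / n
    env <- env + Mod(band)
  }
  structure(env, sample_rate = sample_rate, band_count = n_bands,
            center_frequencies = cf, class = "envelope_signal")
}

#' Low-frequency modulation spectrum of a temporal envelope
#'
#' Decimates the (mean-removed) envelope to `decimate_to` Hz and returns its
#' Fourier amplitude on the analysis grid restricted to `[f_lo, f_hi]` Hz,
#' plus the amplitude at the 2-Hz beat in dB (re 1 a.u.).
#'
#' @param envelope An `envelope_signal` (or plain vector with a
#'   `sample_rate` attribute).
#' @param f_lo,f_hi Analysis band in Hz (defaults 1 and 9).
#' @param decimate_to Rate of the decimated envelope used for the FFT
#'   (default 100 Hz).
#' @param beat Frequency whose amplitude is reported in dB (default 2 Hz).
#' @return A `modulation_spectrum`: list with `frequencies`, `amplitude`,
#'   and `amplitude_db_at_beat`.
#' @export
modulation_spectrum <- function(envelope, f_lo = 1, f_hi = 9,
                                decimate_to = 100, beat = 2) {
  sr <- attr(envelope, "sample_rate")
  if (is.null(sr)) stop("envelope needs a 'sample_rate' attribute")
  x <- as.numeric(envelope)
  if (length(x) / sr < 2 / f_lo)
    stop("envelope too short to resolve f_lo = ", f_lo, " Hz")
  # decimate by averaging blocks (envelope is low-pass by construction)
  dec <- max(1L, floor(sr / decimate_to))
  n_blk <- floor(length(x) / dec)
  x <- colMeans(matrix(x[seq_len(n_blk * dec)], nrow = dec))
  fs <- sr / dec
  x <- x - mean(x)
  n <- length(x)
  X <- Mod(stats::fft(x)) / n * 2
  fr <- (seq_len(n) - 1) * fs / n
  keep <- fr >= f_lo & fr <= f_hi
  k_beat <- which.min(abs(fr - beat))
  structure(list(frequencies = fr[keep], amplitude = X[keep],
                 amplitude_db_at_beat = 20 * log10(X[k_beat])),
            class = "modulation_spectrum")
}

#' @export
print.modulation_spectrum <- function(x, ...) {
  cat(sprintf("<modulation_spectrum> %d bins %.3g-%.3g Hz; 2-Hz amplitude %.3g dB\n",
              length(x$frequencies), min(x$frequencies), max(x$frequencies),
              x$amplitude_db_at_beat))
  invisible(x)
}

#' Write a modulation spectrum to CSV (frequency, amplitude)
#' @param spec A `modulation_spectrum`.
#' @param path File path.
#' @export
write_modulation_csv <- function(spec, path) {
  utils::write.csv(data.frame(frequency = spec$frequencies,
                              amplitude = spec$amplitude),
                   path, row.names = FALSE)
  invisible(path)
}

#' Minimal PCM WAV reader (16- or 24-bit integer; stereo averaged to mono)
#'
#' @param path WAV file path.
#' @return Numeric vector in [-1, 1] with attribute `sample_rate`.
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  riff <- readChar(con, 4, useBytes = TRUE)
  if (riff != "RIFF") stop("not a RIFF/WAV file")
  invisible(readBin(con, "integer", 1, 4, endian = "little"))
  wave <- readChar(con, 4, useBytes = TRUE)
  if (wave != "WAVE") stop("not a WAV file")
  fmt <- NULL; data <- NULL
  while (is.null(data)) {
    id <- readChar(con, 4, useBytes = TRUE)
    if (length(id) == 0 || nchar(id) < 4) stop("malformed WAV: no data chunk")
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      raw <- readBin(con, "raw", size)
      fmt <- list(
        format = readBin(raw[1:2], "integer", 1, 2, endian = "little"),
        channels = readBin(raw[3:4], "integer", 1, 2, endian = "little"),
        sample_rate = readBin(raw[5:8], "integer", 1, 4, endian = "little"),
        bits = readBin(raw[15:16], "integer", 1, 2, endian = "little"))
    } else if (id == "data") {
      data <- readBin(con, "raw", size)
    } else {
      invisible(readBin(con, "raw", size))
    }
  }
  if (is.null(fmt)) stop("malformed WAV: no fmt chunk")
  if (fmt$format != 1) stop("only PCM WAV is supported")
  if (fmt$bits == 16) {
    x <- readBin(data, "integer", length(data) / 2, 2,
                 signed = TRUE, endian = "little") / 32768
  } else if (fmt$bits == 24) {
    n <- length(data) / 3
    m <- matrix(as.integer(data), nrow = 3)
    v <- m[1, ] + 256 * m[2, ] + 65536 * m[3, ]
    v <- ifelse(v >= 8388608, v - 16777216, v)
    x <- v / 8388608
  } else stop("only 16/24-bit PCM supported")
  if (fmt$channels > 1) {
    x <- colMeans(matrix(x, nrow = fmt$channels))
  }
  structure(x, sample_rate = fmt$sample_rate)
}
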