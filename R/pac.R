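#' Phase-amplitude coupling statistic rho
#'
#' The normalized resultant
#' `rho = |sum(a * exp(i*phi))| / sqrt(N * sum(a^2))`, which lies in [0, 1]
#' by Cauchy-Schwarz: 0 when amplitude is unrelated to phase (phases cover
#' whole cycles), 1 when all amplitude is concentrated at a single phase.
#'
#' @param phase Phase series in radians.
#' @param amplitude Non-negative amplitude series of the same length
#'   (>= 100 samples).
#' @param phase_frequency,amplitude_frequency Optional metadata (Hz).
#' @return A `pac_estimate`: list with `rho`, `n_samples` and the metadata.
#' @export
pac_rho <- function(phase, amplitude,
                    phase_frequency = NA_real_,
                    amplitude_frequency = NA_real_) {
  if (length(phase) != length(amplitude)) stop("length mismatch")
  if (length(phase) < 100) stop("need at least 100 samples")
  if (any(amplitude < 0)) stop("amplitudes must be non-negative")
  if (all(amplitude == 0)) stop("all-zero amplitude")
  N <- length(phase)
  rho <- Mod(sum(amplitude * exp(1i * phase))) / sqrt(N * sum(amplitude^2))
  structure(list(rho = rho, n_samples = N,
                 phase_frequency = phase_frequency,
                 amplitude_frequency = amplitude_frequency),
            class = "pac_estimate")
}

#' @export
print.pac_estimate <- function(x, ...) {
  cat(sprintf("<pac_estimate> rho = %.4f (N = %d%s)\n", x$rho, x$n_samples,
              if (!is.na(x$phase_frequency))
                sprintf("; phase %g Hz -> amplitude %g Hz",
                        x$phase_frequency, x$amplitude_frequency) else ""))
  invisible(x)
}

#' Phase-amplitude comodulogram from a trial time-frequency cube
#'
#' For each location and each (phase frequency, amplitude frequency) pair,
#' pools phase and amplitude samples over the analysis window of all trials
#' (time and melodies concatenated, edge-flagged samples dropped) and
#' computes [pac_rho()].  Requested frequencies off the cube grid are
#' substituted by the nearest bin with a warning.
#'
#' @param cube A `tf_cube` containing `phase` and `power`.
#' @param locations Vertex indices to analyse (default all).
#' @param phase_freqs Phase frequencies in Hz (default `c(1.4, 2)`).
#' @param amp_freqs Amplitude frequencies in Hz (default the cube grid
#'   within 3-45 Hz).
#' @param window Analysis window in seconds (default `c(0.5, 16)`).
#' @return Data frame with columns `phase_freq`, `amp_freq`, `location`,
#'   `rho` (class `pac_comodulogram`).
#' @export
pac_comodulogram <- function(cube, locations = NULL,
                             phase_freqs = c(1.4, 2),
                             amp_freqs = NULL,
                             window = c(0.5, 16)) {
  stopifnot(inherits(cube, "tf_cube"))
  if (is.null(cube$phase)) stop("cube carries no phase information")
  if (is.null(locations)) locations <- seq_len(dim(cube$power)[2])
  if (is.null(amp_freqs))
    amp_freqs <- cube$freqs[cube$freqs >= 3 & cube$freqs <= 45]
  snap <- function(f) {
    k <- which.min(abs(cube$freqs - f))
    if (abs(cube$freqs[k] - f) > 1e-9)
      warning(sprintf("frequency %g Hz off-grid; using nearest bin %.4g Hz",
                      f, cube$freqs[k]))
    k
  }
  pf_idx <- vapply(phase_freqs, snap, integer(1))
  af_idx <- vapply(amp_freqs, snap, integer(1))
  keep_t <- cube$time >= window[1] & cube$time <= window[2]
  rows <- list()
  for (loc in locations) {
    for (pi_ in seq_along(pf_idx)) {
      fp <- pf_idx[pi_]
      ok_p <- keep_t & !cube$edge[fp, ]
      ph <- as.vector(t(cube$phase[, loc, fp, ok_p]))
      for (ai in seq_along(af_idx)) {
        fa <- af_idx[ai]
        ok <- ok_p & !cube$edge[fa, ]
        sel <- ok[ok_p]
        amp <- sqrt(as.vector(t(cube$power[, loc, fa, ok_p])))[sel]
        est <- pac_rho(ph[sel], amp,
                       phase_frequency = cube$freqs[fp],
                       amplitude_frequency = cube$freqs[fa])
        rows[[length(rows) + 1L]] <- data.frame(
          phase_freq = cube$freqs[fp], amp_freq = cube$freqs[fa],
          location = loc, rho = est$rho)
      }
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("pac_comodulogram", class(out))
  out
}

#' Cluster versus whole-brain comparison of PAC estimates
#'
#' Per amplitude frequency: the mean rho inside a vertex cluster versus the
#' mean across the whole grid, with (when per-subject maps are supplied) a
#' paired two-tailed t-test across subjects and Storey FDR over amplitude
#' frequencies.
#'
#' @param pac_maps Either one `pac_comodulogram`, or a list of them (one per
#'   subject) for group inference.
#' @param cluster Vertex index set (non-empty, subset of the analysed
#'   locations).
#' @param phase_freq Which phase frequency to analyse (default the first in
#'   the maps).
#' @param q_threshold FDR threshold (default 0.05).
#' @return Data frame per amplitude frequency with `cluster_mean`,
#'   `wholebrain_mean`, `difference`, and (for grouped input) `p`, `q`,
#'   `significant`.
#' @export
cluster_vs_wholebrain <- function(pac_maps, cluster, phase_freq = NULL,
                                  q_threshold = 0.05) {
  if (!length(cluster)) stop("empty cluster")
  maps <- if (inherits(pac_maps, "pac_comodulogram")) list(pac_maps) else pac_maps
  pf <- if (is.null(phase_freq)) maps[[1]]$phase_freq[1] else phase_freq
  af <- sort(unique(maps[[1]]$amp_freq))
  per_subj <- lapply(maps, function(m) {
    m <- m[abs(m$phase_freq - pf) < 1e-9, ]
    if (!all(cluster %in% m$location)) stop("cluster not a subset of analysed locations")
    cl <- vapply(af, function(f)
      mean(m$rho[m$amp_freq == f & m$location %in% cluster]), numeric(1))
    wb <- vapply(af, function(f)
      mean(m$rho[m$amp_freq == f]), numeric(1))
    cbind(cl, wb)
  })
  cl_mat <- t(vapply(per_subj, function(x) x[, 1], numeric(length(af))))
  wb_mat <- t(vapply(per_subj, function(x) x[, 2], numeric(length(af))))
  out <- data.frame(amp_freq = af,
                    cluster_mean = colMeans(cl_mat),
                    wholebrain_mean = colMeans(wb_mat),
                    difference = colMeans(cl_mat - wb_mat))
  if (length(maps) >= 2) {
    ct <- contrast_precision(cl_mat, wb_mat)
    out$p <- ct$p
    ok <- !is.na(out$p)
    out$q <- NA_real_
    if (any(ok)) {
      fdr <- storey_fdr(out$p[ok], q_threshold)
      out$q[ok] <- fdr$q_values
    }
    out$significant <- !is.na(out$q) & out$q <= q_threshold
  }
  out
}

#' Write a comodulogram to CSV
#' @param comod A `pac_comodulogram`.
#' @param path File path.
#' @export
write_pac_csv <- function(comod, path) {
  utils::write.csv(as.data.frame(comod), path, row.names = FALSE)
  invisible(path)
}
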