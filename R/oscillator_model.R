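#' Logarithmically spaced natural-frequency grid
#'
#' @param f_min,f_max Frequency bounds in Hz (defaults 0.375 and 12, covering
#'   the delta--theta range around the 2-Hz beat).
#' @param n Number of oscillators (default 321).
#' @return Numeric vector of `n` log-spaced frequencies with exact endpoints
#'   and a constant ratio between neighbours.
#' @export
frequency_grid <- function(f_min = 0.375, f_max = 12, n = 321) {
  if (!(f_min > 0 && f_min < f_max)) stop("need 0 < f_min < f_max")
  if (n < 2) stop("need n >= 2")
  exp(seq(log(f_min), log(f_max), length.out = n))
}

#' Parameters of one canonical Hopf oscillator layer
#'
#' The intrinsic flow of each oscillator is
#' `dz = z*(a + b|z|^2 + d|z|^4/(1-|z|^2)) + x` with `a = alpha + i*omega`,
#' `b = beta1 + i*delta1`, `d = beta2 + i*delta2`.  `alpha` is the bifurcation
#' parameter; `beta1`, `beta2` shape the amplitude nonlinearity; `delta1`,
#' `delta2` make intrinsic frequency amplitude-dependent (0 here).
#'
#' @param alpha,beta1,beta2,delta1,delta2 Real parameters.
#' @return A list of class `hopf_params`.
#' @export
hopf_params <- function(alpha, beta1, beta2, delta1 = 0, delta2 = 0) {
  structure(list(alpha = alpha, beta1 = beta1, beta2 = beta2,
                 delta1 = delta1, delta2 = delta2), class = "hopf_params")
}

#' Critical (auditory) and bistable (motor) oscillator regimes
#'
#' `auditory_regime()` places oscillators just above a supercritical Hopf
#' bifurcation (tiny spontaneous amplitude, strongly entrainable);
#' `motor_regime()` places them in the double-limit-cycle (bistable) regime
#' with a stable rest state and a stable high-amplitude limit cycle.
#' @return A [hopf_params()] object.
#' @export
auditory_regime <- function() hopf_params(alpha = 1e-4, beta1 = 0, beta2 = -3)

#' @rdname auditory_regime
#' @export
motor_regime <- function() hopf_params(alpha = -0.8, beta1 = 4, beta2 = -3)

#' Intrinsic + input derivative of one canonical Hopf oscillator
#'
#' Reference (pure R) implementation, also used as an oracle for the
#' compiled integrator.
#'
#' @param z Complex state with `|z| < 1`.
#' @param p A [hopf_params()] object.
#' @param omega Natural frequency in rad/s.
#' @param x Complex input.
#' @return Complex time derivative.
#' @export
oscillator_derivative <- function(z, p, omega, x = 0 + 0i) {
  if (any(Mod(z) >= 1)) stop("state escaped the unit disk (|z| >= 1)")
  a <- complex(real = p$alpha, imaginary = omega)
  b <- complex(real = p$beta1, imaginary = p$delta1)
  d <- complex(real = p$beta2, imaginary = p$delta2)
  r2 <- Mod(z)^2
  z * (a + b * r2 + d * r2^2 / (1 - r2)) + x
}

#' Hebbian derivative of one complex connection coefficient
#'
#' `tau * dc = c*(lambda + mu1|c|^2 + mu2|c|^4/(1-|c|^2)) +
#'  kappa * z_target^m * Conj(z_source)^k`.
#'
#' @param c Complex connection state with `|c| < 1`.
#' @param lp List with fields `lambda`, `mu1`, `mu2`, `kappa`, `tau`.
#' @param z_target,z_source Complex oscillator states.
#' @param k,m Mode-locking ratio `k:m`.
#' @return Complex derivative `dc/dt`.
#' @export
hebbian_derivative <- function(c, lp, z_target, z_source, k = 1, m = 1) {
  if (any(Mod(c) >= 1)) stop("connection escaped the unit disk (|c| >= 1)")
  r2 <- Mod(c)^2
  (c * (lp$lambda + lp$mu1 * r2 + lp$mu2 * r2^2 / (1 - r2)) +
     lp$kappa * z_target^m * Conj(z_source)^k) / lp$tau
}

#' Coupling input to one oscillator from a source layer
#'
#' For each mode-locking ratio `k:m`, sums `c_ij * z_j^k * Conj(z_i)^(m-1)`
#' over connected sources `j`; for 1:1 coupling this reduces to
#' `sum(c_ij * z_j)`, independent of the target state.
#'
#' @param states_source Complex vector of source-layer states.
#' @param state_target Complex state of the receiving oscillator.
#' @param c Complex vector of coupling coefficients (one per source).
#' @param k,m Integer mode-locking ratio.
#' @return Complex input.
#' @export
coupling_input <- function(states_source, state_target, c, k = 1, m = 1) {
  if (length(c) != length(states_source)) stop("dimension mismatch")
  if (Mod(state_target) >= 1) stop("target state escaped the unit disk")
  sum(c * states_source^k * Conj(state_target)^(m - 1))
}

#' Connectivity mask at harmonic frequency ratios
#'
#' Pairs `(i, j)` of grid frequencies whose ratio `f_j / f_i` lies within one
#' grid step of one of `ratios` are connected.  The mask describes
#' between-layer connections, so the unison pair (`j = i`, the "first
#' harmonic") is included.
#'
#' @param freqs Log-spaced frequency grid.
#' @param ratios Frequency ratios to connect (default subharmonics 1/4, 1/3,
#'   1/2, unison, and harmonics 2, 3, 4).
#' @return A data frame with 1-based columns `target`, `source` and the
#'   matched `ratio`.
#' @export
harmonic_mask <- function(freqs, ratios = c(1/4, 1/3, 1/2, 1, 2, 3, 4)) {
  step <- log(freqs[2]) - log(freqs[1])
  lf <- log(freqs)
  tg <- integer(0); sr <- integer(0); rt <- numeric(0)
  for (r in ratios) {
    off <- log(r) / step
    cand <- seq(floor(off - 1), ceiling(off + 1))
    cand <- cand[abs(cand - off) <= 1]
    for (d in unique(cand)) {
      i <- seq_along(freqs)
      j <- i + d
      ok <- j >= 1 & j <= length(freqs)
      tg <- c(tg, i[ok]); sr <- c(sr, j[ok]); rt <- c(rt, rep(r, sum(ok)))
    }
  }
  unique(data.frame(target = tg, source = sr, ratio = rt))
}

#' Three-layer gradient-frequency Hopf network
#'
#' Builds the feedforward network used throughout the package: an auditory
#' layer (layer 1) of entrainable near-critical oscillators driven by the
#' stimulus, a motor-planning layer (layer 2) in the bistable regime coupled
#' to layer 1 through Hebbian-plastic multifrequency connections, and a
#' groove layer (layer 3, bistable) receiving fixed 1:1 excitatory input from
#' layer 2 (`w23 = 0.8`) and fixed 1:1 inhibitory input from layer 1
#' (`w13 = -0.7`), i.e. responding to the difference between the
#' pulse/meter dynamics of layer 2 and the stimulus-driven dynamics of
#' layer 1.  All layers share one log-spaced frequency grid.
#'
#' @param n_osc Oscillators per layer (default 321).
#' @param f_min,f_max Frequency-grid bounds in Hz.
#' @param layer1,layer2,layer3 [hopf_params()] per layer.
#' @param w23,w13 Fixed diagonal coupling strengths.
#' @param harmonics Frequency ratios receiving initial layer-1 to layer-2
#'   connections.
#' @param conn_init Initial magnitude of those connections; the mask is
#'   fixed, so unconnected pairs never grow a connection.  The default 0.3
#'   sits below the Hebbian rule's self-sustaining threshold (the unstable
#'   root of its radial equation, ~0.61), so the initial harmonic scaffold
#'   fades over the learning timescale `tau` unless reinforced by
#'   coactivation -- strong enough to transmit the rhythm while the
#'   auditory layer entrains, weak enough that the meter layer engages
#'   selectively; see the package vignette.
#' @param conn_phase `"zero"` (default) starts all connections in phase,
#'   giving coherent resonant transmission between layers; `"random"` draws
#'   a uniform phase per connection per simulation (seeded).
#' @param exponents `"mode_locking"` (default) uses k:m resonance exponents
#'   (1:1, 2:1, 3:1, ...) matched to each pair's frequency ratio, so a
#'   coupling term `c * z_j^k * Conj(z_i)^(m-1)` rotates at the target's own
#'   frequency (`k f_j = m f_i`) and transmits resonantly across harmonic
#'   ratios -- the route by which the meter layer infers the pulse from
#'   harmonics of the rhythm; `"one_to_one"` uses plain 1:1 terms for all
#'   pairs (the connections then carry only same-frequency structure).
#' @param learn Logical: evolve connections by the Hebbian rule.
#' @param lambda,mu1,mu2,kappa Hebbian rule constants.
#' @param tau Hebbian time scale in seconds (default 8, half the melody
#'   duration: the connection scaffold fades over the trial unless
#'   reinforced).
#' @param freq_scaling Logical: multiply each oscillator's flow by its natural
#'   frequency so all oscillators evolve in proportion to their own rate
#'   (standard gradient-frequency network practice; changes transient
#'   durations, not equilibrium amplitudes).
#' @param stimulus_gain Length-3 gains routing the stimulus into each layer
#'   (default `c(1, 0, 0)`: only the auditory layer hears the stimulus).
#' @return An object of class `hopf_network`.
#' @export
hopf_network <- function(n_osc = 321, f_min = 0.375, f_max = 12,
                         layer1 = auditory_regime(),
                         layer2 = motor_regime(),
                         layer3 = motor_regime(),
                         w23 = 0.8, w13 = -0.7,
                         harmonics = c(1/4, 1/3, 1/2, 1, 2, 3, 4),
                         conn_init = 0.3,
                         conn_phase = c("zero", "random"),
                         exponents = c("mode_locking", "one_to_one"),
                         learn = TRUE,
                         lambda = -1, mu1 = 4, mu2 = -2.2, kappa = 0.2,
                         tau = 8,
                         freq_scaling = TRUE,
                         stimulus_gain = c(1, 0, 0)) {
  exponents <- match.arg(exponents)
  conn_phase <- match.arg(conn_phase)
  freqs <- frequency_grid(f_min, f_max, n_osc)
  mask <- harmonic_mask(freqs, harmonics)
  if (exponents == "one_to_one") {
    mask$k <- 1L; mask$m <- 1L
  } else {
    # resonance requires k * f_source = m * f_target, i.e. ratio
    # f_source / f_target = m / k with small integers m, k
    km <- t(vapply(mask$ratio, function(r) {
      if (r >= 1) c(1, round(r)) else c(round(1 / r), 1)
    }, numeric(2)))
    mask$k <- as.integer(km[, 1]); mask$m <- as.integer(km[, 2])
  }
  structure(list(
    n_osc = as.integer(n_osc), freqs = freqs,
    layers = list(layer1, layer2, layer3),
    w23 = w23, w13 = w13,
    mask = mask, conn_init = conn_init, conn_phase = conn_phase,
    exponents = exponents,
    learn = learn,
    learn_params = list(lambda = lambda, mu1 = mu1, mu2 = mu2,
                        kappa = kappa, tau = tau),
    freq_scaling = freq_scaling,
    stimulus_gain = stimulus_gain
  ), class = "hopf_network")
}

#' @export
print.hopf_network <- function(x, ...) {
  cat(sprintf("<hopf_network> 3 layers x %d oscillators, %.3g-%.3g Hz (log-spaced)\n",
              x$n_osc, min(x$freqs), max(x$freqs)))
  cat(sprintf("  layer 1 (auditory): alpha=%g beta1=%g beta2=%g\n",
              x$layers[[1]]$alpha, x$layers[[1]]$beta1, x$layers[[1]]$beta2))
  cat(sprintf("  layer 2 (motor planning): alpha=%g beta1=%g beta2=%g; %d learned connections from layer 1 (|c0|=%g)\n",
              x$layers[[2]]$alpha, x$layers[[2]]$beta1, x$layers[[2]]$beta2,
              nrow(x$mask), x$conn_init))
  cat(sprintf("  layer 3 (groove): fixed 1:1 couplings w23=%g (excitatory), w13=%g (inhibitory)\n",
              x$w23, x$w13))
  invisible(x)
}

#' Simulate a three-layer Hopf network driven by a complex stimulus
#'
#' Integrates all oscillator and learned-connection ODEs with fixed-step RK4.
#' Initial oscillator states are drawn at random (seeded): layer 1 uniformly
#' in a disk of radius 0.01, layers 2 and 3 at rest up to 1e-4 noise; initial
#' connection phases are uniform.  The dynamics themselves are deterministic,
#' so identical seed and inputs give bit-identical trajectories.
#'
#' @param object A [hopf_network()].
#' @param nsim Unused (one trajectory per call); present for the generic.
#' @param seed Integer seed for the initial conditions.
#' @param stimulus Complex vector sampled at `1/dt` (e.g. from
#'   [pulse_signal()] + [analytic_signal()]), or `NULL` for a zero-input run
#'   of `duration` seconds.
#' @param dt Integration step in seconds (default 1/480).
#' @param duration Duration for `stimulus = NULL` runs.
#' @param track Optional data frame with columns `layer` (1-3) and `osc`
#'   (1-based oscillator index) whose full trajectories are kept.
#' @param init Optional list overriding the random initial conditions: any
#'   of `z1`, `z2`, `z3` (complex vectors of length `n_osc`) and `c0`
#'   (complex vector, one per connection).
#' @param ... Unused.
#' @return An object of class `hopf_sim`: complex `mean_fields` (3 x steps+1),
#'   `fs = 1/dt`, `time`, tracked trajectories, final states `z_final`,
#'   final connections `c_final`, and the seed.
#' @export
simulate.hopf_network <- function(object, nsim = 1, seed = NULL,
                                  stimulus = NULL, dt = 1/480,
                                  duration = 16, track = NULL,
                                  init = NULL, ...) {
  if (dt > 1 / (20 * max(object$freqs)))
    stop("dt too large: need dt <= 1/(20 * f_max)")
  if (is.null(stimulus)) {
    stimulus <- complex(real = numeric(round(duration / dt) + 1))
  }
  stimulus <- as.complex(stimulus)
  if (!is.null(seed)) set.seed(as.integer(seed))
  N <- object$n_osc
  r1 <- 0.01 * sqrt(stats::runif(N)); th1 <- stats::runif(N, 0, 2 * pi)
  z1_0 <- complex(modulus = r1, argument = th1)
  z2_0 <- complex(modulus = 1e-4 * sqrt(stats::runif(N)),
                  argument = stats::runif(N, 0, 2 * pi))
  z3_0 <- complex(modulus = 1e-4 * sqrt(stats::runif(N)),
                  argument = stats::runif(N, 0, 2 * pi))
  M <- nrow(object$mask)
  c0 <- complex(modulus = rep(object$conn_init, M),
                argument = if (identical(object$conn_phase, "random"))
                  stats::runif(M, 0, 2 * pi) else rep(0, M))
  if (!is.null(init)) {
    if (!is.null(init$z1)) z1_0 <- as.complex(init$z1)
    if (!is.null(init$z2)) z2_0 <- as.complex(init$z2)
    if (!is.null(init$z3)) z3_0 <- as.complex(init$z3)
    if (!is.null(init$c0)) c0 <- as.complex(init$c0)
    stopifnot(length(z1_0) == N, length(z2_0) == N, length(z3_0) == N,
              length(c0) == M)
  }
  if (is.null(track)) track <- data.frame(layer = integer(0), osc = integer(0))
  lp <- object$learn_params
  pars <- t(vapply(object$layers,
                   function(p) c(p$alpha, p$beta1, p$beta2, p$delta1, p$delta2),
                   numeric(5)))
  res <- .hopf_simulate_cpp(object$freqs, pars,
                            as.integer(object$mask$target - 1L),
                            as.integer(object$mask$source - 1L),
                            c0,
                            as.integer(object$mask$k),
                            as.integer(object$mask$m),
                            object$learn, lp$lambda, lp$mu1, lp$mu2,
                            lp$kappa, lp$tau,
                            object$w23, object$w13,
                            stimulus, as.numeric(object$stimulus_gain),
                            dt, object$freq_scaling,
                            z1_0, z2_0, z3_0,
                            as.integer(track$layer - 1L),
                            as.integer(track$osc - 1L))
  structure(list(
    mean_fields = res$mean_fields,
    tracked = res$tracked,
    track = track,
    z_final = res$z_final,
    c_final = res$c_final,
    fs = 1 / dt,
    time = (seq_len(ncol(res$mean_fields)) - 1) * dt,
    seed = seed,
    model = object
  ), class = "hopf_sim")
}

#' @export
print.hopf_sim <- function(x, ...) {
  cat(sprintf("<hopf_sim> %0.3g s at %g Hz; final layer mean-field magnitudes: %s\n",
              max(x$time), x$fs,
              paste(signif(Mod(x$mean_fields[, ncol(x$mean_fields)]), 3),
                    collapse = ", ")))
  invisible(x)
}

#' Mean field (oscillator average) of one layer
#'
#' @param sim A `hopf_sim` from [simulate.hopf_network()].
#' @param layer Layer index 1-3.
#' @return Complex time series with attribute `fs`.
#' @export
mean_field <- function(sim, layer) {
  stopifnot(inherits(sim, "hopf_sim"), layer %in% 1:3)
  structure(sim$mean_fields[layer, ], fs = sim$fs)
}

#' Fourier amplitude of a mean field at (the bin nearest) a target frequency
#'
#' The first part of the simulation (default 2 s) is discarded as the evoked
#' transient; the Fourier amplitude of the remaining window is read at the
#' FFT bin nearest `f` (the attained bin is recorded in `attr(, "bin_freq")`).
#' Amplitude is reported as `2 |X_k| / n`, so a mean field
#' `A*exp(i*2*pi*f*t)` on a bin-centred frequency returns... its one-sided
#' amplitude `A` (complex series are projected on `exp(-i 2 pi f t)`; see
#' Details).
#'
#' @details For the complex-valued mean field the amplitude at `+f` is
#' `|X_k| / n` where `X_k` is the (unnormalized) DFT coefficient at bin `k`;
#' for real-valued input this equals half the usual one-sided amplitude, so
#' the value is doubled when the input is real.
#'
#' @param x Complex (or real) time series with attribute `fs`, or a
#'   `hopf_sim` (then give `layer`).
#' @param f Target frequency in Hz (default 2, the beat rate).
#' @param window Analysis window in seconds (default `c(2, 16)`).
#' @param layer Layer index when `x` is a `hopf_sim`.
#' @return Non-negative amplitude with attribute `bin_freq`.
#' @export
amplitude_at_beat <- function(x, f = 2, window = c(2, 16), layer = NULL) {
  if (inherits(x, "hopf_sim")) {
    stopifnot(!is.null(layer))
    x <- mean_field(x, layer)
  }
  fs <- attr(x, "fs")
  if (is.null(fs)) stop("time series needs an 'fs' attribute")
  n_total <- length(x)
  i0 <- round(window[1] * fs) + 1L
  i1 <- round(window[2] * fs)
  if (i1 > n_total) stop("window longer than simulation")
  seg <- x[i0:i1]
  n <- length(seg)
  fr <- (seq_len(n) - 1) * fs / n
  X <- stats::fft(seg)
  k <- which.min(abs(fr - f))
  amp <- Mod(X[k]) / n
  if (is.double(x) && !is.complex(x)) amp <- 2 * amp
  structure(amp, bin_freq = fr[k])
}

#' Build the complex stimulus drive for a rhythm pattern
#'
#' Renders the melody onsets as pulses, optionally adds the strictly
#' periodic drum-beat click track (one pulse per beat, present in every
#' melody and identical across syncopation conditions -- coinciding drum
#' and bass onsets simply sum), repeats the result to `duration` seconds,
#' scales by `amplitude`, and takes the analytic signal.
#'
#' @param pattern A [rhythm_pattern()] (the bass line; the syncopation index
#'   is computed on this pattern alone).
#' @param fs Sampling rate (use `1/dt` of the simulation).
#' @param amplitude Drive amplitude (default 0.25).
#' @param duration Target duration in seconds (pattern is tiled; default 16).
#' @param drum Add the beat-aligned drum track (default TRUE).
#' @param width,shape Passed to [pulse_signal()].
#' @return Complex vector of length `duration*fs + 1`.
#' @export
stimulus_from_pattern <- function(pattern, fs, amplitude = 0.25,
                                  duration = 16, drum = TRUE,
                                  width = 0.025, shape = "rectangular") {
  x <- as.numeric(pulse_signal(pattern, fs, shape = shape, width = width,
                               amplitude = amplitude))
  if (drum) {
    g <- pattern$grid
    beats <- seq.int(0L, g$n_positions - 1L, by = g$subdivisions_per_beat)
    dr <- rhythm_pattern(g, beats)
    x <- x + as.numeric(pulse_signal(dr, fs, shape = shape, width = width,
                                     amplitude = amplitude))
  }
  n_target <- round(duration * fs)
  if (length(x) < n_target) x <- rep_len(x, n_target)
  x <- x[seq_len(n_target)]
  analytic_signal(c(x, x[1]))   # one extra sample for the RK4 endpoint
}

#' Run protocol: beat-rate amplitudes for a set of melodies
#'
#' For each melody and run, builds the stimulus, simulates the network from
#' random (seeded) initial conditions, and extracts the 2-Hz mean-field
#' amplitude of each layer.  Per-run seeds are derived deterministically from
#' `base_seed`.  A failed integration aborts only that run (recorded in the
#' `failed` attribute), not the whole table.
#'
#' @param model A [hopf_network()].
#' @param melodies List of [rhythm_pattern()]s.
#' @param n_runs Runs per melody (default 29, one per simulated subject).
#' @param base_seed Integer.
#' @param stim_amplitude Onset-pulse drive amplitude (default 0.25).
#' @param dt Integration step (default 1/480 s).
#' @param duration Simulation length in seconds (default 16; 8-s melodies are
#'   duplicated as in the listening protocol).
#' @param f Readout frequency (default 2 Hz).
#' @param window Readout window (default `c(2, 16)` s, dropping the evoked
#'   transient).
#' @return A data frame (`beat_amplitude_table`) with columns `melody`,
#'   `run`, `layer`, `amplitude_2hz`, plus melody syncopation indices in
#'   attribute `syncopation`.
#' @export
run_protocol <- function(model, melodies, n_runs = 29, base_seed = 1,
                         stim_amplitude = 0.25, dt = 1/480, duration = 16,
                         f = 2, window = c(2, duration)) {
  stopifnot(length(melodies) > 0)
  fs <- 1 / dt
  rows <- list(); failed <- list()
  sync <- vapply(melodies, function(m) syncopation(m)$total, numeric(1))
  for (mi in seq_along(melodies)) {
    stim <- stimulus_from_pattern(melodies[[mi]], fs,
                                  amplitude = stim_amplitude,
                                  duration = duration)
    for (run in seq_len(n_runs)) {
      seed <- (as.integer(base_seed) * 10007L + mi * 101L + run) %% 2147483647L
      sim <- tryCatch(
        simulate(model, seed = seed, stimulus = stim, dt = dt),
        error = function(e) e)
      if (inherits(sim, "error")) {
        failed[[length(failed) + 1L]] <-
          list(melody = mi, run = run, message = conditionMessage(sim))
        next
      }
      amps <- vapply(1:3, function(l)
        as.numeric(amplitude_at_beat(sim, f = f, window = window, layer = l)),
        numeric(1))
      rows[[length(rows) + 1L]] <- data.frame(
        melody = mi, run = run, layer = 1:3, amplitude_2hz = amps)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("beat_amplitude_table", class(out))
  attr(out, "syncopation") <- sync
  attr(out, "failed") <- failed
  out
}

#' Write a beat-amplitude table to CSV
#' @param table A `beat_amplitude_table` from [run_protocol()].
#' @param path File path.
#' @export
write_beat_amplitudes_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Stable radial equilibrium of an isolated oscillator (closed form oracle)
#'
#' Solves `alpha + beta1*r^2 + beta2*r^4/(1-r^2) = 0` for `r` in (0, 1) by
#' root bracketing and returns all roots, ordered; the long-run amplitude of
#' an isolated oscillator sits at a stable root (the largest one in the
#' bistable regime, the unique small one in the critical regime).
#'
#' @param p A [hopf_params()].
#' @return Numeric vector of radial equilibria in (0, 1), possibly empty.
#' @export
radial_equilibria <- function(p) {
  g <- function(r) {
    r2 <- r^2
    p$alpha + p$beta1 * r2 + p$beta2 * r2^2 / (1 - r2)
  }
  rs <- seq(1e-6, 0.999, length.out = 4000)
  vals <- g(rs)
  roots <- numeric(0)
  sg <- sign(vals)
  idx <- which(sg[-1] * sg[-length(sg)] < 0)
  for (i in idx) {
    roots <- c(roots, stats::uniroot(g, c(rs[i], rs[i + 1]),
                                     tol = 1e-12)$root)
  }
  sort(roots)
}
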