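# Independent brute-force oracle for the syncopation index: for every onset,
# enumerate ALL silent positions before the next onset and score the
# best-rest difference directly, without reusing the package's scan.
brute_force_syncopation <- function(onsets, weights) {
  n <- length(onsets)
  notes <- which(onsets)
  total <- 0L
  for (i in notes) {
    later_notes <- notes[notes > i]
    stop_at <- if (length(later_notes)) min(later_notes) - 1L else n
    best <- -Inf
    j <- i + 1L
    while (j <= stop_at) {
      if (!onsets[j] && weights[j] > best) best <- weights[j]
      j <- j + 1L
    }
    if (is.finite(best) && best > weights[i]) total <- total + (best - weights[i])
  }
  total
}

# scalar RK4 for the radial amplitude ODE dr/dt = f*(alpha*r + b1*r^3 +
# b2*r^5/(1-r^2)) -- an integration oracle independent of the network code
radial_rk4 <- function(r0, p, f = 2, dt = 1/80, duration = 100) {
  g <- function(r) f * (p$alpha * r + p$beta1 * r^3 + p$beta2 * r^5 / (1 - r^2))
  r <- r0
  for (i in seq_len(round(duration / dt))) {
    k1 <- g(r); k2 <- g(r + dt * k1 / 2); k3 <- g(r + dt * k2 / 2)
    k4 <- g(r + dt * k3)
    r <- r + dt * (k1 + 2 * k2 + 2 * k3 + k4) / 6
  }
  r
}

# small rhythm fixture: 4/4, two subdivisions per beat, two notes per
# measure on beats 1 and 3
two_note_base <- function(n_measures = 4) {
  g <- beat_grid(2, 2, 4, n_measures)
  rhythm_pattern(g, seq(0, g$n_positions - 1, by = 4))
}

# feature cube with an additive effect planted at given vertices/frequency
# bins: power[trial, vertex, freq] = exp(noise) + size * sd(base) *
# regressor_z at the planted cells
planted_power_cube <- function(n_trials, n_vertices, freqs, vertices, bins,
                               regressor, size = 1, noise_sd = 0.3,
                               seed = 1) {
  set.seed(seed)
  z <- as.numeric(scale(regressor))
  p <- array(exp(rnorm(n_trials * n_vertices * length(freqs), 0, noise_sd)),
             c(n_trials, n_vertices, length(freqs)))
  for (tr in seq_len(n_trials))
    p[tr, vertices, bins] <- p[tr, vertices, bins] + size * noise_sd * z[tr]
  attr(p, "freqs") <- freqs
  p
}
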