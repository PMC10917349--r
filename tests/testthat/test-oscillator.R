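test_that("frequency grid is log-spaced with exact endpoints", {
  f <- frequency_grid(0.375, 12, 321)
  expect_length(f, 321)
  expect_equal(f[1], 0.375)
  expect_equal(f[321], 12)
  ratios <- f[-1] / f[-321]
  expect_equal(max(ratios) - min(ratios), 0, tolerance = 1e-12)
  expect_equal(ratios[1], (12 / 0.375)^(1 / 320))
  expect_equal(frequency_grid(1, 4, 3), c(1, 2, 4))
  # a grid frequency lies within one grid step of the 2-Hz beat
  step <- log(f[2] / f[1])
  expect_lt(min(abs(log(f) - log(2))), step)
  expect_error(frequency_grid(4, 2), "f_min")
})

test_that("oscillator derivative matches the canonical form", {
  p <- motor_regime()
  expect_equal(oscillator_derivative(0 + 0i, p, omega = 2 * pi, x = 0 + 0i),
               0 + 0i)
  # hand-evaluated at z = 0.3 + 0.2i
  z <- 0.3 + 0.2i
  r2 <- Mod(z)^2
  manual <- z * (complex(real = p$alpha, imaginary = 2 * pi) +
                   p$beta1 * r2 + p$beta2 * r2^2 / (1 - r2)) + 0.1
  expect_equal(oscillator_derivative(z, p, 2 * pi, 0.1 + 0i), manual)
  expect_error(oscillator_derivative(1.2 + 0i, p, 2 * pi), "unit disk")
})

test_that("radial equilibria solve the closed-form amplitude equation", {
  # bistable regime: -0.8 + 4 r^2 - 3 r^4/(1-r^2) = 0 at r^2 in {2/7, 0.4}
  r <- radial_equilibria(motor_regime())
  expect_equal(r, c(sqrt(2 / 7), sqrt(0.4)), tolerance = 1e-8)
  # near-critical regime: 1e-4 = 3 r^4/(1-r^2)
  r1 <- radial_equilibria(auditory_regime())
  expect_length(r1, 1)
  g <- function(r) 1e-4 - 3 * r^4 / (1 - r^2)
  expect_lt(abs(g(r1)), 1e-10)
})

test_that("isolated oscillators relax to the stable radial root", {
  net <- hopf_network(n_osc = 2, f_min = 2, f_max = 4, conn_init = 0,
                      learn = FALSE, w23 = 0, w13 = 0)
  roots <- radial_equilibria(motor_regime())
  sim <- simulate(net, seed = 1, duration = 30, dt = 1/160,
                  init = list(z2 = c(0.55 + 0i, 0.55 + 0i)),
                  track = data.frame(layer = 2, osc = 1))
  r_end <- Mod(sim$tracked[1, ncol(sim$tracked)])
  expect_equal(r_end, max(roots), tolerance = 1e-3)
  # independent scalar integration oracle agrees
  expect_equal(radial_rk4(0.55, motor_regime(), duration = 30), r_end,
               tolerance = 1e-3)
  # below the unstable root the state falls back to rest
  sim0 <- simulate(net, seed = 1, duration = 30, dt = 1/160,
                   init = list(z2 = c(0.5 + 0i, 0.5 + 0i)),
                   track = data.frame(layer = 2, osc = 1))
  expect_lt(Mod(sim0$tracked[1, ncol(sim0$tracked)]), 1e-3)
})

test_that("bistability persists under small perturbations of both attractors", {
  p <- motor_regime()
  roots <- radial_equilibria(p)
  hi <- max(roots); un <- min(roots)
  expect_equal(radial_rk4(hi + 1e-3, p, duration = 60), hi, tolerance = 1e-4)
  expect_equal(radial_rk4(hi - 1e-3, p, duration = 60), hi, tolerance = 1e-4)
  expect_lt(radial_rk4(1e-3, p, duration = 60), 1e-4)
  # the intermediate root is never an attractor
  expect_gt(radial_rk4(un + 1e-3, p, duration = 120), hi - 1e-3)
  expect_lt(radial_rk4(un - 1e-3, p, duration = 120), 1e-3)
})

test_that("coupling input reduces correctly per mode-locking ratio", {
  zs <- c(0.1 + 0.2i, 0.3 - 0.1i)
  zt <- 0.2 + 0.1i
  # 1:1 with a single real connection: x = w * z_j, independent of target
  expect_equal(coupling_input(zs[1], zt, 0.8 + 0i), 0.8 * zs[1])
  expect_equal(coupling_input(zs[1], 0.9i, 0.8 + 0i), 0.8 * zs[1])
  # 2:1 transmits the squared source state
  expect_equal(coupling_input(zs[1], zt, 0.5 + 0i, k = 2, m = 1),
               0.5 * zs[1]^2)
  # m > 1 engages the conjugate target state
  expect_equal(coupling_input(zs[1], zt, 0.5 + 0i, k = 1, m = 2),
               0.5 * zs[1] * Conj(zt))
  expect_equal(coupling_input(zs, zt, c(0, 0)), 0 + 0i)
  expect_error(coupling_input(zs, zt, 0.5 + 0i), "mismatch")
})

test_that("Hebbian derivative has the stated fixed points and decay", {
  lp <- list(lambda = -1, mu1 = 4, mu2 = -2.2, kappa = 0.2, tau = 1)
  expect_equal(hebbian_derivative(0 + 0i, lp, 0 + 0i, 0 + 0i), 0 + 0i)
  # kappa = 0, small |c|: rate ~ -c/tau
  lp0 <- lp; lp0$kappa <- 0
  expect_equal(hebbian_derivative(0.01 + 0i, lp0, 0.5 + 0i, 0.5 + 0i),
               -0.01 + 0i, tolerance = 1e-3)
  # with phase-locked unit-drive, |c| settles on a root of the radial
  # learning equation lambda*rho + mu1*rho^3 + mu2*rho^5/(1-rho^2) + kappa*D = 0
  D <- 0.25
  gc <- function(rho) lp$lambda * rho + lp$mu1 * rho^3 +
    lp$mu2 * rho^5 / (1 - rho^2) + lp$kappa * D
  root <- uniroot(gc, c(1e-6, 0.3), tol = 1e-12)$root
  # derivative vanishes at the root (real c, real drive)
  dz <- hebbian_derivative(complex(real = root), lp,
                           z_target = complex(real = sqrt(D)),
                           z_source = complex(real = sqrt(D)))
  expect_lt(Mod(dz), 1e-10)
  expect_error(hebbian_derivative(1 + 0i, lp, 0i, 0i), "unit disk")
})

test_that("network simulation is deterministic and respects initial regimes", {
  model <- hopf_network(n_osc = 41)
  sim1 <- simulate(model, seed = 9, duration = 4)
  sim2 <- simulate(model, seed = 9, duration = 4)
  expect_identical(sim1$mean_fields, sim2$mean_fields)
  sim3 <- simulate(model, seed = 10, duration = 4)
  expect_false(identical(sim1$mean_fields, sim3$mean_fields))
  # zero stimulus: motor layers stay at rest
  expect_lt(max(Mod(mean_field(sim1, 2))), 0.05)
  expect_lt(max(Mod(mean_field(sim1, 3))), 0.05)
})

test_that("a strong 2-Hz pulse drive makes the meter oscillator jump", {
  model <- hopf_network()
  g <- beat_grid(2, 2, 4, 4)
  beats <- rhythm_pattern(g, seq(0, 31, by = 2))
  fs <- 480
  stim <- stimulus_from_pattern(beats, fs, amplitude = 1, duration = 16)
  # drive for 8 s, then silence: the freed oscillator relaxes onto the
  # high-amplitude limit cycle
  stim[(8 * fs):length(stim)] <- 0 + 0i
  k2 <- which.min(abs(model$freqs - 2))
  sim <- simulate(model, seed = 4, stimulus = stim, dt = 1 / fs,
                  track = data.frame(layer = 2, osc = k2))
  r_end <- Mod(sim$tracked[1, ncol(sim$tracked)])
  expect_equal(r_end, sqrt(0.4), tolerance = 0.1 * sqrt(0.4))
})

test_that("driven layer-1 oscillators phase-lock to the stimulus rate", {
  model <- hopf_network(n_osc = 81)
  g <- beat_grid(2, 2, 4, 4)
  beats <- rhythm_pattern(g, seq(0, 31, by = 2))
  fs <- 480
  stim <- stimulus_from_pattern(beats, fs, amplitude = 0.25, duration = 16)
  k2 <- which.min(abs(model$freqs - 2))
  expect_lt(abs(model$freqs[k2] / 2 - 1), 0.02)
  sim <- simulate(model, seed = 5, stimulus = stim, dt = 1 / fs,
                  track = data.frame(layer = 1, osc = k2))
  tail_idx <- which(sim$time >= 12)
  dphi <- Arg(sim$tracked[1, tail_idx] *
                exp(-1i * 2 * pi * 2 * sim$time[tail_idx]))
  expect_lt(var(dphi), 0.01)
})

test_that("halving the integration step leaves 2-Hz amplitudes unchanged", {
  # smooth analytic drive sampled exactly at each rate, so the comparison
  # isolates integrator error from pulse-sampling differences
  model <- hopf_network(n_osc = 81)
  a <- sapply(c(480, 960), function(fs) {
    tt <- seq(0, 16, by = 1 / fs)
    stim <- 0.1 * exp(1i * 2 * pi * 2 * tt)
    sim <- simulate(model, seed = 2, stimulus = stim, dt = 1 / fs)
    as.numeric(amplitude_at_beat(sim, layer = 1))
  })
  expect_lt(abs(a[2] - a[1]) / a[1], 0.005)
})

test_that("mean field is the oscillator average", {
  net <- hopf_network(n_osc = 3, f_min = 1, f_max = 4, conn_init = 0,
                      learn = FALSE, w23 = 0, w13 = 0)
  sim <- simulate(net, seed = 1, duration = 2,
                  track = data.frame(layer = rep(1, 3), osc = 1:3))
  expect_equal(mean_field(sim, 1), structure(colMeans(sim$tracked), fs = sim$fs),
               tolerance = 1e-12)
  # convexity: |mean| never exceeds the largest oscillator magnitude
  expect_true(all(Mod(mean_field(sim, 1)) <=
                    apply(Mod(sim$tracked), 2, max) + 1e-12))
})

test_that("amplitude_at_beat reads the Fourier amplitude at the nearest bin", {
  fs <- 480
  tt <- seq(0, 16, by = 1 / fs)
  mf <- structure(0.3 * exp(1i * 2 * pi * 2 * tt), fs = fs)
  a <- amplitude_at_beat(mf)
  expect_equal(as.numeric(a), 0.3, tolerance = 1e-6)
  expect_equal(attr(a, "bin_freq"), 2)
  # global phase rotation leaves the amplitude unchanged
  expect_equal(as.numeric(amplitude_at_beat(mf * exp(1.3i))), 0.3,
               tolerance = 1e-6)
  expect_equal(as.numeric(amplitude_at_beat(structure(0 * mf, fs = fs))), 0)
  expect_error(amplitude_at_beat(mf, window = c(2, 30)), "window")
})

test_that("run protocol bookkeeping is exact and reproducible", {
  model <- hopf_network(n_osc = 21, f_min = 1, f_max = 4)
  mel <- list(two_note_base(1))
  tab <- run_protocol(model, mel, n_runs = 2, base_seed = 5, dt = 1/120,
                      duration = 4, window = c(1, 4))
  expect_identical(nrow(tab), 6L)               # 3 layers x 2 runs
  expect_identical(sort(unique(tab$layer)), 1:3)
  tab2 <- run_protocol(model, mel, n_runs = 2, base_seed = 5, dt = 1/120,
                       duration = 4, window = c(1, 4))
  expect_identical(tab, tab2)
  expect_true(all(tab$amplitude_2hz >= 0))
})
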