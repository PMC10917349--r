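test_that("source grids have exact counts, spacing and neighbour queries", {
  grid <- make_source_grid(1673)
  expect_identical(nrow(grid$coords), 1673L)
  # lattice spacing: nearest-neighbour distance equals the grid step
  set.seed(1)
  for (v in sample(1673, 10)) {
    nb <- nearest_vertices(grid, v, 6)
    d <- sqrt(rowSums(sweep(grid$coords[nb, ], 2, grid$coords[v, ])^2))
    expect_equal(min(d), grid$spacing, tolerance = 1e-9)
  }
  nb50 <- nearest_vertices(grid, 10, 50)
  expect_length(unique(nb50), 50)
  expect_false(10 %in% nb50)
  # query by coordinate
  nb_pt <- nearest_vertices(grid, c(0, 0, 0), 3)
  expect_length(nb_pt, 3)
  expect_error(make_source_grid(5e5), "infeasible")
  expect_error(make_source_grid(50), "100")
})

test_that("melody table and behavioural generator follow the study design", {
  cfg <- synth_config()
  mel <- melody_table(cfg, seed = 2)
  expect_identical(nrow(mel), 36L)
  expect_equal(as.integer(table(mel$condition)[c("low", "medium", "high")]),
               rep(12L, 3))
  expect_true(all(mel$syncopation[mel$condition == "low"] == 0))
  expect_true(all(mel$syncopation >= 0 & mel$syncopation <= 15))

  beh <- make_behavioral_data(cfg, seed = 2)
  expect_true(all(beh$ratings$rating >= 1 & beh$ratings$rating <= 7))
  expect_identical(nrow(beh$ratings), as.integer(36 * cfg$n_subjects))
  # noiseless link: exact quadratic
  beh0 <- make_behavioral_data(cfg, seed = 2, noise_sd = 0)
  mr0 <- mean_ratings(beh0$ratings)
  fit0 <- fit_quadratic(mel$syncopation, mr0$rating)
  expect_equal(fit0$adjusted_r_squared, 1, tolerance = 1e-9)
  # noisy link at study n: vertex recovered within 1 index unit
  mr <- mean_ratings(beh$ratings)
  fit <- fit_quadratic(mel$syncopation, mr$rating)
  expect_lt(abs(fit$vertex - cfg$rating_link$peak), 1)
  expect_identical(fit$curvature, -1)
  # taps concentrate at the beat
  f <- unlist(lapply(beh$taps, tap_frequency))
  h <- tap_histogram(f)
  expect_equal(h$frequency[which.max(h$count)], 2, tolerance = 0.06)
})

test_that("study configurations load from YAML and JSON", {
  f <- tempfile(fileext = ".yaml")
  writeLines(c("n_subjects: 4", "n_sources: 200", "noise_sd: 0.3"), f)
  cfg <- read_synth_config(f)
  expect_identical(cfg$n_subjects, 4L)
  expect_identical(cfg$n_sources, 200L)
  expect_equal(cfg$noise_sd, 0.3)
  expect_identical(cfg$n_channels, 248)        # untouched default
  j <- tempfile(fileext = ".json")
  jsonlite::write_json(list(n_melodies = 6, n_blocks = 1), j,
                       auto_unbox = TRUE)
  cfg2 <- read_synth_config(j)
  expect_identical(cfg2$n_melodies, 6L)
  writeLines("not_a_field: 1", f)
  expect_error(read_synth_config(f), "unknown configuration")
})

test_that("spectral-domain generation is seeded, structured and labelled", {
  cfg <- synth_config(n_subjects = 1, n_sources = 300, n_freqs = 30)
  grid <- make_source_grid(300)
  a <- synth_source_power(cfg, grid, seed = 5)
  b <- synth_source_power(cfg, grid, seed = 5)
  expect_identical(a$power, b$power)             # bit-identical regeneration
  d <- synth_source_power(cfg, grid, seed = 6)
  expect_false(identical(a$power, d$power))
  expect_identical(dim(a$power), c(144L, 300L, 30L))
  expect_identical(nrow(a$regressors), 144L)
  expect_true(all(table(a$regressors$melody) == cfg$n_blocks))
  # ground truth serialized alongside
  gt <- a$ground_truth
  expect_true(all(lengths(lapply(gt$effects, `[[`, "vertices")) > 0))
  expect_identical(gt$gradient$axis, 2)
  expect_true(all(a$power > 0))
})

test_that("planted effects scale power at exactly the configured cells", {
  cfg <- synth_config(n_sources = 200, n_freqs = 20, noise_sd = 0)
  grid <- make_source_grid(200)
  src <- synth_source_power(cfg, grid, seed = 7)
  gt <- src$ground_truth
  e1 <- gt$effects[[1]]                 # syncopation-linked
  zs <- as.numeric(scale(src$regressors$syncopation))
  hi <- which.max(zs); lo <- which.min(zs)
  v <- e1$vertices[1]; k <- e1$freq_bins[1]
  # noiseless: the power ratio between extreme trials is exp(size*noise_sd*dz)
  expect_equal(log(src$power[hi, v, k] / src$power[lo, v, k]),
               e1$size * cfg$noise_sd * (zs[hi] - zs[lo]), tolerance = 1e-9)
  # untouched cells are trial-invariant
  v0 <- setdiff(seq_len(200), unlist(lapply(gt$effects, `[[`, "vertices")))[1]
  expect_equal(src$power[hi, v0, k], src$power[lo, v0, k], tolerance = 1e-12)
})

test_that("null effects yield null decoding", {
  cfg <- synth_config(n_sources = 150, n_channels = 40, n_freqs = 12)
  cfg$effects <- lapply(cfg$effects, function(e) { e$size <- 0; e })
  grid <- make_source_grid(150)
  src <- synth_source_power(cfg, grid, seed = 8)
  chan <- mix_to_channels(src$power, grid, 40, seed = 8)
  prec <- decode_spectrum(chan, src$regressors$syncopation)
  expect_lt(max(abs(prec)), 0.35)
})

test_that("channel mixing preserves sources in the identity case and adds leakage otherwise", {
  cfg <- synth_config(n_sources = 120, n_freqs = 10)
  grid <- make_source_grid(120)
  src <- synth_source_power(cfg, grid, seed = 9)
  ident <- mix_to_channels(src$power, grid, n_channels = 120, leakage = 0)
  expect_equal(ident, src$power, tolerance = 1e-12, ignore_attr = TRUE)
  mixed <- mix_to_channels(src$power, grid, n_channels = 30, leakage = 30,
                           sensor_noise = 0.05, seed = 9)
  expect_identical(dim(mixed), c(144L, 30L, 10L))
  expect_true(all(mixed > 0))
  # planted source effect survives mixing
  prec <- decode_spectrum(mixed, src$regressors$syncopation)
  k2 <- which.min(abs(src$freqs - 2))
  expect_gt(prec[k2], 0.5)
  # doubling sensor noise lowers precision
  noisier <- mix_to_channels(src$power, grid, n_channels = 30, leakage = 30,
                             sensor_noise = 0.8, seed = 9)
  prec2 <- decode_spectrum(noisier, src$regressors$syncopation)
  expect_lt(prec2[k2], prec[k2])
})

test_that("time-domain generation carries gradient, effects and PAC ground truth", {
  cfg <- synth_config(n_sources = 100, n_melodies = 3, n_blocks = 1,
                      n_subjects = 1, n_freqs = 16, freq_range = c(1, 30),
                      sample_rate = 64)
  cfg$pac$center <- c(0, 0, 0); cfg$pac$radius <- 15
  cfg$effects <- list(list(regressor = "syncopation", bands = list(c(2, 2)),
                           centers = list(c(0, 30, 0)), radius = 15,
                           size = 1))
  grid <- make_source_grid(100)
  td <- generate_trials(cfg, grid, seed = 10, domain = "time")
  expect_s3_class(td$cube, "tf_cube")
  expect_identical(dim(td$cube$power)[1:2], c(3L, 100L))
  expect_true(length(td$ground_truth$pac$vertices) > 0)
  # PAC vertices show delta-phase -> fast-amplitude coupling
  comod <- suppressWarnings(pac_comodulogram(
    td$cube, locations = c(td$ground_truth$pac$vertices[1], 100),
    phase_freqs = 1.4, amp_freqs = c(10, 25)))
  v_pac <- td$ground_truth$pac$vertices[1]
  rho_pac <- comod$rho[comod$location == v_pac &
                         abs(comod$amp_freq - 25) < 2]
  rho_ctrl <- comod$rho[comod$location == 100 &
                          abs(comod$amp_freq - 25) < 2]
  expect_gt(rho_pac, rho_ctrl)
})
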