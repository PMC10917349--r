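test_that("metric weights follow the recursive subdivision convention", {
  g <- beat_grid(2, 2, 4, 1)
  expect_identical(as.integer(metric_weights(g)),
                   c(0L, -3L, -2L, -3L, -1L, -3L, -2L, -3L))
  # degenerate single-level tree: all weights equal
  g1 <- beat_grid(2, 1, 1, 3)
  expect_true(all(as.integer(metric_weights(g1)) == 0L))
  # weights repeat identically across measures
  g2 <- beat_grid(2, 2, 4, 2)
  w2 <- as.integer(metric_weights(g2))
  expect_identical(w2[1:8], w2[9:16])
  # ternary split supported; primes beyond 2/3 rejected with a clear error
  g3 <- beat_grid(2, 3, 2, 1)
  expect_identical(as.integer(metric_weights(g3)), c(0L, -2L, -2L, -1L, -2L, -2L))
  expect_error(metric_weights(beat_grid(2, 1, 5, 1)), "beats_per_measure")
})

test_that("syncopation index scores note->rest successions against the oracle", {
  g <- beat_grid(2, 2, 4, 1)
  w <- metric_weights(g)
  # every onset on a beat: no off-beat notes, index 0
  expect_identical(syncopation(rhythm_pattern(g, c(0, 2, 4, 6)), w)$total, 0L)
  # all-silent pattern: zero total, no events
  s0 <- syncopation(rhythm_pattern(g, integer(0)), w)
  expect_identical(s0$total, 0L)
  expect_identical(nrow(s0$events), 0L)
  # hand-built syncopated pattern: off-beat note before a strong-beat rest
  g2 <- beat_grid(2, 2, 4, 2)
  w2 <- metric_weights(g2)
  p <- rhythm_pattern(g2, c(0, 3, 8, 12))   # note on pos 3 (w -3), rest on 4 (w -1)
  s <- syncopation(p, w2)
  expect_identical(s$total,
                   brute_force_syncopation(p$onsets, as.integer(w2)))
  expect_true(all(s$events$weight_difference > 0))
  expect_identical(s$total, sum(s$events$weight_difference))
})

test_that("syncopation matches exhaustive enumeration on all 8-position patterns", {
  g <- beat_grid(2, 2, 4, 1)
  w <- metric_weights(g)
  wi <- as.integer(w)
  for (code in 0:255) {
    onsets <- as.logical(bitwAnd(code, 2^(0:7)))
    p <- rhythm_pattern(g, onsets)
    expect_identical(syncopation(p, w)$total,
                     brute_force_syncopation(onsets, wi))
  }
})

test_that("syncopation matches the oracle on random 16-position patterns", {
  g <- beat_grid(2, 2, 4, 2)
  w <- metric_weights(g)
  wi <- as.integer(w)
  set.seed(42)
  for (i in 1:300) {
    onsets <- runif(16) < 0.4
    expect_identical(syncopation(rhythm_pattern(g, onsets), w)$total,
                     brute_force_syncopation(onsets, wi))
  }
})

test_that("periodic patterns are invariant to measure order", {
  g <- beat_grid(2, 2, 4, 2)
  w <- metric_weights(g)
  one <- c(0, 3, 4)                       # one measure's content
  tiled <- rhythm_pattern(g, c(one, one + 8))
  swapped <- rhythm_pattern(g, c(one + 8, one))   # same pattern, by periodicity
  expect_identical(syncopation(tiled, w)$total, syncopation(swapped, w)$total)
})

test_that("syncopation_family hits requested levels and is deterministic", {
  base <- two_note_base()
  levels <- c(0, 5, 10)
  fam <- syncopation_family(base, levels, seed = 3)
  ach <- vapply(fam, function(p) syncopation(p)$total, integer(1))
  expect_identical(as.integer(ach), as.integer(levels))
  # note counts preserved
  expect_true(all(vapply(fam, function(p) sum(p$onsets), integer(1)) ==
                    sum(base$onsets)))
  # achieved indices non-decreasing in requested levels
  expect_false(is.unsorted(ach))
  # determinism / seed dependence
  fam2 <- syncopation_family(base, levels, seed = 3)
  expect_identical(lapply(fam, `[[`, "onsets"), lapply(fam2, `[[`, "onsets"))
  fam3 <- syncopation_family(base, levels, seed = 4)
  ach3 <- vapply(fam3, function(p) syncopation(p)$total, integer(1))
  expect_identical(as.integer(ach3), as.integer(levels))
})

test_that("unreachable family levels warn and report the best achieved value", {
  base <- two_note_base(1)                 # 2 notes: max reachable index is small
  expect_warning(fam <- syncopation_family(base, c(40), seed = 1,
                                           max_iter = 200),
                 "unreachable")
  expect_lt(attr(fam[[1]], "achieved_level"), 40)
})

test_that("pulse trains are placed and scaled correctly", {
  g <- beat_grid(2, 1, 4, 1)
  p <- rhythm_pattern(g, 0:3)
  fs <- 1000
  x <- pulse_signal(p, fs, shape = "rectangular", width = 0.010)
  expect_length(x, 2 * fs)
  on_times <- (which(x > 0) - 1) / fs
  expect_true(all(abs((on_times %% 0.5) - 0.25) >= 0.24 - 0.006 |
                    on_times %% 0.5 <= 0.006))
  # pulse area: n_onsets * width * amplitude (rectangular)
  expect_equal(sum(x) / fs, 4 * 0.010, tolerance = 0.15)
  # raised cosine halves the area
  xc <- pulse_signal(p, fs, shape = "raised_cosine", width = 0.010)
  expect_equal(sum(xc) / fs, 4 * 0.010 / 2, tolerance = 0.15)
  # silent pattern gives a zero signal
  expect_true(all(pulse_signal(rhythm_pattern(g, integer(0)), fs) == 0))
  # overlapping pulses are an error
  expect_error(pulse_signal(p, fs, width = 0.60), "overlap")
  expect_error(pulse_signal(p, 7), "sample_rate")
})

test_that("analytic signal has the Hilbert-transform properties", {
  t <- seq(0, 4, by = 1/200)
  x <- cos(2 * pi * 2 * t)
  z <- analytic_signal(x)
  expect_equal(Re(z), x, tolerance = 1e-10)
  mid <- seq(100, length(t) - 100)
  expect_true(all(abs(Mod(z[mid]) - 1) < 0.01))
  expect_true(all(Mod(z) >= abs(Re(z)) - 1e-12))
  expect_true(all(analytic_signal(numeric(8)) == 0))
  expect_error(analytic_signal(numeric(0)), "empty")
})

test_that("rhythm JSON and onset-CSV round-trips preserve the pattern", {
  p <- two_note_base(2)
  f <- tempfile(fileext = ".json")
  write_rhythm_json(p, f)
  q <- read_rhythm_json(f)
  expect_identical(q$onsets, p$onsets)
  expect_equal(q$grid$duration, p$grid$duration)

  csv <- tempfile(fileext = ".csv")
  write.csv(data.frame(time = p$grid$position_times[p$onsets]), csv,
            row.names = FALSE)
  r <- read_onsets_csv(csv, p$grid)
  expect_identical(r$onsets, p$onsets)
  # off-grid onsets warn
  write.csv(data.frame(time = c(0, 0.37)), csv, row.names = FALSE)
  expect_warning(read_onsets_csv(csv, p$grid), "quarter subdivision")

  s <- syncopation(p)
  sj <- tempfile(fileext = ".json")
  write_syncopation_json(s, sj)
  doc <- jsonlite::read_json(sj, simplifyVector = TRUE)
  expect_equal(doc$total, s$total)
})
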