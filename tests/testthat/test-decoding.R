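test_that("ridge weights solve the penalized normal equations", {
  set.seed(1)
  Z <- matrix(rnorm(40), 10, 4)
  x <- rnorm(10)
  w <- ridge_weights(Z, x, alpha = 2)
  # independent oracle: explicit inverse
  w_oracle <- solve(t(Z) %*% Z + 2 * diag(4)) %*% (t(Z) %*% x)
  expect_equal(w, as.numeric(w_oracle), tolerance = 1e-10)
  # single perfectly informative feature, no penalty
  expect_equal(unname(ridge_weights(cbind(x), x, alpha = 0)), 1,
               tolerance = 1e-10)
  # shrinkage limit
  expect_lt(max(abs(ridge_weights(Z, x, alpha = 1e9))), 1e-6)
  # collinear features without penalty
  Zc <- cbind(Z[, 1], Z[, 1])
  expect_error(ridge_weights(Zc, x, alpha = 0), "alpha")
})

test_that("interleaved folds give the stated train/test split sizes", {
  folds <- interleaved_folds(144, 10)
  sizes <- tabulate(folds, 10)
  expect_true(all(sizes %in% c(14, 15)))
  expect_identical(sum(sizes), 144L)
  expect_true(all((144 - sizes) %in% c(129, 130)))
  # assignment is deterministic from row order
  expect_identical(folds[1:12], c(1:10, 1L, 2L))
})

test_that("cross-validated decoding recovers noiseless signal and is leakage-free", {
  set.seed(2)
  Z <- matrix(rnorm(144 * 12), 144, 12)
  beta <- rnorm(12)
  x <- drop(Z %*% beta)
  pred <- crossval_decode(Z, x)
  expect_gt(cor(pred, x), 0.999)
  # every row predicted exactly once: deterministic repeat
  expect_identical(pred, crossval_decode(Z, x))
  # leakage check: fold-3 weights come from the training partition only, so
  # corrupting fold 3's features leaves them (and the standardization
  # statistics) unchanged -- fold-3 predictions are the corrupted features
  # projected on weights fitted from clean data
  folds <- interleaved_folds(144, 10)
  Zc <- Z
  Zc[folds == 3, ] <- Zc[folds == 3, ] + 100
  tr <- folds != 3
  mu <- colMeans(Z[tr, ]); sd_ <- apply(Z[tr, ], 2, sd)
  w_clean <- ridge_weights(scale(Z[tr, ], mu, sd_), x[tr])
  w_corrupt <- ridge_weights(scale(Zc[tr, ], mu, sd_), x[tr])
  expect_identical(w_clean, w_corrupt)
  pred_c <- crossval_decode(Zc, x)
  manual <- drop(scale(Zc[folds == 3, ], mu, sd_) %*% w_clean)
  expect_equal(unname(pred_c[folds == 3]), unname(manual), tolerance = 1e-12)
  expect_error(crossval_decode(Z[1:5, ], x[1:5], n_folds = 10), "folds")
})

test_that("permuted regressors have null mean precision", {
  set.seed(3)
  Z <- matrix(rnorm(80 * 6), 80, 6)
  x <- rnorm(80)
  prec <- replicate(100, {
    xp <- sample(x)
    coding_precision(crossval_decode(Z, xp), xp)
  })
  expect_lt(abs(mean(prec)), 0.05)
})

test_that("coding precision is the capped Fisher-z correlation", {
  set.seed(4)
  x <- rnorm(50)
  noise <- rnorm(50)
  pred <- x + noise * sqrt(3)            # r ~ 0.5
  r <- cor(pred, x)
  expect_equal(coding_precision(pred, x), atanh(r), tolerance = 1e-12)
  expect_equal(atanh(0.5), 0.5493, tolerance = 1e-4)
  # antisymmetry and zero cases
  expect_equal(coding_precision(-pred, x), -coding_precision(pred, x))
  expect_equal(coding_precision(rep(1, 50), x), 0)
  # degenerate perfect predictions stay finite
  expect_lt(coding_precision(x, x), 8)
  expect_error(coding_precision(pred, rep(1, 50)), "constant")
})

test_that("precision is invariant to affine transforms of the regressor", {
  set.seed(5)
  Z <- matrix(rnorm(60 * 5), 60, 5)
  x <- drop(Z %*% rnorm(5)) + rnorm(60)
  p1 <- coding_precision(crossval_decode(Z, x), x)
  x2 <- 3 * x - 10
  p2 <- coding_precision(crossval_decode(Z, x2), x2)
  expect_equal(p1, p2, tolerance = 1e-10)
})

test_that("searchlight decoding localizes a planted cluster effect", {
  set.seed(6)
  grid <- make_source_grid(150)
  freqs <- c(1, 2, 4, 8, 16, 32)
  center <- grid$coords[1, ]               # central vertex of the lattice
  cl <- c(1, nearest_vertices(grid, 1, 7))
  x <- rnorm(60)
  p <- planted_power_cube(60, 150, freqs, cl, bins = 2, regressor = x,
                          size = 2.5, seed = 6001)
  prec <- searchlight_decode(p, grid, x, n_neighbors = 20)
  top <- which.max(prec)
  dist_top <- sqrt(sum((grid$coords[top, ] - center)^2))
  expect_lte(dist_top, 2 * grid$spacing)
  # shuffled regressor: map mean near zero
  prec0 <- searchlight_decode(p, grid, sample(x), n_neighbors = 20)
  expect_lt(abs(mean(prec0)), 0.1)
  # band restriction away from the planted frequency abolishes the effect
  # (cluster-mean precision drops by at least 80%)
  prec_band <- searchlight_decode(p, grid, x, n_neighbors = 20,
                                  band = c(6, 40))
  expect_lt(mean(prec_band[cl]), 0.2 * mean(prec[cl]))
  expect_error(searchlight_decode(p, grid, x, n_neighbors = 200), "vertices")
})

test_that("ROI decoding selects 20-vertex ROIs with peaks at planted bins", {
  set.seed(7)
  grid <- make_source_grid(120)
  freqs <- c(1, 2, 4, 8, 16)
  cl <- c(5, nearest_vertices(grid, 5, 9))
  x <- rnorm(100)
  p <- planted_power_cube(100, 120, freqs, cl, bins = 2, regressor = x,
                          size = 2.5, seed = 7001)
  map <- searchlight_decode(p, grid, x, n_neighbors = 15)
  roi <- roi_decode(map, p, grid, x, n_rois = 3, n_vertices = 20)
  expect_true(all(lengths(roi$rois) == 20))
  expect_identical(length(unique(unlist(roi$rois))), 60L)   # non-overlapping
  expect_identical(which.max(roi$precision[1, ]), 2L)       # peak at 2 Hz
  # within the top ROI the planted bin dominates the null bins
  expect_gt(roi$precision[1, 2], 3 * max(abs(roi$precision[1, -2])))
  # an ROI fully outside the planted cluster stays comparatively flat
  null_roi <- which.min(vapply(roi$rois,
                               function(r) length(intersect(r, cl)),
                               integer(1)))
  expect_lt(max(roi$precision[null_roi, ]), 0.5 * roi$precision[1, 2])
  expect_error(roi_decode(map, p, grid, x, n_rois = 10, n_vertices = 20),
               "vertex count")
})

test_that("precision contrasts are paired, signed and symmetric", {
  set.seed(8)
  A <- matrix(rnorm(20 * 6, mean = 0.3), 20, 6)
  B <- matrix(rnorm(20 * 6), 20, 6)
  ct <- contrast_precision(A, B)
  expect_equal(ct$difference, colMeans(A - B), tolerance = 1e-12)
  ct_rev <- contrast_precision(B, A)
  expect_equal(ct$difference, -ct_rev$difference)
  expect_equal(ct$p, ct_rev$p)
  # identical maps: zero difference, flagged p
  ct0 <- contrast_precision(A, A)
  expect_true(all(ct0$difference == 0))
  expect_true(all(is.na(ct0$p)))
  expect_error(contrast_precision(A, B[, 1:3]), "mismatch")
})

test_that("group precision test matches t.test", {
  set.seed(9)
  prec <- matrix(rnorm(15 * 4, mean = 0.2), 15, 4)
  gt <- group_precision_test(prec)
  ref <- t.test(prec[, 2])
  expect_equal(gt$p[2], ref$p.value, tolerance = 1e-12)
  expect_equal(gt$t[2], unname(ref$statistic), tolerance = 1e-12)
})

test_that("Storey FDR estimates pi0 and always flags extreme signals", {
  set.seed(10)
  p <- c(1e-10, runif(499))
  fdr <- storey_fdr(p)
  expect_true(fdr$significant[1])
  expect_true(fdr$pi0 > 0 && fdr$pi0 <= 1)
  # fully null input: pi0 near 1
  pi0s <- replicate(40, storey_fdr(runif(1000))$pi0)
  expect_gt(median(pi0s), 0.8)
  expect_lt(median(pi0s), 1.2)
  # q-values are monotone in p
  o <- order(p)
  expect_false(is.unsorted(fdr$q_values[o]))
  expect_error(storey_fdr(numeric(0)), "empty")
  expect_error(storey_fdr(c(0.5, 2)), "0, 1")
})
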