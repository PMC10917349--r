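#' Ridge regression weights (normal-equations form)
#'
#' `w = (Z'Z + alpha*I)^{-1} Z'x` with `I` the p x p identity, p = number of
#' features.  `Z` is expected to be column-standardized on the training
#' partition (see [crossval_decode()]).
#'
#' @param Z Feature matrix (exemplars x features), no missing values.
#' @param x Regressor, one value per exemplar.
#' @param alpha Ridge penalty (default 2).
#' @return Numeric weight vector of length `ncol(Z)`.
#' @export
ridge_weights <- function(Z, x, alpha = 2) {
  Z <- as.matrix(Z)
  stopifnot(nrow(Z) == length(x), alpha >= 0, !anyNA(Z), !anyNA(x))
  A <- crossprod(Z) + diag(alpha, ncol(Z))
  b <- crossprod(Z, x)
  w <- tryCatch(solve(A, b), error = function(e)
    stop("singular system; use alpha > 0 with collinear features"))
  drop(w)
}

#' Interleaved cross-validation fold assignment
#'
#' Row `i` (1-based) goes to fold `((i - 1) mod n_folds) + 1`, so folds are
#' deterministic from row order.
#'
#' @param n Number of rows.
#' @param n_folds Number of folds (default 10).
#' @return Integer fold id per row.
#' @export
interleaved_folds <- function(n, n_folds = 10) {
  ((seq_len(n) - 1L) %% as.integer(n_folds)) + 1L
}

#' Cross-validated ridge decoding of a regressor from features
#'
#' For each of `n_folds` interleaved folds: features are z-scored using
#' means/sds estimated on the training partition only (and applied to the
#' test partition -- no leakage), ridge weights are fitted on the training
#' rows, and the held-out rows are predicted as `Z_test %*% w`.  Every row
#' is predicted exactly once.
#'
#' @param Z Feature matrix (exemplars x features).
#' @param x Regressor.
#' @param n_folds Number of folds (default 10).
#' @param alpha Ridge penalty (default 2).
#' @return Numeric vector of out-of-fold predictions (same length as `x`).
#' @export
crossval_decode <- function(Z, x, n_folds = 10, alpha = 2) {
  Z <- as.matrix(Z)
  n <- nrow(Z)
  if (n < n_folds) stop("fewer rows than folds")
  folds <- interleaved_folds(n, n_folds)
  if (min(tabulate(folds, n_folds)) < 2) stop("a fold has fewer than 2 rows")
  pred <- numeric(n)
  for (f in seq_len(n_folds)) {
    te <- folds == f
    tr <- !te
    mu <- colMeans(Z[tr, , drop = FALSE])
    sd <- apply(Z[tr, , drop = FALSE], 2, stats::sd)
    sd[sd == 0] <- 1
    Ztr <- sweep(sweep(Z[tr, , drop = FALSE], 2, mu), 2, sd, "/")
    Zte <- sweep(sweep(Z[te, , drop = FALSE], 2, mu), 2, sd, "/")
    w <- ridge_weights(Ztr, x[tr], alpha)
    pred[te] <- drop(Zte %*% w)
  }
  pred
}

#' Fisher-z coding precision
#'
#' `atanh(r)` of the Pearson correlation between predictions and truth,
#' capped at `|r| = 0.999999` so degenerate noiseless cases stay finite.
#'
#' @param pred Predicted regressor values.
#' @param truth True regressor values (non-constant, length >= 3).
#' @return Fisher-z precision (scalar).
#' @export
coding_precision <- function(pred, truth) {
  stopifnot(length(pred) == length(truth), length(truth) >= 3)
  if (stats::sd(truth) == 0) stop("constant truth regressor")
  if (stats::sd(pred) == 0) return(0)    # uninformative predictions
  r <- stats::cor(pred, truth)
  r <- max(min(r, 0.999999), -0.999999)
  atanh(r)
}

#' Frequency-wise whole-sensor decoding spectrum
#'
#' Decodes the regressor separately at each frequency, using all locations'
#' power at that frequency as features.
#'
#' @param power Array `trial` x `location` x `frequency` of time-averaged
#'   power.
#' @param x Regressor (one value per trial).
#' @param n_folds,alpha Passed to [crossval_decode()].
#' @return Numeric vector of Fisher-z precision per frequency.
#' @export
decode_spectrum <- function(power, x, n_folds = 10, alpha = 2) {
  stopifnot(length(dim(power)) == 3, dim(power)[1] == length(x))
  vapply(seq_len(dim(power)[3]), function(fi) {
    pred <- crossval_decode(power[, , fi], x, n_folds, alpha)
    coding_precision(pred, x)
  }, numeric(1))
}

#' Searchlight decoding over a source grid
#'
#' For each vertex, features are the (optionally band-restricted) power
#' spectra of the vertex and its `n_neighbors` nearest neighbours (Euclidean
#' distance); the regressor is decoded by cross-validated ridge and the
#' Fisher-z precision recorded.
#'
#' @param power Array `trial` x `vertex` x `frequency`.
#' @param grid A `source_grid` (see [make_source_grid()]) matching the
#'   vertex dimension.
#' @param x Regressor.
#' @param n_neighbors Neighbourhood size (default 50).
#' @param band Optional `c(lo, hi)` Hz restriction of the feature spectra.
#' @param n_folds,alpha Passed to [crossval_decode()].
#' @return Numeric vector of per-vertex precision.
#' @export
searchlight_decode <- function(power, grid, x, n_neighbors = 50,
                               band = NULL, n_folds = 10, alpha = 2) {
  stopifnot(length(dim(power)) == 3)
  nv <- dim(power)[2]
  if (nv != nrow(grid$coords)) stop("grid does not match cube locations")
  if (nv < n_neighbors + 1) stop("fewer than n_neighbors + 1 vertices")
  freqs <- attr(power, "freqs")
  fsel <- seq_len(dim(power)[3])
  if (!is.null(band)) {
    if (is.null(freqs)) stop("band restriction needs a 'freqs' attribute")
    fsel <- which(freqs >= band[1] & freqs <= band[2])
    if (!length(fsel)) stop("band excludes every frequency")
  }
  vapply(seq_len(nv), function(v) {
    nb <- c(v, nearest_vertices(grid, v, n_neighbors))
    Z <- power[, nb, fsel, drop = FALSE]
    dim(Z) <- c(dim(power)[1], length(nb) * length(fsel))
    pred <- crossval_decode(Z, x, n_folds, alpha)
    coding_precision(pred, x)
  }, numeric(1))
}

#' ROI selection and per-frequency ROI decoding
#'
#' Each ROI is the maximally (most positively) scoring vertex of a contrast
#' or precision map plus its `n_vertices - 1` nearest neighbours; within
#' each ROI the regressor is decoded frequency by frequency.
#'
#' @param map Per-vertex selection map (e.g. a contrast of precisions);
#'   ROI seeds are its successive maxima, excluding vertices already used.
#' @param power Array `trial` x `vertex` x `frequency`.
#' @param grid A `source_grid`.
#' @param x Regressor.
#' @param n_rois Number of ROIs (default 5).
#' @param n_vertices Vertices per ROI (default 20).
#' @param n_folds,alpha Passed to [crossval_decode()].
#' @return List with `rois` (vertex index sets) and `precision`
#'   (`n_rois` x `n_freq` matrix).
#' @export
roi_decode <- function(map, power, grid, x, n_rois = 5, n_vertices = 20,
                       n_folds = 10, alpha = 2) {
  nv <- nrow(grid$coords)
  if (n_rois * n_vertices > nv)
    stop("requested ROIs exceed the vertex count without overlap")
  used <- logical(nv)
  rois <- vector("list", n_rois)
  score <- as.numeric(map)
  for (r in seq_len(n_rois)) {
    cand <- which(!used)
    seed <- cand[which.max(score[cand])]
    nb <- c(seed, nearest_vertices(grid, seed, nv - 1))
    nb <- nb[!used[nb]][seq_len(n_vertices)]
    used[nb] <- TRUE
    rois[[r]] <- nb
  }
  nf <- dim(power)[3]
  prec <- matrix(NA_real_, n_rois, nf)
  for (r in seq_len(n_rois)) {
    for (fi in seq_len(nf)) {
      pred <- crossval_decode(power[, rois[[r]], fi], x, n_folds, alpha)
      prec[r, fi] <- coding_precision(pred, x)
    }
  }
  list(rois = rois, precision = prec)
}

#' Group-level test of precision maps against zero
#'
#' Two-tailed one-sample t-test per unit of analysis across subjects.
#'
#' @param prec Matrix `subject` x `unit` of Fisher-z precisions.
#' @return Data frame with per-unit `mean`, `t` and `p`.
#' @export
group_precision_test <- function(prec) {
  stopifnot(is.matrix(prec), nrow(prec) >= 2)
  n <- nrow(prec)
  m <- colMeans(prec)
  se <- apply(prec, 2, stats::sd) / sqrt(n)
  t <- m / se
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  data.frame(mean = m, t = t, p = p)
}

#' Paired contrast of two precision maps
#'
#' Per-unit paired difference of Fisher-z precisions (A - B) with a
#' two-tailed paired t-test across subjects.  Units with zero difference in
#' every subject get `p = NA` (flagged, not an error).
#'
#' @param A,B Matrices `subject` x `unit` with identical dimensions (same
#'   subjects, same units).
#' @return Data frame with `difference` (group mean), `t`, `p`.
#' @export
contrast_precision <- function(A, B) {
  if (!all(dim(A) == dim(B))) stop("subject/unit mismatch between maps")
  D <- A - B
  n <- nrow(D)
  m <- colMeans(D)
  sd <- apply(D, 2, stats::sd)
  t <- ifelse(sd > 0, m / (sd / sqrt(n)), NA_real_)
  p <- 2 * stats::pt(abs(t), df = n - 1, lower.tail = FALSE)
  data.frame(difference = m, t = t, p = p)
}

#' Storey false discovery rate: pi0 estimate, q-values and significance mask
#'
#' Estimates the null proportion pi0 on the lambda grid
#' `pi0(lambda) = #\{p > lambda\} / (n (1 - lambda))`, smooths pi0(lambda)
#' with a cubic smoothing spline and takes the value at the largest lambda;
#' q-values follow Storey's step-up construction
#' `q(p_(i)) = min_{j >= i} pi0 * n * p_(j) / j`.
#'
#' @param p P-values in [0, 1] (NAs are ignored and returned as NA).
#' @param q_threshold Significance threshold on q-values (default 0.05).
#' @param lambda Grid for the pi0 estimate (default 0.05 to 0.95 by 0.05).
#' @return List of class `storey_fdr`: `pi0`, `q_values`, logical
#'   `significant` mask.
#' @export
storey_fdr <- function(p, q_threshold = 0.05,
                       lambda = seq(0.05, 0.95, by = 0.05)) {
  if (!length(p)) stop("empty p-value input")
  na <- is.na(p)
  pv <- p[!na]
  if (!length(pv)) stop("all p-values are NA")
  if (any(pv < 0 | pv > 1)) stop("p-values must lie in [0, 1]")
  n <- length(pv)
  pi0_l <- vapply(lambda, function(l) mean(pv > l) / (1 - l), numeric(1))
  if (length(lambda) >= 4 && stats::var(pi0_l) > 0) {
    sp <- stats::smooth.spline(lambda, pi0_l, df = 3)
    pi0 <- stats::predict(sp, x = max(lambda))$y
  } else {
    pi0 <- pi0_l[length(pi0_l)]
  }
  pi0 <- min(max(pi0, 1 / n), 1)
  o <- order(pv)
  ranked <- pi0 * n * pv[o] / seq_len(n)
  qv_sorted <- rev(cummin(rev(ranked)))
  qv_sorted <- pmin(qv_sorted, 1)
  qv <- numeric(n)
  qv[o] <- qv_sorted
  q_values <- rep(NA_real_, length(p))
  q_values[!na] <- qv
  structure(list(pi0 = pi0, q_values = q_values,
                 significant = !is.na(q_values) & q_values <= q_threshold,
                 q_threshold = q_threshold),
            class = "storey_fdr")
}

#' @export
print.storey_fdr <- function(x, ...) {
  cat(sprintf("<storey_fdr> pi0 = %.3f; %d of %d tests significant at q <= %g\n",
              x$pi0, sum(x$significant, na.rm = TRUE),
              length(x$q_values), x$q_threshold))
  invisible(x)
}
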