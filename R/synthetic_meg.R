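#' Volumetric source grid inside an ellipsoidal volume
#'
#' Lattice points at `spacing` mm inside an ellipsoid (semi-axes in mm,
#' MNI-like axis convention: x left-right, y posterior-anterior, z
#' inferior-superior), keeping the `n` points closest to the centre so the
#' count is exact.
#'
#' @param n Number of vertices (default 1673).
#' @param spacing Lattice spacing in mm (default 10).
#' @param semi_axes Ellipsoid semi-axes in mm.
#' @param seed Unused for the deterministic lattice; kept for interface
#'   stability.
#' @return A `source_grid`: list with `coords` (`n` x 3 matrix, mm) and
#'   `spacing`.
#' @export
make_source_grid <- function(n = 1673, spacing = 10,
                             semi_axes = c(72, 90, 65), seed = NULL) {
  if (n < 100) stop("need n >= 100")
  ax <- seq(-semi_axes[1], semi_axes[1], by = spacing)
  ay <- seq(-semi_axes[2], semi_axes[2], by = spacing)
  az <- seq(-semi_axes[3], semi_axes[3], by = spacing)
  g <- as.matrix(expand.grid(x = ax, y = ay, z = az))
  rho <- sqrt((g[, 1] / semi_axes[1])^2 + (g[, 2] / semi_axes[2])^2 +
                (g[, 3] / semi_axes[3])^2)
  if (sum(rho <= 1.05) < n)
    stop("infeasible vertex count for this spacing/volume")
  keep <- order(rho)[seq_len(n)]
  coords <- g[keep, , drop = FALSE]
  rownames(coords) <- NULL
  structure(list(coords = coords, spacing = spacing,
                 semi_axes = semi_axes),
            class = "source_grid")
}

#' @export
print.source_grid <- function(x, ...) {
  cat(sprintf("<source_grid> %d vertices at %g-mm spacing (semi-axes %s mm)\n",
              nrow(x$coords), x$spacing,
              paste(x$semi_axes, collapse = "/")))
  invisible(x)
}

#' Nearest neighbours of a vertex (or point) on a source grid
#'
#' @param grid A `source_grid`.
#' @param v Either a vertex index (length 1) or an xyz coordinate
#'   (length 3).
#' @param k Number of neighbours to return (excluding the vertex itself
#'   when `v` is an index).
#' @return Integer vector of `k` distinct vertex indices, nearest first.
#' @export
nearest_vertices <- function(grid, v, k) {
  co <- grid$coords
  if (length(v) == 1) {
    p <- co[v, ]
    d <- sqrt(rowSums(sweep(co, 2, p)^2))
    d[v] <- Inf
  } else {
    d <- sqrt(rowSums(sweep(co, 2, v)^2))
  }
  if (k > sum(is.finite(d))) stop("k exceeds available vertices")
  order(d)[seq_len(k)]
}

#' Synthetic-study configuration
#'
#' Default values mirror the emulated listening study: 29 subjects, 36
#' melodies (12 per syncopation condition) x 4 blocks = 144 trials, 1673
#' sources on a 10-mm grid mixed to 248 channels, 1/f background spectra, a
#' 4-to-30-Hz dominant-frequency gradient along the posterior-anterior (y)
#' axis, a syncopation-linked 2-Hz effect in two lateral "auditory" patches,
#' a rating-linked effect at 1.4 Hz and 20-30 Hz in a "dorsal" patch, and
#' delta-phase to beta-amplitude coupling in a sensorimotor patch.
#'
#' Effect sizes are expressed in units of the background log-power noise sd,
#' per sd of the (standardized) regressor.
#'
#' @param n_subjects,n_melodies,n_blocks,n_sources,n_channels Study counts.
#' @param n_freqs,freq_range Analysis frequency grid (log-spaced).
#' @param sample_rate,duration Time-domain generation parameters.
#' @param background_exponent 1/f exponent of the background power spectrum.
#' @param noise_sd Lognormal sd of per-trial power fluctuations.
#' @param gradient List: `axis` (1 = x, 2 = y, 3 = z), `f_lo`, `f_hi`,
#'   `amplitude` (bump height relative to background), `log_width`
#'   (bump width in natural-log frequency units).
#' @param effects List of planted condition effects: each has `regressor`
#'   (`"syncopation"` or `"rating"`), `bands` (list of `c(lo, hi)` Hz),
#'   `centers` (list of xyz mm), `radius` (mm), `size`.
#' @param pac List: `phase_freq`, `amp_freq`, `strength` in [0, 1],
#'   `center`, `radius`.
#' @param rating_link List: `peak` syncopation index of maximal rating,
#'   `r_max`, `curvature`, `noise_sd`, `scale_max`.
#' @param seed Default seed for generators.
#' @return A list of class `synth_config`.
#' @export
synth_config <- function(n_subjects = 29, n_melodies = 36, n_blocks = 4,
                         n_sources = 1673, n_channels = 248,
                         n_freqs = 100, freq_range = c(1, 100),
                         sample_rate = 128, duration = 16,
                         background_exponent = 1, noise_sd = 0.4,
                         gradient = list(axis = 2, f_lo = 4, f_hi = 30,
                                         amplitude = 4, log_width = 0.08),
                         effects = list(
                           list(regressor = "syncopation",
                                bands = list(c(2, 2)),
                                centers = list(c(55, -20, 0), c(-55, -20, 0)),
                                radius = 25, size = 0.5),
                           list(regressor = "rating",
                                bands = list(c(1.4, 1.4), c(20, 30)),
                                centers = list(c(-40, -10, 45)),
                                radius = 25, size = 0.5)),
                         pac = list(phase_freq = 1.4, amp_freq = 25,
                                    strength = 0.6,
                                    center = c(-45, 0, 40), radius = 20),
                         rating_link = list(peak = 7, r_max = 6.5,
                                            curvature = 0.07,
                                            noise_sd = 0.5, scale_max = 7),
                         seed = 1L) {
  structure(as.list(environment()), class = "synth_config")
}

#' Read a synthetic-study configuration from a YAML or JSON document
#'
#' Fields present in the document override the [synth_config()] defaults;
#' nested lists (`gradient`, `effects`, `pac`, `rating_link`) are replaced
#' wholesale when given.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A `synth_config` list.
#' @export
read_synth_config <- function(path) {
  doc <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
  cfg <- synth_config()
  unknown <- setdiff(names(doc), names(cfg))
  if (length(unknown))
    stop("unknown configuration fields: ", paste(unknown, collapse = ", "))
  cfg[names(doc)] <- doc
  class(cfg) <- "synth_config"
  cfg
}

#' Melody table: syncopation indices for the three conditions
#'
#' 12 low-syncopation melodies (index 0), 12 medium (indices 4-9) and 12
#' high (indices 10-15), deterministically from the seed.
#'
#' @param config A [synth_config()].
#' @param seed Seed (defaults to the config seed).
#' @return Data frame with `melody`, `condition`, `syncopation`.
#' @export
melody_table <- function(config = synth_config(), seed = config$seed) {
  set.seed(as.integer(seed))
  per <- config$n_melodies / 3
  sync <- c(rep(0, per),
            sample(4:9, per, replace = TRUE),
            sample(10:15, per, replace = TRUE))
  data.frame(melody = seq_len(config$n_melodies),
             condition = rep(c("low", "medium", "high"), each = per),
             syncopation = sync)
}

#' Synthetic behavioural data: groove ratings and finger taps
#'
#' Ratings follow a quadratic (inverted-U) link from the degree of
#' syncopation, with ordinal noise, clipped to the Likert scale; taps are
#' jittered 2-Hz metronomic sequences.
#'
#' @param config A [synth_config()].
#' @param seed Seed.
#' @param noise_sd Rating noise (defaults to the configured link value; 0
#'   gives the noiseless quadratic link).
#' @return List with `ratings` (participant x melody data frame), `taps`
#'   (list of tap-time vectors) and `melodies` (the melody table).
#' @export
make_behavioral_data <- function(config = synth_config(), seed = config$seed,
                                 noise_sd = config$rating_link$noise_sd) {
  mel <- melody_table(config, seed)
  set.seed(as.integer(seed) + 1L)
  link <- config$rating_link
  rows <- list()
  for (p in seq_len(config$n_subjects)) {
    mu <- link$r_max - link$curvature * (mel$syncopation - link$peak)^2
    r <- mu + stats::rnorm(nrow(mel), 0, noise_sd)
    if (noise_sd > 0) r <- round(r)
    r <- pmin(pmax(r, 1), link$scale_max)
    rows[[p]] <- data.frame(participant = p, melody = mel$melody,
                            condition = mel$condition, rating = r)
  }
  ratings <- do.call(rbind, rows)
  taps <- lapply(seq_len(config$n_subjects), function(p) {
    tt <- seq(0.25, config$duration - 0.25, by = 0.5)
    sort(tt + stats::rnorm(length(tt), 0, 0.02))
  })
  list(ratings = ratings, taps = taps, melodies = mel)
}

# per-trial regressors: melody order shuffled per subject, blocks appended
trial_regressors <- function(config, mel, ratings, seed) {
  set.seed(as.integer(seed) + 2L)
  mr <- mean_ratings(ratings)
  order_all <- unlist(lapply(seq_len(config$n_blocks), function(b)
    sample(config$n_melodies)))
  data.frame(trial = seq_along(order_all),
             melody = order_all,
             syncopation = mel$syncopation[order_all],
             rating = mr$rating[order_all])
}

#' Generate one subject's source-level trial power (spectral domain)
#'
#' Draws, per trial and vertex, a time-averaged power spectrum with: a 1/f
#' background; a narrowband bump at each vertex's gradient-determined
#' dominant frequency; multiplicative lognormal trial noise; and planted
#' regressor effects (multiplicative on the log scale, at the configured
#' vertices and bands).  This is the fast, statistically equivalent stand-in
#' for wavelet-decomposing the time-domain signals and time-averaging (see
#' [generate_trials()] with `domain = "time"` for that route).
#'
#' @param config A [synth_config()].
#' @param grid A `source_grid` with `config$n_sources` vertices.
#' @param seed Seed.
#' @return List: `power` (`trial` x `vertex` x `freq`, with `freqs`
#'   attribute), `regressors`, `ground_truth`.
#' @export
synth_source_power <- function(config = synth_config(),
                               grid = make_source_grid(config$n_sources,
                                                       spacing = config$spacing %||% 10),
                               seed = config$seed) {
  freqs <- exp(seq(log(config$freq_range[1]), log(config$freq_range[2]),
                   length.out = config$n_freqs))
  mel <- melody_table(config, seed)
  beh <- make_behavioral_data(config, seed)
  reg <- trial_regressors(config, mel, beh$ratings, seed)
  n_tr <- nrow(reg); nv <- nrow(grid$coords); nf <- length(freqs)

  gt <- synth_ground_truth(config, grid, freqs)
  base <- log(outer(rep(1, nv), freqs^(-config$background_exponent))) +
    log1p(gt$gradient$bump)                       # vertex x freq, log scale

  # planted effects on the log scale: effect_log[v, f, regressor]
  zsync <- scale(reg$syncopation)[, 1]
  zrate <- scale(reg$rating)[, 1]
  zreg <- cbind(syncopation = zsync, rating = zrate)

  set.seed(as.integer(seed) + 3L)
  # wavelet spectral estimates are correlated across neighbouring log-spaced
  # bins (Morlet spectral sd ~ f/8 vs. bin spacing f*dlog); emulate that by
  # smoothing the per-bin noise along frequency with the matching kernel
  dlog <- diff(log(freqs))[1]
  kern_sd <- 1 / (8 * dlog)                       # in bins
  power <- array(NA_real_, c(n_tr, nv, nf))
  eff_log <- gt$effect_log                        # list per effect: v x f matrix
  for (tr in seq_len(n_tr)) {
    lp <- base
    for (e in seq_along(eff_log))
      lp <- lp + eff_log[[e]] * zreg[tr, gt$effects[[e]]$regressor]
    noise <- smooth_freq_noise(nv, nf, kern_sd) * config$noise_sd
    power[tr, , ] <- exp(lp + noise)
  }
  attr(power, "freqs") <- freqs
  list(power = power, regressors = reg, ground_truth = gt, grid = grid,
       freqs = freqs)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# iid normal noise smoothed along the frequency axis with a Gaussian kernel
# (sd in bins), rescaled to unit marginal sd
smooth_freq_noise <- function(nv, nf, kern_sd) {
  m <- matrix(stats::rnorm(nv * nf), nv, nf)
  if (kern_sd <= 0.05) return(m)
  half <- max(1L, ceiling(3 * kern_sd))
  k <- stats::dnorm(seq(-half, half), sd = kern_sd)
  k <- k / sqrt(sum(k^2))                         # preserve marginal variance
  pad <- matrix(stats::rnorm(nv * 2 * half), nv, 2 * half)
  mp <- cbind(pad[, seq_len(half), drop = FALSE], m,
              pad[, half + seq_len(half), drop = FALSE])
  out <- matrix(0, nv, nf)
  for (j in seq_along(k))
    out <- out + k[j] * mp[, (j - 1) + seq_len(nf), drop = FALSE]
  out
}

# resolve the planted structure onto a concrete grid + frequency grid
synth_ground_truth <- function(config, grid, freqs) {
  ax <- config$gradient$axis
  co <- grid$coords[, ax]
  u <- (co - min(co)) / (max(co) - min(co))
  # log-linear progression along the coordinate: equal vertex population per
  # log-frequency band, matching the log spacing of neural rhythms
  f_dom <- exp(log(config$gradient$f_lo) +
                 u * (log(config$gradient$f_hi) - log(config$gradient$f_lo)))
  lw <- config$gradient$log_width
  bump <- config$gradient$amplitude *
    exp(-outer(log(f_dom), log(freqs), function(a, b) (b - a)^2) / (2 * lw^2))
  effects <- lapply(config$effects, function(e) {
    verts <- sort(unique(unlist(lapply(e$centers, function(cen) {
      # snap the centre onto the grid so patches stay populated on small
      # (down-scaled) grids whose extent may not reach the nominal centre
      cen <- grid$coords[nearest_vertices(grid, cen, 1), ]
      d <- sqrt(rowSums(sweep(grid$coords, 2, cen)^2))
      which(d <= e$radius)
    }))))
    bins <- sort(unique(unlist(lapply(e$bands, function(b) {
      k <- which(freqs >= b[1] & freqs <= b[2])
      if (!length(k)) k <- which.min(abs(freqs - mean(b)))
      k
    }))))
    c(e, list(vertices = verts, freq_bins = bins))
  })
  effect_log <- lapply(effects, function(e) {
    m <- matrix(0, nrow(grid$coords), length(freqs))
    m[e$vertices, e$freq_bins] <- e$size * config$noise_sd
    m
  })
  pac_cen <- grid$coords[nearest_vertices(grid, config$pac$center, 1), ]
  pac_d <- sqrt(rowSums(sweep(grid$coords, 2, pac_cen)^2))
  list(gradient = list(axis = ax, f_dom = f_dom, bump = bump,
                       f_lo = config$gradient$f_lo,
                       f_hi = config$gradient$f_hi),
       effects = effects, effect_log = effect_log,
       pac = c(config$pac, list(vertices = which(pac_d <= config$pac$radius))),
       freqs = freqs)
}

#' Mix source-level data to sensor channels
#'
#' Channels sit on an enlarged ellipsoid around the source volume; mixing
#' weights decay with source-channel distance
#' (`exp(-d^2 / (2 * leakage^2))`, rows normalized), plus optional sensor
#' noise.  With `n_channels` equal to the vertex count and `leakage = 0`
#' the mixing is the identity.
#'
#' @param power Array `trial` x `vertex` x `freq` of source power.
#' @param grid The `source_grid` the data live on.
#' @param n_channels Number of sensors (default 248).
#' @param leakage Spatial decay in mm (default 30).
#' @param sensor_noise Lognormal sd of multiplicative sensor noise
#'   (default 0).
#' @param seed Seed for the noise.
#' @return Array `trial` x `channel` x `freq` (with `freqs` carried over).
#' @export
mix_to_channels <- function(power, grid, n_channels = 248, leakage = 30,
                            sensor_noise = 0, seed = 1L) {
  nv <- dim(power)[2]
  if (leakage == 0 && n_channels == nv) {
    W <- diag(nv)
  } else {
    ch <- channel_positions(grid, n_channels)
    d2 <- outer(rowSums(ch^2), rep(1, nv)) +
      outer(rep(1, n_channels), rowSums(grid$coords^2)) -
      2 * ch %*% t(grid$coords)
    W <- exp(-pmax(d2, 0) / (2 * leakage^2))
    W <- W / rowSums(W)
  }
  n_tr <- dim(power)[1]; nf <- dim(power)[3]
  # one big matrix product: vertices x (trials*freqs)
  P <- matrix(aperm(power, c(2, 1, 3)), nrow = nv)
  M <- W %*% P
  out <- aperm(array(M, c(n_channels, n_tr, nf)), c(2, 1, 3))
  if (sensor_noise > 0) {
    set.seed(as.integer(seed))
    out <- out * exp(array(stats::rnorm(length(out), 0, sensor_noise),
                           dim(out)))
  }
  attr(out, "freqs") <- attr(power, "freqs")
  out
}

# quasi-uniform sensor positions on the enlarged ellipsoid (upper part),
# via a Fibonacci spiral
channel_positions <- function(grid, n_channels) {
  i <- seq_len(n_channels)
  ga <- pi * (3 - sqrt(5))
  zz <- 1 - (i - 0.5) / n_channels          # upper hemisphere bias: z in (0,1)
  zz <- zz * 1.6 - 0.6                      # extend a bit below the equator
  r <- sqrt(pmax(1 - zz^2, 0))
  th <- ga * i
  sph <- cbind(r * cos(th), r * sin(th), zz)
  sweep(sph, 2, grid$semi_axes * 1.15, "*")
}

#' Generate a synthetic source-level trial dataset
#'
#' `domain = "spectral"` draws time-averaged power spectra directly (fast;
#' see [synth_source_power()]).  `domain = "time"` synthesizes per-trial
#' time series -- 1/f background noise, a gradient-consistent narrowband
#' oscillation per vertex, regressor-scaled band-limited effect
#' oscillations, and delta-phase-modulated beta amplitude at the PAC
#' vertices -- and wavelet-decomposes them into a full `tf_cube` with power
#' and phase.
#'
#' @param config A [synth_config()].
#' @param grid Optional pre-built `source_grid`.
#' @param seed Seed.
#' @param domain `"spectral"` or `"time"`.
#' @return For `"spectral"`: see [synth_source_power()].  For `"time"`:
#'   list with `cube` (a `tf_cube`), `regressors`, `ground_truth`, `grid`.
#' @export
generate_trials <- function(config = synth_config(), grid = NULL,
                            seed = config$seed,
                            domain = c("spectral", "time")) {
  domain <- match.arg(domain)
  if (is.null(grid)) grid <- make_source_grid(config$n_sources)
  if (domain == "spectral")
    return(synth_source_power(config, grid, seed))

  freqs <- exp(seq(log(config$freq_range[1]), log(config$freq_range[2]),
                   length.out = config$n_freqs))
  if (max(freqs) >= config$sample_rate / 2)
    stop("effect band off the frequency grid: raise sample_rate above twice f_max")
  mel <- melody_table(config, seed)
  beh <- make_behavioral_data(config, seed)
  reg <- trial_regressors(config, mel, beh$ratings, seed)
  gt <- synth_ground_truth(config, grid, freqs)
  n_tr <- nrow(reg); nv <- nrow(grid$coords)
  fs <- config$sample_rate
  n <- round(config$duration * fs)
  tt <- (seq_len(n) - 1) / fs
  zreg <- cbind(syncopation = scale(reg$syncopation)[, 1],
                rating = scale(reg$rating)[, 1])

  # 1/f amplitude shaping of white noise in the frequency domain
  nu <- (seq_len(n) - 1) * fs / n
  nu[nu > fs / 2] <- fs - nu[nu > fs / 2]
  shape <- c(0, nu[-1]^(-config$background_exponent / 2))

  set.seed(as.integer(seed) + 4L)
  power <- array(NA_real_, c(n_tr, nv, length(freqs), n))
  phase <- array(NA_real_, c(n_tr, nv, length(freqs), n))
  edge <- NULL
  for (tr in seq_len(n_tr)) {
    for (v in seq_len(nv)) {
      wn <- stats::rnorm(n)
      bg <- Re(stats::fft(stats::fft(wn) * shape, inverse = TRUE)) / n
      bg <- bg / stats::sd(bg)
      x <- bg + config$gradient$amplitude * 0.5 *
        cos(2 * pi * gt$gradient$f_dom[v] * tt + stats::runif(1, 0, 2 * pi)) +
        # beat-locked 2-Hz activity is present across the whole volume
        # during music listening (random phase per trial and vertex)
        0.5 * cos(2 * pi * 2 * tt + stats::runif(1, 0, 2 * pi))
      for (e in seq_along(gt$effects)) {
        ef <- gt$effects[[e]]
        if (!(v %in% ef$vertices)) next
        amp <- ef$size * (1 + zreg[tr, ef$regressor])
        for (b in ef$freq_bins)
          x <- x + pmax(amp, 0) *
            cos(2 * pi * freqs[b] * tt + stats::runif(1, 0, 2 * pi))
      }
      # every vertex carries a beta-band oscillation whose amplitude
      # fluctuates at a slow rate; only inside the PAC cluster is that
      # fluctuation locked to the vertex's own delta phase -- elsewhere an
      # independent off-frequency modulator gives the same amplitude
      # autocorrelation without phase locking
      if (v %in% gt$pac$vertices) {
        ph0 <- stats::runif(1, 0, 2 * pi)
        slow <- cos(2 * pi * gt$pac$phase_freq * tt + ph0)
        am <- 1 + gt$pac$strength * slow
        x <- x + 0.8 * slow +
          0.8 * am * cos(2 * pi * gt$pac$amp_freq * tt +
                           stats::runif(1, 0, 2 * pi))
      } else {
        f_mod <- stats::runif(1, 1, 2)
        am <- 1 + gt$pac$strength *
          cos(2 * pi * f_mod * tt + stats::runif(1, 0, 2 * pi))
        x <- x + 0.8 * am * cos(2 * pi * gt$pac$amp_freq * tt +
                                  stats::runif(1, 0, 2 * pi))
      }
      tfr <- morlet_tfr(x, fs, freqs)
      power[tr, v, , ] <- tfr$power
      phase[tr, v, , ] <- tfr$phase
      if (is.null(edge)) edge <- tfr$edge
    }
  }
  cube <- as_tf_cube(power, phase, freqs, fs, tt, edge)
  list(cube = cube, regressors = reg, ground_truth = gt, grid = grid)
}

#' Multi-subject channel-level synthetic study
#'
#' Runs [synth_source_power()] + [mix_to_channels()] per subject with
#' subject-specific seeds derived from `seed`, returning channel power
#' arrays and the (subject-invariant) regressors and ground truth.
#'
#' @param config A [synth_config()].
#' @param seed Base seed.
#' @param leakage,sensor_noise Passed to [mix_to_channels()].
#' @param progress Print one line per subject.
#' @return List: `subjects` (list of `trial` x `channel` x `freq` arrays),
#'   `regressors`, `ground_truth`, `grid`, `freqs`.
#' @export
synth_channel_study <- function(config = synth_config(), seed = config$seed,
                                leakage = 30, sensor_noise = 0.1,
                                progress = FALSE) {
  grid <- make_source_grid(config$n_sources)
  subjects <- vector("list", config$n_subjects)
  reg <- NULL; gt <- NULL; freqs <- NULL
  for (s in seq_len(config$n_subjects)) {
    s_seed <- (as.integer(seed) * 131L + s * 7919L) %% 2147483647L
    src <- synth_source_power(config, grid, seed = s_seed)
    if (is.null(reg)) { gt <- src$ground_truth; freqs <- src$freqs }
    reg <- src$regressors       # trial order differs per subject seed
    subjects[[s]] <- list(power = mix_to_channels(src$power, grid,
                                                  config$n_channels,
                                                  leakage, sensor_noise,
                                                  seed = s_seed),
                          regressors = src$regressors)
    if (progress) message("subject ", s, "/", config$n_subjects)
  }
  list(subjects = subjects, ground_truth = gt, grid = grid, freqs = freqs)
}
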