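#' Beat grid for rhythm patterns
#'
#' A metrical grid on which rhythm patterns live: a strictly periodic beat at
#' `beat_rate` Hz, subdivided into `subdivisions_per_beat` positions, grouped
#' into measures of `beats_per_measure` beats.
#'
#' Grid position `i` (0-based) occurs at time
#' `i / (beat_rate * subdivisions_per_beat)` seconds.
#'
#' @param beat_rate Beat frequency in Hz (default 2, a 2-Hz drum beat).
#' @param subdivisions_per_beat Positive integer grid resolution per beat.
#' @param beats_per_measure Positive integer number of beats per measure.
#' @param n_measures Positive integer number of measures.
#' @return An object of class `beat_grid` with fields `beat_rate`,
#'   `subdivisions_per_beat`, `beats_per_measure`, `n_measures`,
#'   `n_positions`, `duration` (seconds) and `position_times`.
#' @export
beat_grid <- function(beat_rate = 2, subdivisions_per_beat = 2,
                      beats_per_measure = 4, n_measures = 4) {
  stopifnot(beat_rate > 0,
            subdivisions_per_beat >= 1, subdivisions_per_beat %% 1 == 0,
            beats_per_measure >= 1, beats_per_measure %% 1 == 0,
            n_measures >= 1, n_measures %% 1 == 0)
  n_pos <- n_measures * beats_per_measure * subdivisions_per_beat
  times <- (seq_len(n_pos) - 1L) / (beat_rate * subdivisions_per_beat)
  structure(list(
    beat_rate = beat_rate,
    subdivisions_per_beat = as.integer(subdivisions_per_beat),
    beats_per_measure = as.integer(beats_per_measure),
    n_measures = as.integer(n_measures),
    n_positions = as.integer(n_pos),
    duration = n_measures * beats_per_measure / beat_rate,
    position_times = times
  ), class = "beat_grid")
}

#' @export
print.beat_grid <- function(x, ...) {
  cat(sprintf("<beat_grid> %g Hz beat, %d subdivisions/beat, %d beats x %d measures (%d positions, %.3g s)\n",
              x$beat_rate, x$subdivisions_per_beat, x$beats_per_measure,
              x$n_measures, x$n_positions, x$duration))
  invisible(x)
}

#' Rhythm pattern on a beat grid
#'
#' @param grid A [beat_grid()].
#' @param onsets Either a logical vector over all grid positions, or an
#'   integer vector of 0-based onset positions.
#' @param pitches Optional labels, one per onset.
#' @return An object of class `rhythm_pattern`.
#' @export
rhythm_pattern <- function(grid, onsets, pitches = NULL) {
  stopifnot(inherits(grid, "beat_grid"))
  if (is.logical(onsets)) {
    if (length(onsets) != grid$n_positions)
      stop("logical onset vector must have length ", grid$n_positions)
    on <- onsets
  } else {
    onsets <- as.integer(onsets)
    if (length(onsets) && (min(onsets) < 0 || max(onsets) >= grid$n_positions))
      stop("onset positions must lie in [0, ", grid$n_positions - 1L, "]")
    on <- rep(FALSE, grid$n_positions)
    on[onsets + 1L] <- TRUE
  }
  if (!is.null(pitches) && length(pitches) != sum(on))
    stop("need one pitch label per onset")
  structure(list(grid = grid, onsets = on, pitches = pitches),
            class = "rhythm_pattern")
}

#' @export
print.rhythm_pattern <- function(x, ...) {
  cat(sprintf("<rhythm_pattern> %d onsets on %d positions\n",
              sum(x$onsets), x$grid$n_positions))
  sub <- x$grid$subdivisions_per_beat
  per_meas <- x$grid$beats_per_measure * sub
  sym <- ifelse(x$onsets, "x", ".")
  for (m in seq_len(x$grid$n_measures)) {
    i <- (m - 1L) * per_meas + seq_len(per_meas)
    cat(" |", paste(sym[i], collapse = ""), "|\n", sep = "")
  }
  invisible(x)
}

#' Metric weights by recursive subdivision (Longuet-Higgins--Lee convention)
#'
#' Assigns one integer weight per grid position: the measure downbeat has
#' weight 0 and each subdivision level subtracts 1.  The measure is split
#' first across beats (duple/triple factors of `beats_per_measure`), then
#' across beat subdivisions; the same weights repeat in every measure.
#'
#' The measure length must factorize into 2s and 3s so the grid is
#' decomposable into a binary/ternary metric tree.
#'
#' @param grid A [beat_grid()].
#' @return An integer vector of length `grid$n_positions` (class
#'   `metric_weights`, with the grid attached as an attribute).
#' @export
metric_weights <- function(grid) {
  stopifnot(inherits(grid, "beat_grid"))
  splits <- c(metric_factors(grid$beats_per_measure, "beats_per_measure"),
              metric_factors(grid$subdivisions_per_beat, "subdivisions_per_beat"))
  w <- 0L                        # the whole measure: depth-0 downbeat
  for (k in splits) {
    # refine every current position into k: the first copy keeps its weight,
    # the inserted k-1 copies sit one level deeper
    depth <- min(w) - 1L
    depth <- min(w) - 1L
    w <- as.vector(vapply(w, function(wi) c(wi, rep(depth, k - 1L)),
                          integer(k)))
  }
  out <- rep(as.integer(w), grid$n_measures)
  structure(out, grid = grid, class = "metric_weights")
}

# factor n into 2s and 3s (largest first); error if not decomposable
metric_factors <- function(n, what) {
  n <- as.integer(n)
  f <- integer(0)
  while (n > 1L) {
    if (n %% 2L == 0L) { f <- c(f, 2L); n <- n %/% 2L }
    else if (n %% 3L == 0L) { f <- c(f, 3L); n <- n %/% 3L }
    else stop(sprintf("%s = %d is not decomposable into a binary/ternary metric tree", what, n))
  }
  sort(f, decreasing = TRUE)
}

#' Longuet-Higgins--Lee syncopation index
#'
#' Scans note-to-rest successions: whenever a note onset on a position of
#' metric weight `w1` is followed, before the next onset, by a silent
#' position of weight `w2 > w1`, a syncopation of value `w2 - w1` is
#' recorded.  When several qualifying rests follow the same note, the
#' maximum-weight rest is used.  The total is the sum over events; a rhythm
#' whose onsets all fall on maximally weighted available positions (e.g. all
#' on beats with rests only on weaker subdivisions) scores 0.
#'
#' @param pattern A [rhythm_pattern()].
#' @param weights Metric weights from [metric_weights()]; computed from the
#'   pattern's grid if omitted.
#' @return An object of class `syncopation_score`: a list with integer
#'   `total` and a data frame `events` (columns `note_position`,
#'   `rest_position`, `weight_difference`; 0-based positions).
#' @export
syncopation <- function(pattern, weights = NULL) {
  stopifnot(inherits(pattern, "rhythm_pattern"))
  if (is.null(weights)) weights <- metric_weights(pattern$grid)
  if (length(weights) != pattern$grid$n_positions)
    stop("pattern and weights do not share a grid")
  if (pattern$grid$n_positions == 0L) stop("empty grid")
  on <- pattern$onsets
  w <- as.integer(weights)
  n <- length(on)
  notes <- which(on)             # 1-based
  ev_note <- integer(0); ev_rest <- integer(0); ev_diff <- integer(0)
  for (idx in seq_along(notes)) {
    i <- notes[idx]
    j_end <- if (idx < length(notes)) notes[idx + 1L] - 1L else n
    if (j_end <= i) next
    rests <- seq.int(i + 1L, j_end)
    if (!length(rests)) next
    best <- rests[which.max(w[rests])]
    if (w[best] > w[i]) {
      ev_note <- c(ev_note, i - 1L)
      ev_rest <- c(ev_rest, best - 1L)
      ev_diff <- c(ev_diff, w[best] - w[i])
    }
  }
  structure(list(
    total = sum(ev_diff),
    events = data.frame(note_position = ev_note, rest_position = ev_rest,
                        weight_difference = ev_diff)
  ), class = "syncopation_score")
}

#' @export
print.syncopation_score <- function(x, ...) {
  cat(sprintf("<syncopation_score> total = %d (%d events)\n",
              x$total, nrow(x$events)))
  invisible(x)
}

#' Generate a family of rhythms with target syncopation indices
#'
#' Starting from the beat-aligned form of the base pattern (all onsets
#' snapped to beats; syncopation 0), variants are built by *anticipating*
#' notes: moving an onset one subdivision earlier, which puts it on a
#' metrically weak position immediately before the now-silent strong
#' position -- the defining syncopation event.  Each candidate anticipation
#' contributes an integer increment to the index; a deterministic (seeded)
#' subset search picks anticipations whose increments sum to each requested
#' level, verified with [syncopation()].  If an exact level is unreachable,
#' a bounded random search runs from the closest anticipation pattern and
#' the best pattern (minimally exceeding the target when possible) is
#' returned with a warning.
#'
#' Note counts are preserved exactly; an anticipated downbeat crosses the
#' barline, so per-measure counts can differ by one between variants
#' (closely matched, as in composed syncopated bass lines).
#'
#' @param base A [rhythm_pattern()]; level 0 requires its beat-aligned form.
#' @param levels Sorted ascending integer target indices.
#' @param seed Integer seed; same seed, same output.
#' @param max_iter Fallback search budget per level.
#' @return A list of `rhythm_pattern`s, one per level, each with attributes
#'   `target_level` and `achieved_level`.
#' @export
syncopation_family <- function(base, levels, seed = 1L, max_iter = 5000L) {
  stopifnot(inherits(base, "rhythm_pattern"), !is.unsorted(levels))
  grid <- base$grid
  w <- metric_weights(grid)
  aligned <- beat_align(base)
  if (syncopation(aligned, w)$total != 0)
    stop("no beat-aligned variant with index 0 exists for this base")
  out <- vector("list", length(levels))
  set.seed(as.integer(seed))
  moves <- anticipation_moves(aligned, w)
  for (li in seq_along(levels)) {
    target <- levels[li]
    cand <- if (target == 0) aligned else
      anticipate_to_level(aligned, w, moves, target, max_iter)
    ach <- syncopation(cand, w)$total
    if (ach != target)
      warning(sprintf("target level %d unreachable; best achieved %d", target, ach))
    attr(cand, "target_level") <- target
    attr(cand, "achieved_level") <- ach
    out[[li]] <- cand
  }
  out
}

# all single-note anticipations of a beat-aligned pattern, with the index
# increment each produces on its own
anticipation_moves <- function(aligned, w) {
  pos <- which(aligned$onsets) - 1L
  base_s <- syncopation(aligned, w)$total
  moves <- list()
  for (p in pos) {
    if (p - 1L < 0L || aligned$onsets[p]) next       # no room / target taken
    cand <- rhythm_pattern(aligned$grid, c(setdiff(pos, p), p - 1L))
    inc <- syncopation(cand, w)$total - base_s
    if (inc > 0) moves[[length(moves) + 1L]] <- list(from = p, inc = inc)
  }
  moves
}

# deterministic subset search over anticipation increments, verified by the
# index itself; falls back to local random search if no subset matches
anticipate_to_level <- function(aligned, w, moves, target, max_iter) {
  incs <- vapply(moves, `[[`, numeric(1), "inc")
  n <- length(incs)
  best <- aligned; best_s <- 0
  if (n) {
    ord <- sample(n)                 # seeded: which subset wins varies by seed
    # depth-first subset-sum on the shuffled moves, exact target first
    found <- NULL
    recurse <- function(i, chosen, total) {
      if (!is.null(found)) return()
      if (total == target) { found <<- chosen; return() }
      if (i > n || total > target) return()
      recurse(i + 1L, c(chosen, ord[i]), total + incs[ord[i]])
      recurse(i + 1L, chosen, total)
    }
    recurse(1L, integer(0), 0)
    apply_moves <- function(sel) {
      pos <- which(aligned$onsets) - 1L
      for (m in moves[sel]) pos[pos == m$from] <- m$from - 1L
      rhythm_pattern(aligned$grid, pos)
    }
    if (!is.null(found)) {
      cand <- apply_moves(found)
      if (syncopation(cand, w)$total == target) return(cand)
      best <- cand; best_s <- syncopation(cand, w)$total
    } else {
      # no exact subset: start from the closest achievable from below
      sums <- c(0, cumsum(sort(incs, decreasing = TRUE)))
      k <- which.min(abs(sums - target)) - 1L
      sel <- order(incs, decreasing = TRUE)[seq_len(k)]
      best <- apply_moves(sel)
      best_s <- syncopation(best, w)$total
    }
  }
  search_level(best, w, target, max_iter)
}

measure_counts <- function(pattern) {
  per_meas <- pattern$grid$beats_per_measure * pattern$grid$subdivisions_per_beat
  meas <- (which(pattern$onsets) - 1L) %/% per_meas
  tabulate(meas + 1L, nbins = pattern$grid$n_measures)
}

# snap every onset to the nearest beat position (ties to the earlier beat)
beat_align <- function(pattern) {
  g <- pattern$grid
  sub <- g$subdivisions_per_beat
  pos <- which(pattern$onsets) - 1L
  beats <- round(pos / sub) * sub
  beats <- pmin(beats, g$n_positions - sub)  # keep inside the grid
  # collisions: push to the next free beat
  beats <- sort(unique(beats))
  want <- sum(pattern$onsets)
  all_beats <- seq.int(0L, g$n_positions - 1L, by = sub)
  while (length(beats) < want) {
    free <- setdiff(all_beats, beats)
    if (!length(free)) break
    beats <- sort(c(beats, free[1L]))
  }
  rhythm_pattern(g, as.integer(beats))
}

search_level <- function(start, w, target, max_iter) {
  g <- start$grid
  per_meas <- g$beats_per_measure * g$subdivisions_per_beat
  cur <- start
  cur_s <- syncopation(cur, w)$total
  best <- cur; best_s <- cur_s
  for (it in seq_len(max_iter)) {
    if (best_s == target) break
    pos <- which(cur$onsets) - 1L
    k <- sample(length(pos), 1L)
    meas <- pos[k] %/% per_meas
    in_meas <- seq.int(meas * per_meas, (meas + 1L) * per_meas - 1L)
    free <- setdiff(in_meas, pos)
    if (!length(free)) next
    new_pos <- pos
    new_pos[k] <- free[sample(length(free), 1L)]
    cand <- rhythm_pattern(g, new_pos)
    s <- syncopation(cand, w)$total
    # accept moves that do not overshoot more than current distance
    if (abs(s - target) <= abs(cur_s - target) || stats::runif(1) < 0.1) {
      cur <- cand; cur_s <- s
    }
    better <- (abs(s - target) < abs(best_s - target)) ||
      (abs(s - target) == abs(best_s - target) && s >= target && best_s < target)
    if (better) { best <- cand; best_s <- s }
  }
  best
}

#' Convert a rhythm pattern to a continuous-time onset pulse signal
#'
#' A unit-amplitude pulse is centered at each onset time; the signal has
#' `duration * sample_rate` samples.
#'
#' @param pattern A [rhythm_pattern()].
#' @param sample_rate Sampling rate in Hz; must be at least
#'   `4 * beat_rate * subdivisions_per_beat`.
#' @param shape `"rectangular"` or `"raised_cosine"`.
#' @param width Pulse width in seconds (default 0.025); must be smaller than
#'   the inter-position interval so pulses cannot overlap.
#' @param amplitude Peak pulse amplitude.
#' @return Numeric vector with attributes `sample_rate` and `times`.
#' @export
pulse_signal <- function(pattern, sample_rate,
                         shape = c("rectangular", "raised_cosine"),
                         width = 0.025, amplitude = 1) {
  stopifnot(inherits(pattern, "rhythm_pattern"))
  shape <- match.arg(shape)
  g <- pattern$grid
  grid_rate <- g$beat_rate * g$subdivisions_per_beat
  if (sample_rate < 4 * grid_rate)
    stop("sample_rate must be >= 4 x beat_rate x subdivisions_per_beat")
  if (width >= 1 / grid_rate)
    stop("pulse width ", width, " s would overlap adjacent grid positions (",
         signif(1 / grid_rate, 3), " s apart)")
  n <- round(g$duration * sample_rate)
  x <- numeric(n)
  t <- (seq_len(n) - 1) / sample_rate
  centers <- g$position_times[pattern$onsets]
  half <- width / 2
  for (tc in centers) {
    i <- which(t >= tc - half & t <= tc + half)
    if (!length(i)) next
    if (shape == "rectangular") {
      x[i] <- amplitude
    } else {
      x[i] <- amplitude * 0.5 * (1 + cos(pi * (t[i] - tc) / half))
    }
  }
  structure(x, sample_rate = sample_rate, class = "pulse_signal")
}

#' Analytic (complex-valued) signal via the frequency-domain Hilbert method
#'
#' Returns the complex signal whose real part equals the input and whose
#' imaginary part is its Hilbert transform (positive-frequency components
#' doubled, negative zeroed).
#'
#' @param x Real numeric vector (non-empty).
#' @return Complex vector of the same length.
#' @export
analytic_signal <- function(x) {
  if (length(x) == 0) stop("empty signal")
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Read a rhythm pattern from JSON
#'
#' The JSON document must contain a `grid` object (fields `beat_rate`,
#' `subdivisions_per_beat`, `beats_per_measure`, `n_measures`) and an
#' `onsets` array of 0-based grid positions.
#'
#' @param path File path.
#' @return A [rhythm_pattern()].
#' @export
read_rhythm_json <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  g <- doc$grid
  grid <- beat_grid(g$beat_rate, g$subdivisions_per_beat,
                    g$beats_per_measure, g$n_measures)
  rhythm_pattern(grid, as.integer(doc$onsets))
}

#' Write a rhythm pattern to JSON
#' @param pattern A [rhythm_pattern()].
#' @param path File path.
#' @export
write_rhythm_json <- function(pattern, path) {
  g <- pattern$grid
  doc <- list(
    grid = list(beat_rate = g$beat_rate,
                subdivisions_per_beat = g$subdivisions_per_beat,
                beats_per_measure = g$beats_per_measure,
                n_measures = g$n_measures),
    onsets = which(pattern$onsets) - 1L
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE)
  invisible(path)
}

#' Read onset times from CSV (one onset time in seconds per row)
#'
#' Onset times are quantized to the nearest grid position; an onset landing
#' more than a quarter of the grid interval away from any position (i.e.
#' clearly off the grid, halfway to the maximal possible rounding error of
#' half a subdivision) raises a warning.
#'
#' @param path CSV file with a column `time` (or a single unnamed column).
#' @param grid A [beat_grid()] to quantize onto.
#' @return A [rhythm_pattern()].
#' @export
read_onsets_csv <- function(path, grid) {
  d <- utils::read.csv(path)
  times <- if ("time" %in% names(d)) d$time else d[[1]]
  grid_rate <- grid$beat_rate * grid$subdivisions_per_beat
  pos <- round(times * grid_rate)
  err <- abs(times - pos / grid_rate)
  if (any(err > 0.25 / grid_rate))
    warning("some onsets are off the grid by more than a quarter subdivision")
  pos <- pos[pos >= 0 & pos < grid$n_positions]
  rhythm_pattern(grid, as.integer(unique(pos)))
}

#' Write a syncopation score (with per-event detail) to JSON
#' @param score A `syncopation_score`.
#' @param path File path.
#' @export
write_syncopation_json <- function(score, path) {
  stopifnot(inherits(score, "syncopation_score"))
  jsonlite::write_json(list(total = score$total, events = score$events),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
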