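#' Consciousness track constructor
#'
#' Per-segment sleep/awake state, either binary (factor) or a continuous
#' vigilance score in `[0, 1]` with 0 = sleep and 1 = awake.
#'
#' @param values factor (`awake`/`sleep`) or numeric scores in `[0, 1]`.
#' @param start_s segment start times, seconds.
#' @param seg_len_s segment duration, seconds.
#' @return A `consciousness_track` with `values`, `start_s`, `seg_len_s`,
#'   `kind` (`"binary"` or `"continuous"`).
#' @export
consciousness_track <- function(values, start_s, seg_len_s = 120) {
  if (is.numeric(values)) {
    if (any(values < 0 | values > 1)) stop("scores must lie in [0, 1]")
    kind <- "continuous"
  } else {
    values <- factor(as.character(values), levels = c("awake", "sleep"))
    if (anyNA(values)) stop("binary track values must be 'awake' or 'sleep'")
    kind <- "binary"
  }
  if (length(values) != length(start_s))
    stop("values and start_s must have equal length")
  structure(list(values = values, start_s = start_s, seg_len_s = seg_len_s,
                 kind = kind),
            class = "consciousness_track")
}

#' @export
print.consciousness_track <- function(x, ...) {
  if (x$kind == "binary")
    cat(sprintf("<consciousness_track binary> %d segments, %d sleep / %d awake\n",
                length(x$values), sum(x$values == "sleep"),
                sum(x$values == "awake")))
  else
    cat(sprintf("<consciousness_track continuous> %d segments, score %.2f-%.2f (mean %.2f)\n",
                length(x$values), min(x$values), max(x$values), mean(x$values)))
  invisible(x)
}

#' @export
plot.consciousness_track <- function(x, ann = NULL, ...) {
  y <- if (x$kind == "binary") as.integer(x$values == "awake") else x$values
  graphics::plot(x$start_s / 3600, y, type = "s", xlab = "time (h)",
                 ylab = "awake score (1 = awake)", ylim = c(-0.05, 1.05), ...)
  if (!is.null(ann) && nrow(ann$sleep))
    graphics::rect(ann$sleep[, 1] / 3600, -0.05, ann$sleep[, 2] / 3600, 0,
                   col = "steelblue", border = NA)
  invisible(x)
}

#' Binary classification from one shapelet's split
#'
#' Each segment inherits the self-reported majority label of the distance
#' class it falls into: below-threshold segments get class A's majority
#' label, the rest class B's. An empty class contributes no segments; with
#' a threshold beyond the distance range the whole track carries one state.
#'
#' @param dv the shapelet's `distance_vector`.
#' @param split a `split_result` for the same shapelet (see
#'   [optimal_split()]).
#' @param start_s segment start times (optional; defaults to 120-s tiling).
#' @param seg_len_s segment duration in seconds.
#' @return A binary `consciousness_track`.
#' @export
classify_binary <- function(dv, split, start_s = NULL, seg_len_s = 120) {
  stopifnot(inherits(split, "split_result"))
  delta <- if (inherits(dv, "distance_vector")) dv$delta else as.numeric(dv)
  maj <- split$majority
  maj[is.na(maj)] <- "awake"   # empty class never receives segments anyway
  state <- ifelse(delta < split$threshold, maj[["A"]], maj[["B"]])
  if (is.null(start_s)) start_s <- (seq_along(delta) - 1L) * seg_len_s
  consciousness_track(state, start_s, seg_len_s)
}

# draw one random shapelet: random level, random start anywhere in the
# segment-covered part of the series (any sample offset, not only the
# half-length shifts of the structured pool)
draw_random_shapelet <- function(segs, levels = 1:3) {
  x <- as.vector(segs$samples)
  lev <- sample(levels, 1L)
  m <- nrow(segs$samples) / 2^lev
  start <- sample.int(length(x) - m + 1L, 1L)
  list(samples = x[start:(start + m - 1L)], level = lev, start_index = start)
}

#' Continuous vigilance score from an ensemble of random shapelets
#'
#' Draws `n` shapelets with random level (1-3 by default), random sample
#' offset and random location across the whole recording; classifies the
#' segments with each shapelet's own optimal split; and scores every
#' segment by the fraction of the ensemble voting awake. With `n = 1` the
#' continuous track coincides with that shapelet's binary track.
#'
#' @param segs a `segment_set`.
#' @param labels per-segment labels (see [segment_labels()]).
#' @param n ensemble size (default 50).
#' @param seed optional RNG seed; the draw is reproducible given the seed.
#' @param bin_frac histogram bin fraction for each member's split.
#' @param levels shapelet levels to draw from.
#' @return A continuous `consciousness_track`; attribute `members` records
#'   each draw's level, start index and information gain.
#' @export
ensemble_score <- function(segs, labels, n = 50, seed = NULL, bin_frac = 0.01,
                           levels = 1:3) {
  stopifnot(inherits(segs, "segment_set"))
  if (n < 1L) stop("ensemble size `n` must be at least 1")
  labels <- as_state_labels(labels)
  if (!is.null(seed)) set.seed(seed)
  votes <- matrix(NA_real_, segs$n, n)
  members <- vector("list", n)
  got <- 0L; tries <- 0L
  while (got < n) {
    tries <- tries + 1L
    if (tries > 20L * n)
      stop("could not assemble ", n, " valid ensemble classifiers")
    S <- draw_random_shapelet(segs, levels)
    dv <- distance_vector(S$samples, segs)
    sp <- tryCatch(optimal_split(dv, labels, bin_frac), error = function(e) NULL)
    if (is.null(sp)) next
    got <- got + 1L
    tr <- classify_binary(dv, sp, start_s = segs$start_s,
                          seg_len_s = segs$seg_len_s)
    votes[, got] <- as.integer(tr$values == "awake")
    members[[got]] <- data.frame(level = S$level, start_index = S$start_index,
                                 ig = sp$ig)
  }
  track <- consciousness_track(rowMeans(votes), segs$start_s, segs$seg_len_s)
  attr(track, "members") <- do.call(rbind, members)
  attr(track, "votes") <- votes          # 1 = awake, one column per member
  track
}

#' Binarize a continuous vigilance track
#'
#' Scores at or below the threshold become sleep. The boundary goes to
#' sleep so that an exactly split ensemble errs toward the safe state
#' (false positives are preferable to missed sleep); above-threshold
#' segments agree with the majority vote of the ensemble.
#'
#' @param track a `consciousness_track`.
#' @param threshold score threshold (default 0.5).
#' @return A binary `consciousness_track`.
#' @export
binarize_track <- function(track, threshold = 0.5) {
  stopifnot(inherits(track, "consciousness_track"))
  if (track$kind == "binary") return(track)
  consciousness_track(ifelse(track$values <= threshold, "sleep", "awake"),
                      track$start_s, track$seg_len_s)
}

#' Display smoothing of a distance or score trace
#'
#' Zero-phase low-pass Butterworth filter (default order 2, cutoff one
#' cycle per 30 min at the one-sample-per-2-min segment rate). Purely
#' cosmetic — smoothed values never feed the classification. Inputs too
#' short for a stable filter pass through unchanged with a warning.
#'
#' @param x numeric series sampled once per segment.
#' @param order filter order.
#' @param cutoff normalized cutoff in `(0, 1)` (fraction of the Nyquist
#'   frequency); the default `2 * 120 / 1800` is a 30-min smoothing scale
#'   for 2-min segments.
#' @return Smoothed numeric series of the same length.
#' @export
smooth_track <- function(x, order = 2, cutoff = 2 * 120 / 1800) {
  x <- as.numeric(x)
  if (length(x) <= 3 * (order + 1)) {
    warning("input too short to smooth (", length(x), " samples); returned unchanged")
    return(x)
  }
  bf <- signal::butter(order, cutoff, type = "low")
  # filter around the mean: the zero-padded forward-backward pass would
  # otherwise pull the edges toward zero (and distort a constant input)
  mu <- mean(x)
  out <- tryCatch(as.numeric(signal::filtfilt(bf, x - mu)) + mu,
                  error = function(e) {
                    warning("smoothing failed (", conditionMessage(e),
                            "); returned unchanged")
                    x
                  })
  out
}

#' Detect the onset of sleep by the consecutive-run rule
#'
#' Among all maximal runs of at least `min_run` consecutive sleep-classified
#' segments (>= 10 min at the defaults), picks the run whose start is
#' nearest in time to the self-reported lights-off; its start is the onset
#' estimate. A tie resolves to the earlier run (the safe side). Continuous
#' tracks are binarized at `score_threshold` first. With no qualifying run
#' an explicit no-onset result is returned, not an error.
#'
#' @param track a `consciousness_track`.
#' @param self_reported_s self-reported time of falling asleep, seconds.
#' @param min_run minimum run length in segments (default 5).
#' @param score_threshold binarization threshold for continuous tracks.
#' @return An `onset_estimate`: `found`, `onset_s` (`NA` when not found),
#'   `self_reported_s`, `delta_min` (signed, estimate minus self-report),
#'   `run_segments`.
#' @export
detect_onset <- function(track, self_reported_s, min_run = 5,
                         score_threshold = 0.5) {
  stopifnot(inherits(track, "consciousness_track"))
  bt <- binarize_track(track, score_threshold)
  asleep <- bt$values == "sleep"
  r <- rle(as.vector(asleep))
  run_end <- cumsum(r$lengths)
  run_start <- run_end - r$lengths + 1L
  ok <- r$values & r$lengths >= min_run
  if (!any(ok)) {
    return(structure(list(found = FALSE, onset_s = NA_real_,
                          self_reported_s = self_reported_s,
                          delta_min = NA_real_, run_segments = NA_integer_),
                     class = "onset_estimate"))
  }
  starts_s <- bt$start_s[run_start[ok]]
  dist <- abs(starts_s - self_reported_s)
  pick <- which(dist == min(dist))[1L]   # runs in time order: tie -> earlier
  structure(list(found = TRUE, onset_s = starts_s[pick],
                 self_reported_s = self_reported_s,
                 delta_min = (starts_s[pick] - self_reported_s) / 60,
                 run_segments = r$lengths[ok][pick]),
            class = "onset_estimate")
}

#' @export
print.onset_estimate <- function(x, ...) {
  if (!x$found)
    cat("<onset_estimate> no qualifying sleep run found\n")
  else
    cat(sprintf("<onset_estimate> onset at %.1f min (self-reported %.1f min, offset %+.1f min, run %d segments)\n",
                x$onset_s / 60, x$self_reported_s / 60, x$delta_min,
                x$run_segments))
  invisible(x)
}

#' Class-separation statistic of a split
#'
#' Mean distance of the awake-majority class minus mean distance of the
#' sleep-majority class — the gap between the two histogram peaks. Large
#' values mean heart activity differs strongly between sleep and awake for
#' that subject. `NA` when either class is empty.
#'
#' @inheritParams classify_binary
#' @param age,sex optional subject covariates carried along for
#'   [age_regression()].
#' @return A `separation_stat`: `value`, `age`, `sex`, class sizes.
#' @export
separation_statistic <- function(dv, split, age = NA_real_, sex = NA_character_) {
  stopifnot(inherits(split, "split_result"))
  delta <- if (inherits(dv, "distance_vector")) dv$delta else as.numeric(dv)
  maj <- split$majority
  state <- ifelse(delta < split$threshold, maj[["A"]], maj[["B"]])
  m_awake <- if (any(state == "awake", na.rm = TRUE))
    mean(delta[state == "awake"]) else NA_real_
  m_sleep <- if (any(state == "sleep", na.rm = TRUE))
    mean(delta[state == "sleep"]) else NA_real_
  structure(list(value = m_awake - m_sleep, age = age, sex = sex,
                 n_awake = sum(state == "awake", na.rm = TRUE),
                 n_sleep = sum(state == "sleep", na.rm = TRUE)),
            class = "separation_stat")
}

#' Age regression of the separation statistic, stratified by sex
#'
#' Ordinary least squares of the class-separation statistic on age, fitted
#' separately for each sex. Requires at least three subjects per stratum.
#'
#' @param stats a list of `separation_stat` objects, or a data.frame with
#'   columns `separation`, `age`, `sex`.
#' @return data.frame, one row per sex: `sex`, `n`, `slope`, `intercept`,
#'   `r_squared`, `p_value`.
#' @export
age_regression <- function(stats) {
  if (is.data.frame(stats)) {
    df <- stats
  } else {
    df <- do.call(rbind, lapply(stats, function(s)
      data.frame(separation = s$value, age = s$age, sex = s$sex)))
  }
  stopifnot(all(c("separation", "age", "sex") %in% names(df)))
  df <- df[stats::complete.cases(df), ]
  out <- lapply(split(df, df$sex), function(d) {
    if (nrow(d) < 3L)
      stop("need at least 3 subjects per sex (", d$sex[1], " has ", nrow(d), ")")
    fit <- stats::lm(separation ~ age, data = d)
    sm <- summary(fit)
    data.frame(sex = d$sex[1], n = nrow(d),
               slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
               r_squared = sm$r.squared,
               p_value = sm$coefficients[2, 4])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
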