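#' Cut a uniform series into fixed-duration segments
#'
#' Tiles the recording into non-overlapping segments of `seg_len_s` seconds
#' (default 120 s, i.e. 2 min — the working resolution at which heart
#' activity is assumed roughly stationary). A trailing partial window is
#' dropped, so a full 24-h recording yields 720 segments.
#'
#' @param u a `uniform_series` (see [resample_uniform()]).
#' @param seg_len_s segment duration in seconds; `seg_len_s * fs` must be a
#'   whole number of samples.
#' @return A `segment_set`: fields `samples` (matrix, one column per
#'   segment), `start_s`, `fs`, `seg_len_s`, `n`.
#' @export
segmentize <- function(u, seg_len_s = 120) {
  stopifnot(inherits(u, "uniform_series"))
  spl <- seg_len_s * u$fs
  if (abs(spl - round(spl)) > 1e-9)
    stop("`seg_len_s * fs` must be an integer number of samples")
  spl <- as.integer(round(spl))
  n <- length(u$x) %/% spl
  if (n < 1L)
    stop(sprintf("recording (%.1f s) is shorter than one %g-s segment",
                 length(u$x) / u$fs, seg_len_s))
  samples <- matrix(u$x[seq_len(n * spl)], nrow = spl, ncol = n)
  structure(list(samples = samples,
                 start_s = u$t0 + (seq_len(n) - 1L) * seg_len_s,
                 fs = u$fs, seg_len_s = seg_len_s, n = n),
            class = "segment_set")
}

#' @export
print.segment_set <- function(x, ...) {
  cat(sprintf("<segment_set> %d segments x %g s (%d samples @ %g Hz)\n",
              x$n, x$seg_len_s, nrow(x$samples), x$fs))
  invisible(x)
}

#' Extract one segment
#'
#' @param segs a `segment_set`.
#' @param i segment index (1-based).
#' @return An `hrv_segment`: `index`, `start_s`, `samples`, `fs`.
#' @export
get_segment <- function(segs, i) {
  stopifnot(inherits(segs, "segment_set"))
  if (i < 1L || i > segs$n) stop("segment index out of range: ", i)
  structure(list(index = i, start_s = segs$start_s[i],
                 samples = segs$samples[, i], fs = segs$fs),
            class = "hrv_segment")
}

# number of samples in a level-l shapelet of a segment with spl samples
shapelet_samples_per_level <- function(spl, level) spl / 2^level

# validate that main and half-shifted shapelets at `level` land on the grid
check_divisibility <- function(spl, level) {
  if (spl %% 2^(level + 1) != 0)
    stop(sprintf(paste0("segment sample count (%d) is not divisible by %d; ",
                        "choose fs so that seg_len_s*fs %%%% %d == 0"),
                 spl, 2^(level + 1), 2^(level + 1)))
}

new_shapelet <- function(samples, parent, level, set, position, start_s, start_index) {
  structure(list(samples = samples, parent = parent, level = level,
                 set = set, position = position, start_s = start_s,
                 start_index = start_index),
            class = "shapelet")
}

#' @export
print.shapelet <- function(x, ...) {
  cat(sprintf("<shapelet> segment %s, level %d, %s #%d: %d samples from %.1f s\n",
              x$parent, x$level, x$set, x$position, length(x$samples), x$start_s))
  invisible(x)
}

#' Build the three-level shapelet pool of one segment
#'
#' Each level halves the shapelet duration: level 1 = two 60-s halves,
#' level 2 = four 30-s quarters, level 3 = eight 15-s eighths. The main set
#' tiles the segment without overlap; an additional shifted set, offset by
#' half a shapelet length, contributes one fewer shapelet per level
#' (1, 3 and 7). The full pool of a segment therefore holds 25 shapelets.
#'
#' @param seg an `hrv_segment` (see [get_segment()]).
#' @param levels integer levels to generate (default `1:3`; deeper levels
#'   are supported but were found uninformative below ~15 s).
#' @return list of `shapelet` objects, level-major, main before shifted,
#'   position ascending.
#' @export
build_pool <- function(seg, levels = 1:3) {
  stopifnot(inherits(seg, "hrv_segment"))
  spl <- length(seg$samples)
  if (spl %% 8 != 0)
    stop("segment sample count must be divisible by 8 (choose fs so 120*fs %% 8 == 0)")
  out <- list()
  for (lev in levels) {
    check_divisibility(spl, lev)
    m <- shapelet_samples_per_level(spl, lev)
    half <- m %/% 2L
    for (p in seq_len(2^lev)) {
      s0 <- (p - 1L) * m
      out[[length(out) + 1L]] <- new_shapelet(
        seg$samples[(s0 + 1L):(s0 + m)], seg$index, lev, "main", p,
        seg$start_s + s0 / seg$fs, s0)
    }
    for (p in seq_len(2^lev - 1L)) {
      s0 <- (p - 1L) * m + half
      out[[length(out) + 1L]] <- new_shapelet(
        seg$samples[(s0 + 1L):(s0 + m)], seg$index, lev, "shifted", p,
        seg$start_s + s0 / seg$fs, s0)
    }
  }
  out
}

#' Enumerate the pool of shapelets of a whole recording
#'
#' Returns a manifest data frame, one row per shapelet, in a stable,
#' reproducible order: segment-major, then level, main before shifted,
#' position ascending. Shapelet samples are materialized on demand with
#' [shapelet_from_manifest()].
#'
#' @param segs a `segment_set`.
#' @param levels levels to include (default `1:3`).
#' @return data.frame with columns `shapelet_id`, `segment`, `level`, `set`,
#'   `position`, `start_s`, `length_s`.
#' @export
pool_manifest <- function(segs, levels = 1:3) {
  stopifnot(inherits(segs, "segment_set"), segs$n >= 1L)
  spl <- nrow(segs$samples)
  per_level <- lapply(levels, function(lev) {
    check_divisibility(spl, lev)
    m <- shapelet_samples_per_level(spl, lev)
    data.frame(
      level = lev,
      set = rep(c("main", "shifted"), c(2^lev, 2^lev - 1L)),
      position = c(seq_len(2^lev), seq_len(2^lev - 1L)),
      offset_s = c((seq_len(2^lev) - 1L) * m,
                   (seq_len(2^lev - 1L) - 1L) * m + m %/% 2L) / segs$fs,
      length_s = m / segs$fs)
  })
  one_seg <- do.call(rbind, per_level)
  df <- one_seg[rep(seq_len(nrow(one_seg)), times = segs$n), ]
  df$segment <- rep(seq_len(segs$n), each = nrow(one_seg))
  df$start_s <- segs$start_s[df$segment] + df$offset_s
  df$offset_s <- NULL
  df <- df[, c("segment", "level", "set", "position", "start_s", "length_s")]
  rownames(df) <- NULL
  df$shapelet_id <- seq_len(nrow(df))
  df[, c("shapelet_id", "segment", "level", "set", "position", "start_s", "length_s")]
}

#' @rdname pool_manifest
#' @return `pool_size()`: the number of shapelets across all segments
#'   (25 per segment at the default levels).
#' @export
pool_size <- function(segs, levels = 1:3) {
  per_seg <- sum(2^levels + (2^levels - 1L))
  segs$n * per_seg
}

#' @rdname pool_manifest
#' @param row a single row of the manifest (or its `shapelet_id`).
#' @export
shapelet_from_manifest <- function(segs, row) {
  if (is.numeric(row) && length(row) == 1L)
    row <- pool_manifest(segs)[row, ]
  select_shapelet(get_segment(segs, row$segment),
                  level = row$level, set = row$set, position = row$position)
}

#' Select one shapelet of a segment by (level, set, position)
#'
#' The default `(level = 2, set = "main", position = 4)` is the last
#' shapelet of the main (unshifted) row at level 2, i.e. the final quarter
#' of the segment — the selector used to build segment-to-segment distance
#' matrices.
#'
#' @param seg an `hrv_segment`.
#' @param level shapelet level (1, 2 or 3 by default tooling).
#' @param set `"main"` or `"shifted"`.
#' @param position 1-based position within the set.
#' @return A `shapelet`.
#' @export
select_shapelet <- function(seg, level = 2, set = c("main", "shifted"),
                            position = 4) {
  stopifnot(inherits(seg, "hrv_segment"))
  set <- match.arg(set)
  spl <- length(seg$samples)
  check_divisibility(spl, level)
  m <- shapelet_samples_per_level(spl, level)
  n_in_set <- if (set == "main") 2^level else 2^level - 1L
  if (position < 1L || position > n_in_set)
    stop(sprintf("position %d out of range for level %d %s set (1..%d)",
                 position, level, set, n_in_set))
  s0 <- (position - 1L) * m + if (set == "shifted") m %/% 2L else 0L
  new_shapelet(seg$samples[(s0 + 1L):(s0 + m)], seg$index, level, set,
               position, seg$start_s + s0 / seg$fs, s0)
}

#' @rdname select_shapelet
#' @export
default_selector <- function() list(level = 2L, set = "main", position = 4L)
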