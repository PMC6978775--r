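#' Global min-max normalization of a heart-rate series
#'
#' One affine map for the whole recording, sending the recording minimum to
#' 0 and the maximum to 1 (never per-segment). Shapelet distances computed
#' after this step are dimensionless and invariant under positive affine
#' transforms of the raw heart rate; their typical scale matches the
#' distance histograms the split-point search operates on (sleep peak near
#' 0, awake peak well below 1).
#'
#' @param u a `uniform_series`.
#' @return The normalized `uniform_series`.
#' @export
normalize_series <- function(u) {
  stopifnot(inherits(u, "uniform_series"))
  rng <- range(u$x)
  if (diff(rng) == 0)
    stop("constant recording: min-max normalization undefined")
  uniform_series(u$fs, (u$x - rng[1]) / diff(rng), u$t0)
}

#' Equal-length squared-Euclidean distance
#'
#' Sum of squared pointwise differences between two equal-length windows
#' (no square root). Zero iff the windows are identical.
#'
#' @param a,b numeric vectors of equal length.
#' @return Non-negative scalar.
#' @export
distance_sq <- function(a, b) {
  if (length(a) != length(b))
    stop("distance_sq: windows differ in length (", length(a), " vs ",
         length(b), ")")
  if (length(a) < 1L) stop("distance_sq: empty windows")
  sum((a - b)^2)
}

#' Sliding shapelet-to-segment distance
#'
#' Slides the shapelet along the segment one sample at a time and returns
#' the minimum [distance_sq()] over all alignments, together with the
#' best-match offset (0-based samples from the segment start). Ties are
#' broken toward the smallest offset. The distance from a shapelet to its
#' own parent segment is exactly zero.
#'
#' @param S a `shapelet` or numeric vector.
#' @param seg an `hrv_segment` or numeric vector, at least as long as `S`.
#' @return list `delta` (minimal distance) and `offset` (0-based argmin).
#' @export
shapelet_delta <- function(S, seg) {
  s <- if (inherits(S, "shapelet")) S$samples else as.numeric(S)
  x <- if (inherits(seg, "hrv_segment")) seg$samples else as.numeric(seg)
  m <- length(s); L <- length(x)
  if (m > L)
    stop("shapelet (", m, " samples) longer than segment (", L, " samples)")
  d <- sliding_sq_distances(s, x)
  j <- which.min(d)                      # first minimum = smallest offset
  list(delta = d[j], offset = j - 1L)
}

# squared distances of `s` against every length-m window of `x`, computed
# directly (no expansion trick) so that identical windows give exactly zero
sliding_sq_distances <- function(s, x) {
  m <- length(s); L <- length(x)
  vapply(seq_len(L - m + 1L),
         function(j) sum((s - x[j:(j + m - 1L)])^2), 0)
}

#' Distance from one shapelet to every segment
#'
#' Computes [shapelet_delta()] against each segment of a `segment_set`,
#' order-aligned with segment index. Because the segments tile one
#' contiguous series, the sliding dot products are evaluated over the full
#' recording in a single linear-filter pass and windows crossing segment
#' boundaries are discarded, which is algebraically identical to the
#' per-segment computation.
#'
#' @param S a `shapelet` or numeric vector of samples.
#' @param segs a `segment_set`.
#' @param stride offset step of the sliding search. The default 1 is the
#'   exact sliding minimum; larger strides probe every `stride`-th
#'   alignment only, trading a (one-sided, upward) approximation of delta
#'   for speed on very long recordings.
#' @return A `distance_vector`: `delta` (per segment), `offset` (0-based
#'   best-match start per segment), `shapelet` (metadata), `n`.
#' @export
distance_vector <- function(S, segs, stride = 1L) {
  stopifnot(inherits(segs, "segment_set"))
  if (stride < 1L) stop("`stride` must be a positive integer")
  s <- if (inherits(S, "shapelet")) S$samples else as.numeric(S)
  spl <- nrow(segs$samples); m <- length(s)
  if (m > spl) stop("shapelet longer than segment")
  x <- as.vector(segs$samples)
  ss <- sum(s^2)
  # cross[t] = sum_k s[k] * x[t - m + k]  (window ending at t)
  cross <- as.numeric(stats::filter(x, rev(s), method = "convolution", sides = 1))
  csum2 <- cumsum(x^2)
  n_off <- spl - m + 1L
  probe <- seq.int(1L, n_off, by = stride)
  starts <- outer(probe, (seq_len(segs$n) - 1L) * spl, `+`)
  ends <- starts + m - 1L
  csum2_0 <- c(0, csum2)                 # csum2_0[k + 1] = sum of x[1..k]^2
  win_ss <- csum2[ends] - csum2_0[starts]
  d <- matrix(pmax(win_ss - 2 * cross[ends] + ss, 0), length(probe), segs$n)
  best <- max.col(-t(d), ties.method = "first")
  # the expansion above cancels catastrophically near zero; re-evaluate the
  # near-minimal alignments of each segment directly so the reported delta
  # is exact (in particular, exactly 0 against the parent segment)
  delta <- numeric(segs$n)
  for (k in seq_len(segs$n)) {
    dk <- d[, k]
    tol <- 1e-8 * max(dk[best[k]], 1)
    cand <- which(dk <= dk[best[k]] + tol)
    if (length(cand) > 8L) cand <- cand[order(dk[cand])[1:8]]
    cand <- sort(cand)
    seg0 <- (k - 1L) * spl
    vals <- vapply(cand, function(j)
      sum((s - x[(seg0 + probe[j]):(seg0 + probe[j] + m - 1L)])^2), 0)
    pick <- which.min(vals)              # cand ascending: tie -> smallest offset
    best[k] <- cand[pick]
    delta[k] <- vals[pick]
  }
  structure(list(delta = delta,
                 offset = probe[best] - 1L,
                 shapelet = if (inherits(S, "shapelet"))
                   S[c("parent", "level", "set", "position", "start_s")]
                 else list(length = m),
                 n = segs$n),
            class = "distance_vector")
}

#' @export
print.distance_vector <- function(x, ...) {
  cat(sprintf("<distance_vector> %d segments, delta in [%.4g, %.4g]\n",
              x$n, min(x$delta), max(x$delta)))
  invisible(x)
}

#' All-to-all segment distance matrix
#'
#' Row *i* holds the distances from an equivalently positioned shapelet of
#' segment *i* (by default the last main level-2 quarter) to every segment,
#' so entry *i,j* reads as the distance from segment *i* to segment *j*.
#' The matrix is not exactly symmetric — it depends on the shapelet chosen
#' per row — but the mismatch is small; downstream consumers use the
#' arithmetic-mean symmetrization `(M + t(M))/2`, and the relative
#' asymmetry `max|M - t(M)| / max(M)` is reported.
#'
#' @param segs a `segment_set` (at least 2 segments).
#' @param selector list with `level`, `set`, `position` naming the shapelet
#'   taken from every segment (default [default_selector()]).
#' @return A `distance_matrix`: `M` (raw), `S` (symmetrized), `asymmetry`,
#'   `selector`, `start_s`.
#' @export
distance_matrix <- function(segs, selector = default_selector()) {
  stopifnot(inherits(segs, "segment_set"))
  if (segs$n < 2L) stop("need at least two segments")
  M <- matrix(NA_real_, segs$n, segs$n)
  for (i in seq_len(segs$n)) {
    S <- select_shapelet(get_segment(segs, i), level = selector$level,
                         set = selector$set, position = selector$position)
    M[i, ] <- distance_vector(S, segs)$delta
  }
  asym <- if (max(M) > 0) max(abs(M - t(M))) / max(M) else 0
  structure(list(M = M, S = (M + t(M)) / 2, asymmetry = asym,
                 selector = selector, start_s = segs$start_s),
            class = "distance_matrix")
}

#' @export
print.distance_matrix <- function(x, ...) {
  cat(sprintf("<distance_matrix> %d x %d, relative asymmetry %.3g\n",
              nrow(x$M), ncol(x$M), x$asymmetry))
  invisible(x)
}

#' Heat-map of a segment distance matrix
#'
#' Dark cells = small distance (similar heart activity), mirroring the
#' usual presentation where the sleep block stands out as a dark square.
#'
#' @param x a `distance_matrix`.
#' @param symmetrized plot the symmetrized matrix (default) or the raw one.
#' @param ... passed to [graphics::image()].
#' @export
plot.distance_matrix <- function(x, symmetrized = TRUE, ...) {
  M <- if (symmetrized) x$S else x$M
  h <- x$start_s / 3600
  graphics::image(h, h, M, col = grDevices::gray.colors(64, start = 0, end = 1),
                  xlab = "time (h)", ylab = "time (h)", useRaster = TRUE, ...)
  invisible(x)
}
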