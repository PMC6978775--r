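# Shared fixtures, built in code at test time.

# uniform series straight from a sample vector
u_series <- function(x, fs = 2, t0 = 0) uniform_series(fs = fs, x = x, t0 = t0)

# a clean two-regime recording (awake then sleep then awake), preprocessed
# up to the normalized segment set, with both the self-report labels and
# the ground-truth labels
two_regime <- function(duration_h = 2, seed = 1, ...) {
  cfg <- synth_config(duration_h = duration_h, seed = seed, ...)
  rec <- generate_recording(cfg)
  flt <- filter_hr(rec$series)
  u <- suppressWarnings(normalize_series(resample_uniform(flt$series, 2)))
  segs <- segmentize(u)
  list(cfg = cfg, rec = rec, segs = segs,
       labels = segment_labels(rec$annotation, segs),
       truth = segment_labels(annotation(rec$truth$sleep_intervals), segs),
       removed = flt$removed_fraction)
}

# independent brute-force sliding distance: explicit double loop
brute_delta <- function(s, x) {
  m <- length(s)
  best <- Inf; best_j <- NA_integer_
  for (j in seq_len(length(x) - m + 1L)) {
    d <- 0
    for (i in seq_len(m)) d <- d + (s[i] - x[j + i - 1L])^2
    if (d < best) { best <- d; best_j <- j }
  }
  list(delta = best, offset = best_j - 1L)
}

# independent information gain: literal three-entropy-term evaluation
brute_ig <- function(delta, labels, threshold) {
  h2 <- function(p) {
    tm <- function(q) if (q > 0) q * log2(q) else 0
    -tm(p) - tm(1 - p)
  }
  sl <- labels == "sleep"
  a <- delta < threshold
  e_before <- h2(mean(sl))
  term <- function(idx) {
    if (!any(idx)) return(0)
    fa <- mean(!sl[idx])                 # fraction awake in the class
    sum(idx) / length(delta) * h2(fa)
  }
  e_before - term(a) - term(!a)
}

# write a temporary rr-only file
tmp_rr <- function(rr_ms) {
  f <- tempfile(fileext = ".txt")
  writeLines(as.character(rr_ms), f)
  f
}
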