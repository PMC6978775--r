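#' End-to-end sleep/awake pipeline
#'
#' Chains the full method: read the RR file, filter artifacts, resample,
#' normalize, segmentize, label the segments from the self-report
#' annotation, search for the best shapelet, classify, score with the
#' random-shapelet ensemble, detect the onset of sleep and compute the
#' class-separation statistic.
#'
#' @param rr_path RR recording (rr-only or time-rr dialect, see
#'   [load_rr()]).
#' @param ann_path self-report annotation JSON (see [read_annotation()]).
#' @param config named list overriding defaults: `dialect`, `lo`, `hi`,
#'   `fs`, `seg_len_s`, `bin_frac`, `sampler` (`"random"` or `"all"`),
#'   `k`, `levels`, `ensemble_n` (0 disables the ensemble), `min_run`,
#'   `score_threshold`, `seed`.
#' @return An `hrv_report` list: preprocessing counts, the best shapelet
#'   and its split, the binary and (optionally) continuous tracks, the
#'   onset estimate and the separation statistic.
#' @export
run_pipeline <- function(rr_path, ann_path, config = list()) {
  cfg <- utils::modifyList(list(
    dialect = "rr-only", lo = 40, hi = 180, fs = 2, seg_len_s = 120,
    bin_frac = 0.01, sampler = "random", k = 200, levels = 1:3,
    ensemble_n = 50, min_run = 5, score_threshold = 0.5, seed = 1
  ), config)

  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
  }

  beats <- stage("load", load_rr(rr_path, cfg$dialect))
  if (is.null(ann_path) || !file.exists(ann_path))
    stop("pipeline stage 'annotation' failed: annotation file not found (",
         if (is.null(ann_path)) "NULL" else ann_path,
         "); the split-point search needs self-reported sleep windows",
         call. = FALSE)
  ann <- stage("annotation", read_annotation(ann_path))

  flt <- stage("filter", filter_hr(beats, cfg$lo, cfg$hi))
  u <- stage("resample", resample_uniform(flt$series, cfg$fs))
  u <- stage("normalize", normalize_series(u))
  segs <- stage("segmentize", segmentize(u, cfg$seg_len_s))
  labels <- stage("labels", segment_labels(ann, segs))

  bs <- stage("best_shapelet",
              best_shapelet(segs, labels, sampler = cfg$sampler, k = cfg$k,
                            bin_frac = cfg$bin_frac, levels = cfg$levels,
                            seed = cfg$seed))
  track <- stage("classify",
                 classify_binary(bs$dv, bs$split, start_s = segs$start_s,
                                 seg_len_s = segs$seg_len_s))
  ens <- if (cfg$ensemble_n >= 1)
    stage("ensemble", ensemble_score(segs, labels, n = cfg$ensemble_n,
                                     seed = cfg$seed, bin_frac = cfg$bin_frac,
                                     levels = cfg$levels))
  else NULL

  reported_onset <- if (nrow(ann$sleep)) ann$sleep[1, 1] else NA_real_
  onset <- if (!is.na(reported_onset))
    stage("onset", detect_onset(track, reported_onset, cfg$min_run,
                                cfg$score_threshold))
  else NULL
  sep <- stage("separation", separation_statistic(bs$dv, bs$split))

  structure(list(
    config = cfg,
    n_beats = length(beats$t),
    removed_fraction = flt$removed_fraction,
    n_segments = segs$n,
    labels = labels,
    best = list(shapelet = bs$shapelet, ig = bs$ig,
                threshold = bs$split$threshold,
                majority = bs$split$majority),
    track = track,
    ensemble = ens,
    onset = onset,
    separation = sep,
    segments = segs,
    best_dv = bs$dv,
    best_split = bs$split
  ), class = "hrv_report")
}

#' @export
print.hrv_report <- function(x, ...) {
  cat(sprintf("<hrv_report> %d beats (%.2f%% removed), %d segments\n",
              x$n_beats, 100 * x$removed_fraction, x$n_segments))
  cat(sprintf("  best shapelet: segment %d, level %d %s #%d, IG %.4f bits, threshold %.4g\n",
              x$best$shapelet$segment, x$best$shapelet$level,
              x$best$shapelet$set, x$best$shapelet$position, x$best$ig,
              x$best$threshold))
  cat(sprintf("  track: %d sleep / %d awake segments\n",
              sum(x$track$values == "sleep"), sum(x$track$values == "awake")))
  if (!is.null(x$onset)) print(x$onset)
  cat(sprintf("  separation statistic: %.4g\n", x$separation$value))
  invisible(x)
}

#' Serialize a pipeline report to JSON
#'
#' Writes the machine-readable part of an `hrv_report` (counts, best
#' shapelet, threshold, per-segment states/scores, onset, separation).
#'
#' @param report an `hrv_report` from [run_pipeline()].
#' @param path output JSON path.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "hrv_report"))
  obj <- list(
    n_beats = report$n_beats,
    removed_fraction = report$removed_fraction,
    n_segments = report$n_segments,
    best_shapelet = as.list(report$best$shapelet),
    ig = report$best$ig,
    threshold = report$best$threshold,
    segment_start_s = report$track$start_s,
    state = as.character(report$track$values),
    ensemble_score = if (!is.null(report$ensemble))
      as.numeric(report$ensemble$values) else NULL,
    onset = if (!is.null(report$onset))
      report$onset[c("found", "onset_s", "self_reported_s", "delta_min")]
    else NULL,
    separation = report$separation$value
  )
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}
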