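test_that("binary classification propagates each class's majority label", {
  lab <- rep(c("sleep", "awake"), each = 5)
  d <- c(rep(0.1, 5), rep(0.9, 5))
  sp <- information_gain(d, lab, 0.5)
  tr <- classify_binary(d, sp)
  expect_s3_class(tr, "consciousness_track")
  expect_equal(as.character(tr$values), lab)

  # threshold beyond the range: a one-state track
  all_b <- classify_binary(d, information_gain(d, lab, 0.01))
  expect_length(unique(all_b$values), 1)
  all_a <- classify_binary(d, information_gain(d, lab, 2))
  expect_length(unique(all_a$values), 1)
})

test_that("best-shapelet classification recovers the true state of a two-regime day", {
  sch <- data.frame(state = c("awake", "sleep", "awake"),
                    start_s = c(0, 7200, 13200),
                    end_s = c(7200, 13200, 14400))
  tw <- two_regime(duration_h = 4, seed = 51, schedule = sch)
  bs <- best_shapelet(tw$segs, tw$labels, sampler = "random", k = 100, seed = 5)
  tr <- classify_binary(bs$dv, bs$split, start_s = tw$segs$start_s)
  agreement <- mean((tr$values == "sleep") == (tw$truth == "sleep"))
  expect_gte(agreement, 0.95)
})

test_that("an ensemble of one equals that shapelet's own binary track", {
  tw <- two_regime(duration_h = 2, seed = 52)
  es <- ensemble_score(tw$segs, tw$labels, n = 1, seed = 9)
  expect_true(all(es$values %in% c(0, 1)))
  m <- attr(es, "members")
  x <- as.vector(tw$segs$samples)
  s <- x[m$start_index:(m$start_index + nrow(tw$segs$samples) / 2^m$level - 1)]
  dv <- distance_vector(s, tw$segs)
  tr <- classify_binary(dv, optimal_split(dv, tw$labels))
  expect_equal(es$values, as.numeric(tr$values == "awake"))
})

test_that("ensemble scores recover the regimes and agree with the majority vote", {
  sch <- data.frame(state = c("awake", "sleep", "awake"),
                    start_s = c(0, 7200, 13200),
                    end_s = c(7200, 13200, 14400))
  tw <- two_regime(duration_h = 4, seed = 53, schedule = sch)
  es <- ensemble_score(tw$segs, tw$labels, n = 50, seed = 10)
  expect_true(all(es$values >= 0 & es$values <= 1))
  expect_lt(mean(es$values[tw$truth == "sleep"]), 0.2)
  expect_gt(mean(es$values[tw$truth == "awake"]), 0.8)

  votes <- attr(es, "votes")
  bt <- binarize_track(es, 0.5)
  maj_awake <- rowMeans(votes) > 0.5       # strict majority of 50 classifiers
  expect_equal(as.vector(bt$values == "awake"), as.vector(maj_awake))
  expect_error(ensemble_score(tw$segs, tw$labels, n = 0), "at least 1")
})

test_that("display smoothing is a well-behaved low-pass filter", {
  const <- rep(0.4, 100)
  expect_equal(smooth_track(const), const, tolerance = 1e-9)

  set.seed(18)
  noise <- rnorm(500)
  expect_lt(var(smooth_track(noise)), var(noise))

  step <- rep(c(0, 1), each = 100)
  sm <- smooth_track(step)
  expect_lt(max(sm), 1 + 0.15)            # overshoot bounded at 15% of the step
  expect_gt(min(sm), -0.15)
  expect_lt(sm[50], 0.5); expect_gt(sm[150], 0.5)

  expect_warning(short <- smooth_track(c(1, 2, 3)), "too short")
  expect_equal(short, c(1, 2, 3))
})

test_that("onset detection applies the nearest >=5-segment run rule", {
  mk <- function(states) consciousness_track(states, (seq_along(states) - 1) * 120)
  # single qualifying run: chosen regardless of the self-report anchor
  tr <- mk(rep(c("awake", "sleep", "awake"), c(10, 6, 10)))
  on <- detect_onset(tr, self_reported_s = 0)
  expect_true(on$found)
  expect_equal(on$onset_s, 10 * 120)
  expect_equal(on$run_segments, 6)
  expect_equal(on$onset_s %% 120, 0)       # lands on a segment boundary

  # a 4-segment run never qualifies
  no <- detect_onset(mk(rep(c("awake", "sleep", "awake"), c(10, 4, 10))), 1200)
  expect_false(no$found)
  expect_true(is.na(no$onset_s))

  # two qualifying runs straddling the self-report: nearer start wins
  tr2 <- mk(rep(c("sleep", "awake", "sleep"), c(6, 10, 6)))
  expect_equal(detect_onset(tr2, 300)$onset_s, 0)
  expect_equal(detect_onset(tr2, 1800)$onset_s, 16 * 120)
  # exact tie resolves to the earlier run
  expect_equal(detect_onset(tr2, 16 * 120 / 2)$onset_s, 0)

  # continuous tracks are binarized first; boundary scores count as sleep
  cont <- consciousness_track(rep(c(0.9, 0.5, 0.9), c(5, 5, 5)),
                              (0:14) * 120)
  on2 <- detect_onset(cont, 600)
  expect_true(on2$found)
  expect_equal(on2$onset_s, 5 * 120)
})

test_that("the separation statistic measures the gap between class means", {
  lab <- rep(c("sleep", "awake"), each = 2)
  d <- c(0.1, 0.1, 0.5, 0.5)
  sp <- information_gain(d, lab, 0.3)
  expect_equal(separation_statistic(d, sp)$value, 0.4)

  # sign records which state sits near the shapelet: with awake nearby the
  # awake-majority class has the smaller mean distance
  lab_r <- rep(c("awake", "sleep"), each = 2)
  sp_r <- information_gain(d, lab_r, 0.3)
  expect_equal(separation_statistic(d, sp_r)$value, -0.4)

  # empty class: undefined marker, not zero
  sp3 <- information_gain(d, lab, 2)
  expect_true(is.na(separation_statistic(d, sp3)$value))
})

test_that("separation grows with the sleep RSA amplitude when bases are equal", {
  # probe with the same sleep-segment shapelet at every amplitude so the
  # statistic responds to the RSA contrast alone
  vals <- sapply(c(2.5, 5, 7.5), function(a) {
    sch <- data.frame(state = c("awake", "sleep"), start_s = c(0, 7200),
                      end_s = c(7200, 14400))
    tw <- two_regime(duration_h = 4, seed = 60, schedule = sch,
                     hr_base = c(awake = 70, sleep = 70),
                     rsa_amp = c(awake = 1.5, sleep = a),
                     annotation_offset_min = 0)
    S <- select_shapelet(get_segment(tw$segs, 90))   # deep in the sleep block
    dv <- distance_vector(S, tw$segs)
    separation_statistic(dv, optimal_split(dv, tw$labels))$value
  })
  expect_true(all(diff(vals) > 0))
})

test_that("age regression recovers exact, absent and injected trends", {
  # collinear points: R^2 = 1
  exact <- data.frame(separation = 10 - 0.1 * (20:29), age = 20:29,
                      sex = rep(c("M", "F"), 5))
  fit <- suppressWarnings(age_regression(exact))   # exact fit is intentional
  expect_equal(fit$r_squared, c(1, 1), tolerance = 1e-9)
  expect_equal(fit$slope, c(-0.1, -0.1), tolerance = 1e-9)

  # permuted ages carry (almost) no signal
  set.seed(19)
  age <- runif(40, 16, 57)
  sep <- 8 - 0.12 * age + rnorm(40, sd = 0.3)
  perm <- data.frame(separation = sep, age = sample(age), sex = "M")
  expect_lt(age_regression(perm)$r_squared, 0.2)

  expect_error(age_regression(data.frame(separation = 1:2, age = 1:2,
                                         sex = "F")), "at least 3")
})

test_that("the injected male aging trend is recovered end to end", {
  co <- generate_cohort(n_male = 12, n_female = 0, duration_h = 3, seed = 77)
  stats <- lapply(seq_len(12), function(i) {
    rec <- generate_recording(co$configs[[i]])
    flt <- filter_hr(rec$series)
    segs <- segmentize(suppressWarnings(
      normalize_series(resample_uniform(flt$series, 2))))
    labels <- segment_labels(rec$annotation, segs)
    # probe at a single level so separations share a scale across subjects
    # (delta is length-dependent, so levels are not directly comparable)
    bs <- best_shapelet(segs, labels, sampler = "random", k = 40, levels = 2,
                        seed = co$demographics$seed[i])
    s <- separation_statistic(bs$dv, bs$split,
                              age = co$demographics$age[i], sex = "M")
    s$value <- abs(s$value)      # peak separation, sign-free
    s
  })
  fit <- age_regression(stats)
  expect_lt(fit$slope, 0)
})

test_that("run_pipeline chains every stage and fails with stage context", {
  cfg <- synth_config(duration_h = 3, seed = 81)
  rec <- generate_recording(cfg)
  rr <- tempfile(); ann <- tempfile()
  write_rr(rec$series, rr)
  write_annotation(rec$annotation, ann)

  rep <- suppressWarnings(run_pipeline(rr, ann, config = list(
    k = 60, ensemble_n = 5, seed = 4)))
  expect_s3_class(rep, "hrv_report")
  expect_equal(rep$n_segments, floor(3 * 3600 / 120))
  expect_gt(rep$best$ig, 0.5)
  expect_true(rep$onset$found)
  expect_s3_class(rep$ensemble, "consciousness_track")

  out <- tempfile(fileext = ".json")
  write_report(rep, out)
  parsed <- jsonlite::fromJSON(out)
  expect_equal(parsed$n_segments, rep$n_segments)
  expect_equal(parsed$ig, rep$best$ig)

  expect_error(run_pipeline(rr, tempfile(), config = list()),
               "annotation")
})
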