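#' Configuration of the synthetic RR generator
#'
#' The generator emulates the phenomenology a 24-h ambulatory recording
#' presents to the pipeline: a lower mean heart rate and a stronger
#' respiratory modulation (RSA, ~0.25 Hz band) during sleep, a slow
#' circadian drift, occasional daytime naps, artifact beats outside the
#' 40-180 bpm band, and a self-report annotation that only partially
#' matches the true state.
#'
#' The default state schedule for a 24-h recording (taken to start at
#' 09:00) is: awake, a 20-min nap 5 h in, awake again, the main sleep
#' block from hour 14 to hour 22 (23:00-07:00 on the clock), then awake.
#' Shorter recordings use the same fractional layout (sleep from 55% to
#' 90% of the duration, nap only when the recording exceeds 12 h).
#'
#' @param duration_h recording duration in hours.
#' @param schedule optional data.frame `state`/`start_s`/`end_s` tiling
#'   `[0, duration]`; overrides the default layout.
#' @param hr_base named numeric, baseline heart rate per state in bpm
#'   (defaults awake 78, sleep 58).
#' @param rsa_amp named numeric, RSA amplitude per state in bpm (defaults
#'   awake 1.5, sleep 5 — sleep deepens the respiratory modulation).
#' @param f_resp named numeric, respiration frequency per state in Hz
#'   (defaults awake 0.30, sleep 0.25; a 4-s cycle during sleep).
#' @param circadian_amp amplitude of the 24-h sinusoidal drift, bpm
#'   (minimum placed 18 h into the recording, i.e. mid-sleep).
#' @param noise_sd beat-to-beat Gaussian heart-rate noise, bpm.
#' @param artifact_rate proportion of beats replaced by out-of-band
#'   artifacts (default 0.0063, reproducing a ~0.63% removal rate).
#' @param annotation_offset_min signed offset, in minutes, of the reported
#'   lights-off/lights-on relative to the true transitions (default -5:
#'   lights go off five minutes before sleep actually starts, and back on
#'   five minutes after it ends).
#' @param ramp_min duration, in minutes, of a pre-sleep "relaxation ramp"
#'   over which the heart-rate parameters blend linearly from awake to
#'   sleep values before each sleep interval (default 0 = sharp
#'   transition).
#' @param seed RNG seed; identical config + seed gives identical beats.
#' @return A `synth_config` list.
#' @export
synth_config <- function(duration_h = 24,
                         schedule = NULL,
                         hr_base = c(awake = 78, sleep = 58),
                         rsa_amp = c(awake = 1.5, sleep = 5),
                         f_resp = c(awake = 0.30, sleep = 0.25),
                         circadian_amp = 3,
                         noise_sd = 1.5,
                         artifact_rate = 0.0063,
                         annotation_offset_min = -5,
                         ramp_min = 0,
                         seed = NULL) {
  dur <- duration_h * 3600
  if (is.null(schedule)) schedule <- default_schedule(dur)
  schedule <- as.data.frame(schedule)
  stopifnot(all(c("state", "start_s", "end_s") %in% names(schedule)))
  schedule$state <- as.character(schedule$state)
  if (!all(schedule$state %in% c("awake", "sleep")))
    stop("schedule states must be 'awake' or 'sleep'")
  schedule <- schedule[order(schedule$start_s), ]
  if (abs(schedule$start_s[1]) > 1e-9 ||
      abs(schedule$end_s[nrow(schedule)] - dur) > 1e-6 ||
      (nrow(schedule) > 1L &&
       any(abs(schedule$start_s[-1] - schedule$end_s[-nrow(schedule)]) > 1e-6)))
    stop("schedule must tile [0, duration] without gaps or overlaps")
  for (p in list(hr_base, rsa_amp, f_resp))
    stopifnot(all(c("awake", "sleep") %in% names(p)), all(p >= 0))
  structure(list(duration_s = dur, schedule = schedule, hr_base = hr_base,
                 rsa_amp = rsa_amp, f_resp = f_resp,
                 circadian_amp = circadian_amp, noise_sd = noise_sd,
                 artifact_rate = artifact_rate,
                 annotation_offset_min = annotation_offset_min,
                 ramp_min = ramp_min, seed = seed),
            class = "synth_config")
}

default_schedule <- function(dur) {
  if (dur >= 20 * 3600) {
    sl <- c(14, 22) * 3600
    nap <- c(5 * 3600, 5 * 3600 + 1200)
  } else {
    sl <- c(0.55, 0.90) * dur
    nap <- if (dur > 12 * 3600) c(0.2 * dur, 0.2 * dur + 1200) else NULL
  }
  starts <- c(0, if (!is.null(nap)) nap, sl)
  states <- c("awake", if (!is.null(nap)) c("sleep", "awake"), "sleep", "awake")
  ends <- c(starts[-1], dur)
  data.frame(state = states, start_s = starts, end_s = ends)
}

# state-dependent parameters evaluated on a time grid, with optional
# linear awake->sleep blending over the ramp before each sleep interval
state_params_on_grid <- function(cfg, tt) {
  sched <- cfg$schedule
  idx <- findInterval(tt, sched$start_s, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  state <- sched$state[idx]
  w <- as.numeric(state == "sleep")   # sleep weight
  if (cfg$ramp_min > 0) {
    ramp <- cfg$ramp_min * 60
    sleep_starts <- sched$start_s[sched$state == "sleep"]
    for (s0 in sleep_starts) {
      in_ramp <- tt >= (s0 - ramp) & tt < s0 & w == 0
      w[in_ramp] <- (tt[in_ramp] - (s0 - ramp)) / ramp
    }
  }
  blend <- function(p) (1 - w) * p[["awake"]] + w * p[["sleep"]]
  list(base = blend(cfg$hr_base), rsa = blend(cfg$rsa_amp),
       f_resp = blend(cfg$f_resp), state = state)
}

#' Generate a synthetic RR recording with known ground truth
#'
#' Instantaneous heart rate is modeled as
#' `HR(t) = hr_base(state) + circadian_amp * sin(2 pi t / 24h) +
#' rsa_amp(state) * sin(2 pi f_resp(state) t)`; beats are emitted by
#' integrating `HR/60` on a fine grid and placing a beat each time the
#' integral advances by one, so the RR sequence is internally consistent
#' with the underlying rate. Beat-to-beat Gaussian noise is then added on
#' the heart-rate scale, and a small fraction of beats is replaced by
#' out-of-band artifacts (half tachycardic > 180 bpm, half bradycardic
#' < 40 bpm) that the 40-180 bpm filter removes.
#'
#' @param cfg a [synth_config()].
#' @return list with `series` (a [beat_series()]), `annotation` (the
#'   imperfect self-report handed to the pipeline) and `truth`
#'   (`sleep_intervals` — the real state including naps —, `onset_s` of the
#'   main sleep block, and the `schedule`).
#' @export
generate_recording <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  dt <- 0.1
  tt <- seq(0, cfg$duration_s, by = dt)
  pars <- state_params_on_grid(cfg, tt)
  hr <- pars$base +
    cfg$circadian_amp * sin(2 * pi * tt / 86400) +
    pars$rsa * sin(2 * pi * pars$f_resp * tt)
  # cumulative beat count: trapezoidal integral of HR/60
  rate <- hr / 60
  lambda <- c(0, cumsum((rate[-1] + rate[-length(rate)]) / 2 * dt))
  n_beats <- floor(lambda[length(lambda)])
  t_beats <- stats::approx(lambda, tt, xout = seq_len(n_beats))$y
  rr_s <- diff(c(0, t_beats))
  hr_beat <- 60 / rr_s
  if (cfg$noise_sd > 0)
    hr_beat <- hr_beat + stats::rnorm(n_beats, sd = cfg$noise_sd)
  hr_beat <- pmax(hr_beat, 41)          # noise must not fake artifacts
  rr_ms <- 60000 / hr_beat
  t_out <- cumsum(rr_ms) / 1000
  if (cfg$artifact_rate > 0) {
    # artifacts are detection errors: they corrupt the recorded RR value of
    # a beat without dilating the time axis, leaving a gap once filtered
    is_art <- stats::runif(n_beats) < cfg$artifact_rate
    n_art <- sum(is_art)
    if (n_art > 0) {
      hi <- stats::runif(n_art, 185, 240)
      lo <- stats::runif(n_art, 25, 39)
      rr_ms[is_art] <- 60000 / ifelse(stats::runif(n_art) < 0.5, hi, lo)
    }
  }
  series <- beat_series(t_out, rr_ms)

  sched <- cfg$schedule
  true_sleep <- as.matrix(sched[sched$state == "sleep", c("start_s", "end_s")])
  main <- which.max(true_sleep[, 2] - true_sleep[, 1])
  off_s <- cfg$annotation_offset_min * 60
  reported <- c(max(0, true_sleep[main, 1] + off_s),
                min(cfg$duration_s, true_sleep[main, 2] - off_s))
  list(series = series,
       annotation = annotation(reported),
       truth = list(sleep_intervals = unname(true_sleep),
                    onset_s = unname(true_sleep[main, 1]),
                    schedule = sched))
}

#' Generate a synthetic cohort with an injected male aging trend
#'
#' Draws per-subject configurations matching the shape of the study
#' cohort: by default 75 subjects, 40 men aged 16-57 and 35 women aged
#' 16-56. For men, both the sleep RSA amplitude and the sleep/awake
#' baseline heart-rate contrast shrink linearly with age (the autonomic
#' sleep/awake contrast fades), so the class-separation statistic carries a
#' negative age trend; for women both stay flat. Subject seeds derive
#' deterministically from the master seed.
#'
#' @param n_male,n_female cohort composition.
#' @param age_range_m,age_range_f age ranges sampled uniformly.
#' @param duration_h per-subject recording duration (shorten for quick
#'   experiments).
#' @param seed master seed.
#' @param materialize if `TRUE`, generate all recordings now (memory-heavy
#'   for long recordings); otherwise return the configs and generate
#'   lazily via [generate_recording()].
#' @return list with `demographics` (data.frame `id`, `age`, `sex`,
#'   `seed`), `configs` (list of [synth_config()]), and — when
#'   materialized — `recordings`.
#' @export
generate_cohort <- function(n_male = 40, n_female = 35,
                            age_range_m = c(16, 57), age_range_f = c(16, 56),
                            duration_h = 24, seed = 1, materialize = FALSE) {
  n <- n_male + n_female
  if (n < 1L) stop("cohort must contain at least one subject")
  set.seed(seed)
  sex <- c(rep("M", n_male), rep("F", n_female))
  age <- round(c(stats::runif(n_male, age_range_m[1], age_range_m[2]),
                 stats::runif(n_female, age_range_f[1], age_range_f[2])))
  seeds <- sample.int(2^30, n)
  jitter_rsa <- stats::rnorm(n, sd = 0.3)
  jitter_base <- stats::rnorm(n, sd = 1)
  configs <- vector("list", n)
  for (i in seq_len(n)) {
    if (sex[i] == "M") {
      frac <- (age[i] - age_range_m[1]) / diff(age_range_m)
      rsa_sleep <- max(1, 5 - 2.5 * frac + jitter_rsa[i])
      contrast <- max(6, 20 - 8 * frac + jitter_base[i])
    } else {
      rsa_sleep <- max(1, 5 + jitter_rsa[i])
      contrast <- max(6, 20 + jitter_base[i])
    }
    configs[[i]] <- synth_config(
      duration_h = duration_h,
      hr_base = c(awake = 78, sleep = 78 - contrast),
      rsa_amp = c(awake = 1.5, sleep = rsa_sleep),
      seed = seeds[i])
  }
  out <- list(demographics = data.frame(id = seq_len(n), age = age, sex = sex,
                                        seed = seeds),
              configs = configs)
  if (materialize)
    out$recordings <- lapply(configs, generate_recording)
  out
}
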