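---
title: "Detecting sleep from heart-rate variability with shapelets"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting sleep from heart-rate variability with shapelets}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 7)
library(hrvshape)
```

## The physiological signal

During sleep the vagal (parasympathetic) branch of the autonomic nervous
system dominates, and the heart rhythm becomes strongly modulated by
respiration: *respiratory sinus arrhythmia* (RSA), a quasi-periodic
oscillation of instantaneous heart rate in a band around 0.25 Hz (a ~4-s
respiration cycle). Awake, the modulation is weaker and the mean heart rate
is higher. This package exploits that contrast to decide, from beat-to-beat
RR intervals alone, whether a subject is asleep, and to pinpoint when sleep
began.

The working hypothesis is self-similarity: short chunks of the heart-rate
series recorded during sleep recur, with very similar shape, throughout
sleep — because the RSA oscillation stamps a repeating pattern a few
respiration cycles long onto the series — while awake activity is far more
heterogeneous. A well-chosen chunk ("shapelet") therefore sits close, in
sliding Euclidean distance, to sleep segments and far from awake segments.

## The procedure

1. **Preprocessing** (`load_rr()`, `filter_hr()`, `resample_uniform()`,
   `normalize_series()`). RR intervals (ms) are converted to instantaneous
   heart rate (60000/RR, bpm). Beats outside 40–180 bpm — the standard
   ambulatory-ECG artifact bounds — are dropped; on realistic data this
   removes a fraction of a percent. The irregular beat series is then
   linearly interpolated onto a uniform 2-Hz grid. This resampling step is a
   design choice of the package: sliding a shapelet along a segment "point
   by point" only makes sense when both live on a common grid, and a fixed
   grid gives every 2-min segment the same sample count. Whether removed
   artifact gaps should instead exclude their segments is genuinely open;
   since removal rates are well below 1% the gaps are rare and short, so we
   bridge them by interpolation and warn when a gap exceeds 5 s. Finally the
   whole recording is min–max scaled to [0, 1] with a single affine map —
   never per segment, which would destroy the sleep/awake amplitude
   contrast. Distances are therefore dimensionless and invariant under
   positive affine transforms of the raw heart rate, and their scale matches
   the distance histograms on which the split-point search operates.

2. **Segments and the shapelet pool** (`segmentize()`, `build_pool()`,
   `pool_manifest()`). The recording is tiled into non-overlapping 2-min
   segments (720 for a full day); heart activity is treated as roughly
   stationary at that scale. Each segment yields a three-level pool:
   level 1 halves (60 s), level 2 quarters (30 s), level 3 eighths (15 s),
   plus a half-shifted copy of each level with one fewer member — 2+1, 4+3,
   8+7, i.e. 25 shapelets per segment. A level-3 shapelet spans roughly 3–4
   respiration cycles, which is the natural scale of the RSA pattern.
   Deeper levels are supported (`build_pool(levels =)`), but windows below
   15 s carry too little pattern and add nothing.

3. **Distances** (`distance_sq()`, `shapelet_delta()`, `distance_vector()`,
   `distance_matrix()`). The elementary distance is the *sum of squared
   differences* of two equal-length windows — deliberately without the
   square root, as the method's split-point search is monotone-invariant and
   the squared form is cheaper. The shapelet-to-segment distance δ is the
   minimum over all one-sample-step alignments of the shapelet inside the
   segment; the distance of a shapelet to its own parent segment is exactly
   zero. No per-length normalization is applied, so shorter shapelets
   achieve smaller distances; comparisons across levels happen only through
   the information-gain criterion, which is unaffected. An all-to-all
   segment matrix (row *i* = distances from an equivalently positioned
   shapelet of segment *i*, by default the last main level-2 quarter) is
   slightly asymmetric because each row uses a different shapelet; the
   package reports the relative asymmetry and hands the symmetrized
   `(M + t(M))/2` downstream.

4. **Split-point search** (`distance_histogram()`, `information_gain()`,
   `optimal_split()`, `best_shapelet()`). The distances from one shapelet to
   all segments form a histogram with (for an informative shapelet) a
   near-zero peak — segments in the same state as the shapelet — and a
   far peak. Every interior bin edge is a tentative threshold: segments
   below it form class A, the rest class B; each class is assigned the
   majority of the self-reported labels it contains, and the information
   gain is the label entropy minus the count-weighted entropies of
   correctly- vs mis-classified segments within each class,
   `IG = E(D) − n_awake/n_total·E(D_awake) − n_sleep/n_total·E(D_sleep)`,
   all in bits. The optimal split maximizes IG (ties: smallest threshold);
   the best shapelet maximizes IG over the pool (ties: pool order — earlier
   segment, higher level, main before shifted, lower position — tie-breaks
   are implementation conventions; the method itself does not fix them). For full-day recordings the exhaustive pool holds 18,000
   candidates; `sampler = "random"` with `k` ≈ 200 reaches within a few
   percent of the exhaustive maximum in our experiments and is the default
   in the pipeline.

   Two readings of the "entropy before" term are possible: the entropy of
   the self-reported label proportions, or of the class proportions. For
   binary labels and a binary split the two resulting gains are the same
   number — both equal the mutual information between split class and
   self-report — so the package implements the label-based decision-stump
   form and the choice is immaterial. For the same reason IG is invariant
   under swapping the label names and bounded by the label entropy, with
   equality exactly for a perfect split. `bin_sensitivity()` re-runs the
   search at bin widths of 1–3% and 10–30% of the distance range and
   compares the threshold variability of the two groups with Levene's test;
   the bin size plays essentially no role.

5. **Classification, ensemble, onset** (`classify_binary()`,
   `ensemble_score()`, `detect_onset()`). The best shapelet's split labels
   every segment sleep or awake. For a continuous vigilance score,
   `ensemble_score()` averages the votes of 50 random shapelets (random
   level, random sample offset — not just the structured half-shifts — and
   random location in the recording), each classified through its own
   optimal split; the score is the fraction voting awake. The onset of
   sleep is the start of the qualifying sleep run — at least 5 consecutive
   sleep segments, i.e. 10 min — whose start lies nearest the self-reported
   lights-off; a distance tie resolves to the earlier run, and ensemble
   scores are binarized at 0.5 with the boundary counted as sleep. Both
   choices deliberately err toward *early* sleep calls: in the intended
   alarm-type applications a false positive (alarm while awake) is far
   cheaper than a false negative. When no qualifying run exists the result
   is an explicit no-onset value, not an error.

6. **Separation and demographics** (`separation_statistic()`,
   `age_regression()`). The gap between the two histogram peaks — mean δ of
   the awake-majority class minus mean δ of the sleep-majority class —
   quantifies how discriminable the two states are for a subject. Its sign
   only records which state the best shapelet came from (the near class is
   always the shapelet's own state), so cohort-level analyses use its
   magnitude. `age_regression()` fits ordinary least squares of separation
   on age per sex.

## The synthetic generator

No public recordings accompany the method, so `generate_recording()`
produces test data with known ground truth. Instantaneous heart rate is

    HR(t) = hr_base(state) + circadian_amp·sin(2π t/24 h)
            + rsa_amp(state)·sin(2π f_resp(state)·t) + noise

with defaults chosen to match the phenomenology of ambulatory recordings:
awake base 78 bpm vs sleep 58 bpm (the heart beats slower asleep), RSA
amplitude 1.5 vs 5 bpm at 0.30 vs 0.25 Hz (sleep deepens and slows the
respiratory modulation), a 3-bpm circadian drift with its minimum placed
mid-sleep, and 1.5 bpm beat-to-beat Gaussian noise. Beats are emitted by
integrating HR/60 on a 0.1-s grid and placing a beat whenever the integral
advances by one — not by naively sampling RR = 60000/HR at arbitrary
times — so the RR sequence is internally consistent with the rate that
generated it. A 24-h default day contains the main sleep block (hours
14–22 of a recording taken to start at 09:00) and a 20-min afternoon nap;
artifacts replace 0.63% of the recorded RR values with out-of-band beats
(half tachycardic, half bradycardic) *without* dilating the time axis,
mimicking detection errors; and the self-report annotation covers only the
main sleep block, offset by 5 min at each edge (lights-off before sleep
actually starts). An optional `ramp_min` blends the awake parameters into
the sleep parameters over the minutes before each sleep interval, emulating
pre-sleep relaxation. `generate_cohort()` draws per-subject configurations
(40 men 16–57, 35 women 16–56 by default) in which, for men only, both the
sleep RSA amplitude and the sleep/awake base-rate contrast shrink with age.
The injected trend touches the base-rate contrast as well as RSA because,
under global min–max normalization, shrinking RSA alone *narrows the
recording range* and thereby inflates normalized distances — the net effect
on the separation statistic would be ambiguous; letting the whole autonomic
sleep/awake contrast fade with age (which is also the physiologically
realistic picture) makes the injected decline express itself cleanly.

What the generator does *not* emulate: REM/non-REM microstructure,
baroreflex and sympathetic dynamics, movement artifacts with temporal
structure, ectopic beats, or between-night variability. Passing the
recovery tests therefore shows that the implementation is faithful and that
the method works when its core premise (state-dependent self-similarity)
holds — it does not certify performance on real Holter data.

## Numerical choices

* Sliding distances are computed through the expansion
  `|w−s|² = |w|² − 2 w·s + |s|²` with a single linear-filter pass over the
  whole recording; because the expansion cancels catastrophically near
  zero, the near-minimal alignments of every segment are re-evaluated
  directly, so reported minima are exact (the parent-segment distance is
  exactly 0, not 1e−13).
* Histogram bins: `round(1/bin_frac)` equal-width bins spanning exactly
  [min, max]; only interior edges are tentative thresholds. Degenerate
  cases (constant distances, all-sleep or all-awake self-report) abort
  with explicit errors rather than returning a silent zero-gain split.
* The class-A rule is strictly `delta < threshold`; a distance equal to
  the threshold falls in class B, consistently between the histogram scan
  and `information_gain()`.
* Butterworth display smoothing (order 2, cutoff one cycle per 30 min at
  the segment rate) is applied around the series mean, because a
  zero-padded forward–backward pass would drag the edges toward zero. It
  is display-only and never feeds classification.
* `max(0, ·)` clamps information gains against −1e−16-scale floating
  noise.

## Problem sizes in the test-suite experiments

The packaged experiments run on synthetic days at 2 Hz: single-day
recovery uses one 24-h recording with a 200-candidate random search;
onset recovery uses twenty 24-h days at 100 candidates; the conservatism
experiment uses twenty 6-h evenings (4 h awake, 2 h sleep, 15-min ramp) at
60 candidates; the cohort experiment uses twelve 3-h male recordings at 40
candidates with the search restricted to level 2, so that the separation
magnitudes being regressed share a scale across subjects (δ is
length-dependent, so separations from different levels are not directly
comparable). These sizes recover the expected behavior stably while keeping
the whole suite inside a few minutes; all of them scale up linearly if
larger experiments are wanted.

## A worked example

```{r example, eval = FALSE}
rec <- generate_recording(synth_config(seed = 11))
flt <- filter_hr(rec$series)
segs <- segmentize(normalize_series(resample_uniform(flt$series, fs = 2)))
labels <- segment_labels(rec$annotation, segs)

bs <- best_shapelet(segs, labels, sampler = "random", k = 200, seed = 5)
track <- classify_binary(bs$dv, bs$split, start_s = segs$start_s)
detect_onset(track, rec$annotation$sleep[1, 1])
plot(track, ann = rec$annotation)
```

## Known limitations

* The method needs a self-report annotation; with a constant label the
  information gain is undefined and the pipeline stops by design.
* Distances are length-dependent across levels; only IG makes levels
  comparable.
* The separation statistic's sign is an artifact of the best shapelet's
  origin; use magnitudes across subjects.
* Awake periods are classified conservatively: quiet wakefulness tends to
  be called sleep. This is the intended bias, not an accuracy bug.
* Prediction of sleep *ahead* of time is out of scope; the method
  establishes the onset at, or shortly after (sometimes before, with
  relaxation), the transition.
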