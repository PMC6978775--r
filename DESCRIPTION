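Package: hrvshape
Title: Shapelet-Based Sleep/Awake Classification from Heart Rate Variability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects the sleep/awake state of a subject from beat-to-beat
    RR-interval (heart rate variability) recordings alone. A 24-h recording is
    converted to heart rate, artifact-filtered, resampled to a uniform grid
    and cut into 2-min segments; each segment is decomposed into a three-level
    pool of shapelets (60/30/15 s sub-windows plus half-shifted copies). The
    sliding minimum sum-of-squared-differences distance from a shapelet to
    every segment, combined with an information-gain split-point search
    against self-reported lights-off/lights-on annotations, yields the best
    shapelet and a binary consciousness track; an ensemble of random shapelets
    gives a continuous vigilance score. Includes onset-of-sleep detection via
    a consecutive-run rule, a class-separation statistic with its age
    regression, and a synthetic RR generator with state-dependent respiratory
    sinus arrhythmia, circadian drift, naps, artifacts and imperfect
    self-report for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    signal,
    car,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
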