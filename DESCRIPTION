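Package: bearrhythms
Title: Annual and Daily Rhythm Analysis for Brown Bear Biologging Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools to detect and model biological rhythms in year-round
    biologging records (body temperature, heart rate, activity) of
    free-ranging brown bears. Provides hibernation phenology detection
    from sustained daily body-temperature threshold crossings, seasonal
    state assignment with per-variable transition offsets, tiling of
    seasonal states into 15-25 day analysis windows, Lomb-Scargle
    periodogram estimation for unevenly sampled series with rhythm
    classification into ultradian, diel, infradian and arrhythmic
    categories, construction of environmental and intrinsic covariates
    (inverse-distance-weighted weather interpolation, photoperiod),
    penalized multinomial spline models of rhythm-class probabilities
    with cross-validated predictive-density model comparison and
    stacking, double-plot actogram matrices, and a synthetic bear-year
    generator with known ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    mgcv,
    stats,
    utils
Suggests:
    jsonlite,
    nnet,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
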