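---
title: "Methods: rhythm detection and modelling in bear biologging data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: rhythm detection and modelling in bear biologging data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bearrhythms)
```

This vignette documents the statistical procedure implemented by
`bearrhythms`, the assumptions behind each stage, the tunable parameters
and their defaults, and the design decisions taken where the analysis
admitted more than one reasonable choice.

## Seasonal segmentation

Hibernation phenology is operationalized through daily mean body
temperature: den entry is the **first autumn day** on which the daily
mean Tb is at or below **36.4 °C for seven consecutive observed days**,
den exit the first spring day at or above **36.7 °C** for seven
consecutive days. Three choices deserve comment.

* *Search windows.* "Autumn" and "spring" are bounded as Aug 1 – Jan 31
  and Feb 1 – Jul 31 by default (configurable). The candidate first day
  must fall inside the window; the seven-day run may extend past it.
* *Missing days break runs.* The definition requires seven *observed*
  daily means; a day without samples is never imputed and interrupts a
  candidate run. Imputation would let capture gaps manufacture
  phenology.
* *Transition offsets.* Tb, HR and activity change on different
  schedules around den entry/exit. The per-variable offsets (days
  before/after entry and exit) default to Tb (13, 30, 33, 0),
  HR (24, 30, 63, 0) and activity (25, 9, 10, 0). The pre-entry and
  pre-exit values are published observations; the post-entry offset for
  HR and all post-exit offsets are package defaults, exposed in
  `default_transition_offsets()` and flagged as assumptions rather than
  measured quantities. With zero offsets on both sides a year collapses
  to `{active, hibernation}` split exactly at entry/exit; overlapping
  transitions (a very short hibernation) are truncated at their
  midpoint with a warning.

## Windowing

Each state interval is tiled with consecutive **25-day** windows from
the state's first day; a terminal remainder is kept only if it spans at
least **15 days** — merging it backward would create windows longer than
25 days, violating the stated maximum, so remainders below the floor are
dropped and logged. A window is discarded when the spacing between
consecutive retained samples (or between a window edge and the nearest
sample) exceeds **2 days**. The 15-day floor guarantees at least ten
cycles for diel detection. Whether a mid-state gap should drop or merely
truncate a window is not determined by the definitions; we drop and log,
which keeps every retained window's duration interpretation clean.

Each window carries a *season* grouping identifier: the calendar year of
the window start for active windows, and the den-entry year for
hibernation and transition windows (so one winter is one season even
when it crosses New Year). The season definition is a package
convention.

## Lomb-Scargle rhythm detection

The classical normalized Lomb-Scargle periodogram is computed over the
2–168 h period band on a frequency grid with spacing
`1/(oversampling × window length)`; the default oversampling of 4
balances resolution at the 2 h band edge against runtime. Values are
mean-centred, the per-frequency phase offset decouples the sine and
cosine terms, and powers are normalized by twice the sample variance, so
the power at a frequency equals the least-squares sinusoid-fit reduction
there and pure-noise powers are approximately Exponential(1). The
implementation is verified against a brute-force least-squares oracle at
`1e-8` relative tolerance in the test suite.

The highest peak over the band is tested with the independent-frequency
bound `p = 1 − (1 − e^(−z))^M`. We take **M = the number of frequencies
actually searched** (the oversampled band grid). Neighbouring
oversampled frequencies are correlated, so this bound is mildly
conservative; calibration simulations in the test suite (2000 white-noise
windows) show the realized false-alarm rate at α = 0.01 lies within the
nominal band. Using the coarser un-oversampled frequency count instead
under-corrects — the maximum is searched over the fine grid — and
empirically rejects at roughly three times the nominal rate, which is why
the searched-grid count is the package's convention.

Significant peaks are classified **ultradian** (2–18 h), **diel**
(18–36 h) or **infradian** (36–168 h); non-significant windows are
**arrhythmic**, with the peak period still reported. Band boundaries are
half-open upward (a peak at exactly 18 h is diel); no published boundary
values exist, so any consistent convention serves, and this one is
documented and property-tested. The significance level α defaults to
0.01 and is exposed in the configuration; only the highest peak is
classified — multi-peak reporting, wavelets and cosinor fits are out of
scope. Periods below 2 h are ignored even at the 2-min HR cadence,
matching the classification floor.

## Covariates

* *Day length* follows the standard Forsythe et al. (1995) model with
  the conventional 0.8333° sunrise/sunset depression; it agrees with
  `geosphere::daylength` to numerical precision (a test cross-check) and
  with the package's sunrise/sunset times to well under 10 minutes. Its
  direction over a window is the sign of the endpoint difference, ties
  classified *increasing* — a convention needed only for windows almost
  perfectly centred on a solstice.
* *Weather* is interpolated by inverse-distance weighting from the
  **k = 3** nearest stations with exponent **2** (the conventional IDW
  default; the method's exponent is otherwise unconstrained), using
  great-circle distances. A target within 1 m of a station returns that
  station's value exactly; with fewer than k reporting stations all
  available ones are used with a warning.
* Window means are taken over the window's calendar days at the bear's
  summer-range position for active and transition windows and at the den
  for hibernation windows, switching coordinates on recorded den-change
  dates. Incomplete covariate records are emitted with missing markers
  and dropped by the models.

## Multinomial rhythm-probability models

The rhythm class of a window is modelled by multinomial logistic
regression with linear predictors per non-reference class. Continuous
effects enter as **thin-plate regression smooths** whose penalty null
space is the linear function — under heavy penalization a smooth
collapses to a straight line. Grouping factors (bear identity, season)
enter as ridge-penalized indicator blocks, the penalized-likelihood
analogue of group-level intercepts. This is a deliberate methodological
substitution: the deterministic penalized-ML fit with K-fold
cross-validation replaces a Bayesian MCMC fit with PSIS-LOO, trading
posterior uncertainty for reproducibility and desk-scale runtime; it is
documented as an analogue, not a reproduction, and no posterior
quantities (credible intervals, convergence diagnostics) are produced.

Numerical choices:

* The objective (log-likelihood minus penalties) is concave; a full
  Newton iteration with step halving is run to a gradient sup-norm below
  `1e-6`. Penalties are scaled with the number of observations, so
  duplicating every row leaves estimates unchanged.
* One smoothing parameter λ is shared by all smooth terms and selected
  by 5-fold cross-validated log score over the grid
  {0.01, 0.1, 1, 10, 100}; per-term λs would square the search for
  little gain at these data sizes. The group ridge rate defaults to 0.1.
* The reference class is *diel* when present (the most frequent class
  overall), otherwise the most frequent observed class.
* Linear predictors beyond ±30 pin probabilities to machine 0/1; the
  likelihood is flat there, so coefficients exceeding that bound are
  reported as (quasi-)separation with a warning.
* Standard errors come from the inverse of the penalized observed
  information.

Model comparison uses the cross-validated **elpd** (sum of held-out log
predictive probabilities of the observed class; standard error from the
pointwise variance). Folds default to 10 and are **grouped by bear** so
no individual spans folds, approximating the leave-one-group-out
structure implied by group-level effects; when the grouping column is
absent, folds are stratified by class. A training fold missing a class
is penalized through the model itself (no special-casing) with a
warning. Models whose elpd lies within 4 of the best are combined by
**stacking**: the simplex weights maximizing the summed log of the
weighted held-out densities, found by deterministic multiplicative
updates on the (concave) objective; duplicate predictive distributions
are collapsed first and tied weight split evenly. The candidate sets for
the hibernation (15 models) and active-state (13 models) analyses are
constructible by name via `candidate_models()`.

## The synthetic generator

`simulate_bear_year()` emulates the structure the pipeline must handle:
state-dependent baselines with **linear** daily-mean drifts through the
transitions (the published profiles show gradual change without a
functional form; a line is the least-committal choice), anchored so the
daily mean crosses 36.4 °C exactly on the planted entry day and 36.7 °C
on the exit day — making phenology exactly recoverable on noise-free
traces. Active-state Tb/HR carry 24 h + 12 h sinusoids; hibernation
carries a multiday oscillation (default period 120 h) and, for activity,
a small residual 24 h component (default 5 counts) so diel hibernation
activity is an available scenario rather than an impossibility. Noise is
stationary AR(1) (default lag-1 coefficient 0.8) because raw biologging
traces are strongly autocorrelated; activity is rectified to \[0, 510\]
and quantized. Captures remove 14 days, disturbances 3 days.

No published amplitude or noise magnitudes exist for these variables;
the defaults (e.g. Tb diel amplitude 0.5 °C, noise SD 0.15 °C, activity
diel amplitude 80 counts) are free parameters chosen once to be
physiologically plausible, not measured values. The weather generator
produces a smooth seasonal temperature cycle and snow that is zero in
summer and rises smoothly through winter, inside the observed covariate
ranges (mean Ta −15.4–19.1 °C, snow 0–0.63 m).

What the generator does **not** emulate: den microclimate, GPS
movement, photoperiod-driven phase drift within a window, irregular
cadence jitter, or pregnancy-specific Tb profiles. Passing tests
therefore demonstrate correctness of the *methods* under known ground
truth, not field-data effect sizes: real-cohort probabilities and period
tables require the original field data and are explicitly out of scope.

## Problem sizes

The validation suite uses 25-day windows at a 30-min cadence for
spectral checks (600 tone windows, 2000 noise windows), 50 seeded
bear-years per noise level for phenology, and 20 cohorts of n = 2000
windows for model recovery — sizes at which every Monte-Carlo check
is stable while the whole suite stays desk-scale.

## Known limitations

* The analytic false-alarm bound is an approximation; a randomization
  test is not implemented (the analytic form is the default and only
  method).
* One shared smoothing parameter across smooth terms.
* Confidence intervals are Wald-type from the observed information;
  no posterior or bootstrap uncertainty.
* Den relocation affects covariate locations only, never state labels.
* The pipeline assumes the fixed UTC+1 civil time of the study area.
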