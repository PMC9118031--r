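# bearrhythms

Tools for detecting and modelling biological rhythms in year-round
biologging records of free-ranging brown bears (*Ursus arctos*):
body temperature (Tb), heart rate (HR) and locomotor activity.

Brown bears in Scandinavia hibernate for up to seven months, and their
daily organisation changes radically across the year: crepuscular or
nocturnal activity with ~24 h (diel) and ~12 h (ultradian) rhythms while
active, and depressed body temperature with multiday (infradian)
oscillations during hibernation. `bearrhythms` implements the full
analysis chain for such data:

1. **Phenology** — den entry is the first autumn day whose daily mean Tb
   is ≤ 36.4 °C for seven consecutive observed days; den exit the first
   spring day with daily mean Tb ≥ 36.7 °C for seven consecutive days.
   Each bear-year is segmented into *active*, *transition (den entry)*,
   *hibernation* and *transition (den exit)* states, with per-variable
   transition offsets (e.g. Tb starts to fall 13 days before entry and
   keeps falling 30 days after; activity 25 days before and 9 after).
2. **Windowing** — data are cleaned (Tb < 30 °C removed; 14 days after a
   capture and 3 days after a disturbance discarded) and each state is
   tiled into consecutive 25-day analysis windows (terminal remainders
   ≥ 15 days kept; windows containing a sampling gap > 2 days dropped).
3. **Rhythm detection** — the Lomb-Scargle periodogram, the least-squares
   spectral estimator valid for unevenly sampled series, is evaluated
   over the 2–168 h band. For mean-centred values *y* at times *t* and
   frequency ω the normalized power is

   P(ω) = \[ (Σ y cos ω(t−τ))² / Σ cos² ω(t−τ)
           + (Σ y sin ω(t−τ))² / Σ sin² ω(t−τ) \] / (2 s²),

   with τ the decoupling phase and s² the sample variance; P equals the
   least-squares sinusoid-fit reduction at ω. The highest peak is tested
   against the white-noise null with the independent-frequency bound
   p = 1 − (1 − e^(−z))^M and classified as **ultradian** (2–18 h),
   **diel** (18–36 h), **infradian** (36–168 h) or, when not significant,
   **arrhythmic**.
4. **Covariates** — per-window means of ambient temperature and snow
   depth (inverse-distance-weighted from the three nearest stations),
   photoperiod (Forsythe day-length model) and its direction, plus den
   and intrinsic predictors (den type, open area, body mass, sex, age
   class, reproductive status).
5. **Rhythm-probability models** — multinomial logistic regression of the
   rhythm class on covariates, with thin-plate regression smooths that
   shrink to straight lines under penalization and ridge-penalized group
   effects for bear and season; fitted by penalized maximum likelihood
   (full Newton). Candidate models are compared by K-fold
   cross-validated expected log predictive density (elpd) and combined by
   stacking of predictive distributions; the printed candidate sets for
   the hibernation (15 models) and active-state (13 models) analyses are
   built by `candidate_models()`.
6. **Reporting** — double-plot actogram/thermogram matrices (day *x*
   beside day *x + 1*), sunrise/sunset overlays and period summary
   tables by state and rhythm class.

A synthetic bear-year generator (`simulation_config()`,
`simulate_bear_year()`, `simulate_weather()`, `simulate_rhythm_cohort()`)
produces cohorts with known ground truth — planted den dates, rhythm
periods and multinomial coefficients — so every stage is testable
without any field data.

## Worked example

```r
library(bearrhythms)

cfg  <- simulation_config(n_bears = 1, seed = 42)
sim  <- simulate_bear_year(cfg, "bear01", variables = "tb")
smap <- seasonal_state_map(sim$series$tb)
cat("den entry:", format(smap$den_entry),
    " den exit:", format(smap$den_exit), "\n")
#> den entry: 2014-11-16  den exit: 2015-04-10

tw    <- tile_windows(smap, sim$series$tb)
calls <- calls_table(lapply(tw$windows, classify_window))
period_summary(calls)
#>             state     class mean_period_hours min_period_hours max_period_hours  n n_individuals
#>            active      diel          23.93162         23.93162         23.93162 10             1
#>       hibernation infradian         118.30986        118.30986        118.30986  3             1
#>  transition_entry infradian         150.59987        147.36842        153.83133  2             1
#>   transition_exit infradian         147.36842        147.36842        147.36842  1             1
```

The configuration plants den entry on 2014-11-15 and exit on 2015-04-10
with a 24 h active rhythm and a 120 h hibernation oscillation in Tb. The
detector recovers the exit exactly and the entry one day late (sensor
noise can move the sustained-run start by a day); the sixteen 15–25-day
windows are classified diel in the active state (peak 23.9 h, one grid
step from 24 h) and infradian in hibernation (118.3 h, one grid step
from 120 h). Transition windows, dominated by the monotone entry/exit
drift, register long-period infradian power — the reason transition
states are modelled separately. `run_pipeline()` composes the same
stages for a whole cohort, including covariates, model comparison and
stamped CSV outputs.

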