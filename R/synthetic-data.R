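# Synthetic bear-year generator: biologging series with planted seasonal
# states, rhythm components and noise, plus weather networks and
# rhythm-labelled cohorts with known ground truth.

#' Simulation configuration for synthetic bear-years
#'
#' Bundles every parameter of the synthetic biologging generator.  Defaults
#' describe a plausible Scandinavian brown-bear year: body temperature (Tb)
#' around 37.3 degC when active and 33.5 degC in hibernation, heart rate (HR)
#' around 75 and 15 beats/min, activity counts around 120 and 8, with a diel
#' (24 h) plus ultradian (12 h) rhythm while active and a multiday
#' (default 120 h) Tb/HR oscillation during hibernation.  Sensor cadences
#' follow the deployed loggers: Tb every 5-30 min, HR 2-min means, activity
#' 5-min biaxial sums in 0-510.
#'
#' Daily mean Tb drifts linearly through the transition states so that it
#' crosses the den-entry threshold (36.4 degC) exactly on `den_entry_day` and
#' the den-exit threshold (36.7 degC) exactly on `den_exit_day`, which makes
#' the planted phenology exactly recoverable by the detectors on noise-free
#' traces.
#'
#' @param n_bears Number of bears in a simulated cohort.
#' @param start_date,end_date Calendar span of the simulation (>= 60 days).
#' @param tb_cadence_minutes Tb sampling cadence, in \[5, 30\] minutes.
#' @param hr_cadence_minutes HR sampling cadence (default 2 minutes).
#' @param act_cadence_minutes Activity cadence (default 5 minutes).
#' @param active_tb_mean,hib_tb_mean State mean Tb (degC).
#' @param diel_amplitude,ultradian_amplitude Amplitudes (degC) of the 24 h
#'   and 12 h Tb components in the active state.
#' @param infradian_amplitude Amplitude (degC) of the multiday Tb
#'   oscillation during hibernation.
#' @param infradian_period_hours Period (h) of the hibernation oscillation.
#' @param noise_sd Marginal standard deviation of the Tb noise process.
#' @param ar1_coefficient Lag-1 autocorrelation of the noise (in \[0, 1)).
#' @param den_entry_day,den_exit_day Planted den entry/exit dates; scalars
#'   are recycled to `n_bears`, or supply one date per bear.
#' @param transition_offsets Per-variable transition offsets, as returned by
#'   [default_transition_offsets()].
#' @param capture_dates,disturbance_dates Lists (one element per bear) of
#'   capture and disturbance dates; data are removed for 14 days after a
#'   capture and 3 days after a disturbance.
#' @param hr_active_mean,hr_hib_mean State mean HR (beats/min).
#' @param hr_diel_amplitude,hr_ultradian_amplitude,hr_infradian_amplitude
#'   HR rhythm amplitudes (beats/min).
#' @param hr_noise_sd Marginal SD of HR noise.
#' @param act_active_mean,act_hib_mean State mean activity (counts).
#' @param act_diel_amplitude,act_ultradian_amplitude Activity rhythm
#'   amplitudes (counts) in the active state.
#' @param act_hib_diel_amplitude Small residual 24 h activity amplitude
#'   retained during hibernation (counts), so that diel hibernation
#'   activity is an available scenario rather than an impossibility.
#' @param act_noise_sd Marginal SD of activity noise.
#' @param latitude,longitude Nominal study-area coordinates.
#' @param seed Integer seed; identical configurations give identical output.
#'
#' @return An object of class `simulation_config` (a validated list).
#' @seealso [simulate_bear_year()], [simulate_weather()]
#' @export
simulation_config <- function(n_bears = 5,
                              start_date = "2014-06-01",
                              end_date = "2015-07-31",
                              tb_cadence_minutes = 5,
                              hr_cadence_minutes = 2,
                              act_cadence_minutes = 5,
                              active_tb_mean = 37.3,
                              hib_tb_mean = 33.5,
                              diel_amplitude = 0.5,
                              ultradian_amplitude = 0.25,
                              infradian_amplitude = 0.5,
                              infradian_period_hours = 120,
                              noise_sd = 0.15,
                              ar1_coefficient = 0.8,
                              den_entry_day = "2014-11-15",
                              den_exit_day = "2015-04-10",
                              transition_offsets = default_transition_offsets(),
                              capture_dates = NULL,
                              disturbance_dates = NULL,
                              hr_active_mean = 75,
                              hr_hib_mean = 15,
                              hr_diel_amplitude = 10,
                              hr_ultradian_amplitude = 5,
                              hr_infradian_amplitude = 3,
                              hr_noise_sd = 4,
                              act_active_mean = 120,
                              act_hib_mean = 8,
                              act_diel_amplitude = 80,
                              act_ultradian_amplitude = 50,
                              act_hib_diel_amplitude = 5,
                              act_noise_sd = 20,
                              latitude = 61.2,
                              longitude = 15.0,
                              seed = 1L) {
  cfg <- list(
    n_bears = as.integer(n_bears),
    start_date = as.Date(start_date), end_date = as.Date(end_date),
    tb_cadence_minutes = tb_cadence_minutes,
    hr_cadence_minutes = hr_cadence_minutes,
    act_cadence_minutes = act_cadence_minutes,
    active_tb_mean = active_tb_mean, hib_tb_mean = hib_tb_mean,
    diel_amplitude = diel_amplitude,
    ultradian_amplitude = ultradian_amplitude,
    infradian_amplitude = infradian_amplitude,
    infradian_period_hours = infradian_period_hours,
    noise_sd = noise_sd, ar1_coefficient = ar1_coefficient,
    den_entry_day = as.Date(rep(as.Date(den_entry_day), length.out = n_bears)),
    den_exit_day = as.Date(rep(as.Date(den_exit_day), length.out = n_bears)),
    transition_offsets = transition_offsets,
    capture_dates = capture_dates, disturbance_dates = disturbance_dates,
    hr_active_mean = hr_active_mean, hr_hib_mean = hr_hib_mean,
    hr_diel_amplitude = hr_diel_amplitude,
    hr_ultradian_amplitude = hr_ultradian_amplitude,
    hr_infradian_amplitude = hr_infradian_amplitude,
    hr_noise_sd = hr_noise_sd,
    act_active_mean = act_active_mean, act_hib_mean = act_hib_mean,
    act_diel_amplitude = act_diel_amplitude,
    act_ultradian_amplitude = act_ultradian_amplitude,
    act_hib_diel_amplitude = act_hib_diel_amplitude,
    act_noise_sd = act_noise_sd,
    latitude = latitude, longitude = longitude,
    seed = as.integer(seed)
  )
  validate_simulation_config(cfg)
  structure(cfg, class = "simulation_config")
}

validate_simulation_config <- function(cfg) {
  with(cfg, {
    if (end_date - start_date < 60) {
      stop_br("simulation span must be at least 60 days")
    }
    if (tb_cadence_minutes < 5 || tb_cadence_minutes > 30) {
      stop_br("tb_cadence_minutes must lie in [5, 30]")
    }
    cadences <- c(tb_cadence_minutes, hr_cadence_minutes, act_cadence_minutes)
    if (any(cadences <= 0)) stop_br("cadences must be positive")
    if (any(1440 %% cadences != 0)) {
      stop_br("cadences must divide 1440 minutes")
    }
    amps <- c(diel_amplitude, ultradian_amplitude, infradian_amplitude,
              hr_diel_amplitude, hr_ultradian_amplitude,
              hr_infradian_amplitude, act_diel_amplitude,
              act_ultradian_amplitude, act_hib_diel_amplitude)
    if (any(amps < 0)) stop_br("amplitudes must be non-negative")
    if (ar1_coefficient < 0 || ar1_coefficient >= 1) {
      stop_br("ar1_coefficient must lie in [0, 1)")
    }
    if (any(!is.na(den_entry_day) & !is.na(den_exit_day) &
            den_entry_day >= den_exit_day)) {
      stop_br("den_entry_day must precede den_exit_day")
    }
  })
  invisible(cfg)
}

# Evaluate code with a locally seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(
      rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# Per-bear event date list access tolerating NULL configs.
event_dates <- function(lst, i) {
  if (is.null(lst) || length(lst) < i || is.null(lst[[i]])) {
    return(as.Date(character()))
  }
  as.Date(lst[[i]])
}

# Stationary AR(1) + white noise with marginal sd `sd` and lag-1
# autocorrelation `rho`.
ar1_noise <- function(n, sd, rho) {
  if (sd == 0 || n == 0) return(numeric(n))
  innov <- stats::rnorm(n, 0, sd * sqrt(1 - rho^2))
  as.numeric(stats::filter(innov, rho, method = "recursive",
                           init = stats::rnorm(1, 0, sd)))
}

# Daily baseline mean for one variable across the planted seasonal states.
# Tb is anchored so the linear entry/exit drifts hit the detection
# thresholds (36.4 / 36.7 degC) exactly on the planted entry/exit dates;
# HR and activity drift linearly between their state means across their
# own transition offsets.
daily_baseline <- function(dates, variable, entry, exit, offs, cfg) {
  means <- switch(variable,
    tb = c(active = cfg$active_tb_mean, hib = cfg$hib_tb_mean),
    hr = c(active = cfg$hr_active_mean, hib = cfg$hr_hib_mean),
    activity = c(active = cfg$act_active_mean, hib = cfg$act_hib_mean))
  base <- rep(means[["active"]], length(dates))
  if (is.na(entry) || is.na(exit)) return(base)
  d <- as.numeric(dates)
  e0 <- as.numeric(entry); x0 <- as.numeric(exit)
  pre_e <- offs$pre_entry; post_e <- offs$post_entry
  pre_x <- offs$pre_exit; post_x <- offs$post_exit
  # anchor values at the entry/exit dates themselves
  if (variable == "tb") {
    v_entry <- 36.4; v_exit <- 36.7
  } else {
    # plain linear interpolation between state means over the transition
    v_entry <- means[["active"]] +
      (means[["hib"]] - means[["active"]]) * pre_e / max(pre_e + post_e, 1)
    v_exit <- means[["hib"]] +
      (means[["active"]] - means[["hib"]]) * pre_x / max(pre_x + post_x, 1)
  }
  ramp <- function(x, x1, y1, x2, y2) {
    if (x2 == x1) return(rep(y2, length(x)))
    y1 + (y2 - y1) * (x - x1) / (x2 - x1)
  }
  in_seg <- function(a, b) d >= a & d <= b
  i <- in_seg(e0 - pre_e, e0)
  base[i] <- ramp(d[i], e0 - pre_e, means[["active"]], e0, v_entry)
  i <- d > e0 & d <= e0 + post_e
  base[i] <- ramp(d[i], e0, v_entry, e0 + post_e, means[["hib"]])
  i <- d > e0 + post_e & d < x0 - pre_x
  base[i] <- means[["hib"]]
  i <- in_seg(x0 - pre_x, x0) & d > e0 + post_e
  base[i] <- ramp(d[i], x0 - pre_x, means[["hib"]], x0, v_exit)
  if (post_x > 0) {
    i <- d > x0 & d <= x0 + post_x
    base[i] <- ramp(d[i], x0, v_exit, x0 + post_x, means[["active"]])
  }
  base
}

# Which planted regime each date falls in: oscillatory components apply in
# the steady active and hibernation regimes only; transitions carry the
# drift with noise.
planted_regime <- function(dates, entry, exit, offs) {
  reg <- rep("active", length(dates))
  if (is.na(entry) || is.na(exit)) return(reg)
  d <- as.numeric(dates)
  e0 <- as.numeric(entry); x0 <- as.numeric(exit)
  reg[d >= e0 - offs$pre_entry & d <= e0 + offs$post_entry] <- "transition_entry"
  reg[d > e0 + offs$post_entry & d < x0 - offs$pre_exit] <- "hibernation"
  reg[d >= x0 - offs$pre_exit & d <= x0 + offs$post_exit] <- "transition_exit"
  reg
}

simulate_variable <- function(cfg, bear_id, variable, bear_index) {
  cad <- switch(variable,
    tb = cfg$tb_cadence_minutes,
    hr = cfg$hr_cadence_minutes,
    activity = cfg$act_cadence_minutes)
  t0 <- br_midnight(cfg$start_date)
  t1 <- br_midnight(cfg$end_date + 1)
  ts <- seq(t0, t1 - cad * 60, by = cad * 60)
  dates <- br_date(ts)
  hours <- as.numeric(ts - t0, units = "hours")

  entry <- cfg$den_entry_day[bear_index]
  exit <- cfg$den_exit_day[bear_index]
  offs <- cfg$transition_offsets[[variable]]
  # per-date baseline mapped onto samples
  base <- daily_baseline(unique(dates), variable, entry, exit, offs,
                         cfg)[match(dates, unique(dates))]
  regime <- planted_regime(dates, entry, exit, offs)

  amp <- switch(variable,
    tb = list(diel = cfg$diel_amplitude, ultra = cfg$ultradian_amplitude,
              infra = cfg$infradian_amplitude, hib_diel = 0,
              noise = cfg$noise_sd),
    hr = list(diel = cfg$hr_diel_amplitude, ultra = cfg$hr_ultradian_amplitude,
              infra = cfg$hr_infradian_amplitude, hib_diel = 0,
              noise = cfg$hr_noise_sd),
    activity = list(diel = cfg$act_diel_amplitude,
                    ultra = cfg$act_ultradian_amplitude,
                    infra = 0, hib_diel = cfg$act_hib_diel_amplitude,
                    noise = cfg$act_noise_sd))

  osc <- numeric(length(ts))
  act_i <- regime == "active"
  hib_i <- regime == "hibernation"
  # active: 24 h + 12 h components (peaks near dusk / crepuscular hours)
  osc[act_i] <- amp$diel * cos(2 * pi * (hours[act_i] - 21) / 24) +
    amp$ultra * cos(2 * pi * (hours[act_i] - 4) / 12)
  # hibernation: multiday oscillation (Tb/HR) and residual diel activity
  osc[hib_i] <- amp$infra *
    cos(2 * pi * hours[hib_i] / cfg$infradian_period_hours) +
    amp$hib_diel * cos(2 * pi * (hours[hib_i] - 21) / 24)

  values <- base + osc + ar1_noise(length(ts), amp$noise, cfg$ar1_coefficient)
  if (variable == "activity") {
    values <- round(pmin(pmax(values, 0), 510))
  }

  # planted data gaps after captures / disturbances
  keep <- rep(TRUE, length(ts))
  for (cd in as.list(event_dates(cfg$capture_dates, bear_index))) {
    keep[dates >= cd & dates < cd + 14] <- FALSE
  }
  for (dd in as.list(event_dates(cfg$disturbance_dates, bear_index))) {
    keep[dates >= dd & dates < dd + 3] <- FALSE
  }

  biologging_series(bear_id, variable, ts[keep], values[keep])
}

#' Simulate one bear-year of biologging data with known ground truth
#'
#' Generates body temperature, heart rate and activity series for one bear
#' over the configured span.  Each trace is a state-dependent daily baseline
#' (active / linear transition drift / hibernation) plus sinusoidal rhythm
#' components (24 h and 12 h while active; a multiday oscillation during
#' hibernation, with a small residual 24 h activity component) plus
#' stationary AR(1) noise.  Activity is rectified to \[0, 510\] and
#' quantized to integer counts.  Data are removed for 14 days after each
#' planted capture and 3 days after each disturbance.
#'
#' @param config A [simulation_config()].
#' @param bear_id Identifier of the simulated bear (also selects the bear's
#'   entry/exit dates and event lists from the config, matched by position
#'   via `bear_index`).
#' @param bear_index Position of this bear in the config vectors (default 1).
#' @param variables Which of `"tb"`, `"hr"`, `"activity"` to generate.
#'
#' @return A list with elements `series` (named list of biologging series
#'   data frames) and `truth` (planted den entry/exit dates and the true
#'   dominant period and rhythm class per variable and regime).
#' @export
simulate_bear_year <- function(config, bear_id,
                               bear_index = 1L,
                               variables = c("tb", "hr", "activity")) {
  stopifnot(inherits(config, "simulation_config"))
  validate_simulation_config(config)
  variables <- match.arg(variables, several.ok = TRUE)
  series <- with_seed(config$seed + 1000L * bear_index, {
    out <- lapply(variables, function(v)
      simulate_variable(config, bear_id, v, bear_index))
    names(out) <- variables
    out
  })
  truth <- list(
    bear_id = bear_id,
    den_entry = config$den_entry_day[bear_index],
    den_exit = config$den_exit_day[bear_index],
    state_periods = planted_periods(config)
  )
  list(series = series, truth = truth)
}

# True dominant period and class per variable/regime implied by the
# configured amplitudes.
planted_periods <- function(cfg) {
  pick <- function(amps, periods) {
    if (all(amps == 0)) return(c(NA_real_, NA_character_))
    i <- which.max(amps)
    c(periods[i], rhythm_band(periods[i]))
  }
  rows <- list(
    c("tb", "active", pick(c(cfg$diel_amplitude, cfg$ultradian_amplitude),
                           c(24, 12))),
    c("tb", "hibernation", pick(cfg$infradian_amplitude,
                                cfg$infradian_period_hours)),
    c("hr", "active", pick(c(cfg$hr_diel_amplitude, cfg$hr_ultradian_amplitude),
                           c(24, 12))),
    c("hr", "hibernation", pick(cfg$hr_infradian_amplitude,
                                cfg$infradian_period_hours)),
    c("activity", "active",
      pick(c(cfg$act_diel_amplitude, cfg$act_ultradian_amplitude), c(24, 12))),
    c("activity", "hibernation", pick(cfg$act_hib_diel_amplitude, 24))
  )
  out <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  names(out) <- c("variable", "regime", "period_hours", "class")
  out$period_hours <- as.numeric(out$period_hours)
  out
}

#' Simulate a daily weather-station network
#'
#' Places `n_stations` around the study area and generates daily ambient
#' temperature (min/mean/max) and snow depth per station: a smooth seasonal
#' temperature cycle with station-level offsets, and snow that is zero in
#' summer and rises smoothly through winter.  Values stay within the
#' observed study ranges (mean Ta in -15.4 to 19.1 degC, snow depth in
#' 0 to 0.63 m).
#'
#' @param config A [simulation_config()] (supplies span and centre
#'   coordinates).
#' @param n_stations Number of stations (>= 3).
#' @param seed Integer seed.
#'
#' @return A data frame with columns `station_id`, `lat`, `lon`, `date`,
#'   `ta_min`, `ta_mean`, `ta_max`, `snow_depth`.
#' @export
simulate_weather <- function(config, n_stations = 5, seed = config$seed) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_stations < 3) stop_br("n_stations must be >= 3")
  dates <- seq(config$start_date, config$end_date, by = "day")
  doy <- as.integer(format(dates, "%j"))
  with_seed(seed + 77L, {
    out <- vector("list", n_stations)
    for (s in seq_len(n_stations)) {
      lat <- config$latitude + stats::runif(1, -0.8, 0.8)
      lon <- config$longitude + stats::runif(1, -1.5, 1.5)
      offset <- stats::rnorm(1, 0, 1)
      # seasonal cycle peaking mid-July (doy 196)
      ta_mean <- 1.5 + 12 * cos(2 * pi * (doy - 196) / 365.25) + offset +
        stats::rnorm(length(doy), 0, 1.5)
      ta_mean <- pmin(pmax(ta_mean, -15.4), 19.1)
      spread <- 3.5 + abs(stats::rnorm(length(doy), 0, 1))
      # snow: zero May-Oct, smooth rise Nov-Mar, melt through April
      s_max <- stats::runif(1, 0.3, 0.55)
      winter <- cos(2 * pi * (doy - 15) / 365.25)    # peaks mid-January
      snow <- pmax(0, s_max * (winter - 0.25) / 0.75)
      out[[s]] <- data.frame(
        station_id = sprintf("st%02d", s), lat = lat, lon = lon,
        date = dates,
        ta_min = ta_mean - spread, ta_mean = ta_mean,
        ta_max = ta_mean + spread,
        snow_depth = round(snow, 3),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Simulate a rhythm-labelled cohort from known multinomial coefficients
#'
#' Draws per-window covariates from supplied distributions and samples
#' rhythm-class labels from the multinomial-logit probabilities implied by a
#' known coefficient matrix, for parameter-recovery experiments.
#'
#' @param n_windows Number of windows (observations) to generate.
#' @param true_coefficients Matrix with one row per predictor column of the
#'   design (first row the intercept, remaining rows named after
#'   covariates) and one column per non-reference class (column names are
#'   the class labels).
#' @param covariate_distributions Named list of functions `f(n)` drawing
#'   `n` covariate values; names must match the coefficient row names.
#' @param reference_class Label of the reference class (first level).
#' @param seed Integer seed.
#'
#' @return A list with `covariates` (data frame), `labels` (factor with the
#'   reference class as first level), `probabilities` (the true class
#'   probabilities per window) and `coefficients` (as supplied).
#' @export
simulate_rhythm_cohort <- function(n_windows, true_coefficients,
                                   covariate_distributions,
                                   reference_class = "diel",
                                   seed = 1L) {
  coefs <- as.matrix(true_coefficients)
  covars <- rownames(coefs)[-1]
  if (!setequal(covars, names(covariate_distributions))) {
    stop_br("coefficient rows and covariate_distributions names must match")
  }
  if (is.null(colnames(coefs)) || ncol(coefs) < 1) {
    stop_br("true_coefficients needs one named column per non-reference class")
  }
  with_seed(seed, {
    X <- vapply(covars, function(v) covariate_distributions[[v]](n_windows),
                numeric(n_windows))
    X <- cbind(`(Intercept)` = 1, X)
    eta <- X %*% coefs
    expEta <- cbind(1, exp(eta))          # reference class first
    probs <- expEta / rowSums(expEta)
    classes <- c(reference_class, colnames(coefs))
    colnames(probs) <- classes
    labels <- factor(
      classes[apply(probs, 1, function(p) sample.int(length(p), 1, prob = p))],
      levels = classes)
    list(covariates = as.data.frame(X[, -1, drop = FALSE]),
         labels = labels, probabilities = probs, coefficients = coefs)
  })
}
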