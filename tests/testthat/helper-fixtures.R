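# Shared fixtures and independent oracles, built in code at test time.

# Brute-force least-squares sinusoid-fit periodogram: for each frequency,
# regress the mean-centered values on cos/sin and convert the residual
# sum-of-squares reduction to the normalized power.  Independent of the
# package's tau-form implementation.
brute_force_lsp <- function(t_h, y, frequencies) {
  yc <- y - mean(y)
  s2 <- stats::var(y)
  tss <- sum(yc^2)
  vapply(frequencies, function(f) {
    X <- cbind(cos(2 * pi * f * t_h), sin(2 * pi * f * t_h))
    rss <- sum(stats::lm.fit(X, yc)$residuals^2)
    (tss - rss) / (2 * s2)
  }, numeric(1))
}

# A 25-day analysis window holding a sinusoid of period `period_hours`
# (amplitude `amp`) plus N(0, sd) noise at a regular cadence.
tone_window <- function(period_hours = 24, amp = 1, sd = 0,
                        cadence_minutes = 30, days = 25,
                        phase = 0, state = "active",
                        bear_id = "bear01", variable = "tb",
                        start = as.Date("2014-06-01")) {
  t0 <- as.POSIXct(paste(start, "00:00:00"), tz = br_timezone())
  ts <- seq(t0, t0 + days * 86400 - cadence_minutes * 60,
            by = cadence_minutes * 60)
  hours <- as.numeric(ts - t0, units = "hours")
  vals <- 37 + amp * cos(2 * pi * hours / period_hours + phase) +
    stats::rnorm(length(ts), 0, sd)
  analysis_window(bear_id, variable, state,
                  start = t0, end = t0 + days * 86400,
                  season = as.integer(format(start, "%Y")),
                  timestamps = ts, values = vals)
}

# Regular daily-mean table over consecutive dates.
daily_table <- function(start, means) {
  data.frame(date = seq(as.Date(start), by = "day",
                        length.out = length(means)),
             mean = means, n = 48L)
}

# Regular hourly Tb series spanning `days` days from `start`.
regular_tb_series <- function(start, days, value = 37,
                              cadence_minutes = 60, bear_id = "bear01") {
  t0 <- as.POSIXct(paste(as.Date(start), "00:00:00"), tz = br_timezone())
  ts <- seq(t0, t0 + days * 86400 - cadence_minutes * 60,
            by = cadence_minutes * 60)
  biologging_series(bear_id, "tb", ts, rep_len(value, length(ts)))
}

# A linear-effect multinomial cohort with a strong day-length slope
# (three classes, diel reference), used for recovery experiments.
recovery_cohort <- function(n = 2000, seed = 1) {
  coefs <- matrix(c(-14, 1.2, 6, -0.5), 2, 2,
                  dimnames = list(c("(Intercept)", "day_length"),
                                  c("ultradian", "infradian")))
  sim <- simulate_rhythm_cohort(
    n, coefs, list(day_length = function(m) stats::runif(m, 6, 19)),
    seed = seed)
  list(data = cbind(sim$covariates, class = sim$labels), sim = sim,
       coefs = coefs)
}
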