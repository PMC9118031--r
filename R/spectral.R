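# Lomb-Scargle periodogram estimation for unevenly sampled windows,
# analytic false-alarm probability, and rhythm classification.

RHYTHM_BAND_EDGES <- c(2, 18, 36, 168)   # hours

#' Build a period grid for periodogram evaluation
#'
#' Frequencies are evenly spaced with step `1 / (oversampling *
#' window_length)` and truncated to the searched band (default 2-168 h,
#' spanning the ultradian, diel and infradian bands).  The peak
#' multiplicity `M` driving the false-alarm probability of the highest
#' peak is the number of frequencies searched; neighbouring oversampled
#' frequencies are correlated, making the independent-frequency bound
#' slightly conservative.
#'
#' @param window_length_hours Window duration in hours (> `max_period`;
#'   shorter windows shrink `max_period` to `window_length_hours /
#'   shrink_divisor` with a warning).
#' @param min_period,max_period Period band bounds in hours.
#' @param oversampling Frequency oversampling factor (>= 1), default 4.
#' @param shrink_divisor Divisor applied to the window length when the
#'   window is shorter than `max_period`.
#'
#' @return An object of class `period_grid`: `period_hours` (descending),
#'   `frequency` (cycles/hour, ascending), `M`, `oversampling`.
#' @export
build_period_grid <- function(window_length_hours,
                              min_period = RHYTHM_BAND_EDGES[1],
                              max_period = RHYTHM_BAND_EDGES[4],
                              oversampling = 4,
                              shrink_divisor = 1) {
  if (oversampling < 1) stop_br("oversampling must be >= 1")
  if (min_period <= 0 || max_period <= min_period) {
    stop_br("need 0 < min_period < max_period")
  }
  if (window_length_hours <= max_period) {
    max_period <- window_length_hours / shrink_divisor
    warn_br("window shorter than max_period; shrinking max_period to ",
            signif(max_period, 4), " h")
    if (max_period <= min_period) stop_br("window too short for period band")
  }
  df <- 1 / (oversampling * window_length_hours)
  # extend to the first grid point at or beyond 1/min_period so the grid
  # endpoints bracket the full band
  nf <- ceiling((1 / min_period - 1 / max_period) / df - 1e-9)
  freq <- 1 / max_period + (0:nf) * df
  # peak multiplicity = the number of frequencies actually searched; with
  # oversampling these are correlated, so the independent-frequency bound
  # is slightly conservative (empirically near-nominal at alpha = 0.01)
  M <- length(freq)
  structure(list(period_hours = 1 / freq, frequency = freq,
                 M = M, oversampling = oversampling,
                 window_length_hours = window_length_hours),
            class = "period_grid")
}

#' Classical normalized Lomb-Scargle periodogram
#'
#' Computes the Lomb-Scargle power at each grid frequency for an unevenly
#' sampled series: values are mean-centered, the per-frequency phase
#' offset tau is chosen so the sine and cosine terms decouple, and the
#' power is normalized by twice the sample variance.  The power at a
#' frequency equals the reduction in residual sum of squares from fitting
#' a sinusoid at that frequency by least squares, scaled by `2 * var(y)`;
#' for pure Gaussian noise each power is approximately Exponential(1).
#'
#' @param timestamps POSIXct instants or numeric hours; uneven spacing is
#'   handled natively (no resampling).
#' @param values Numeric measurements (must be non-constant; >= 8 samples).
#' @param grid A [build_period_grid()] object, or `NULL` to build one from
#'   the observed span.
#' @param oversampling Used only when `grid` is `NULL`.
#'
#' @return An object of class `periodogram`: the grid fields plus `power`
#'   and `n_samples`.
#' @export
lomb_scargle_power <- function(timestamps, values, grid = NULL,
                               oversampling = 4) {
  t_h <- if (inherits(timestamps, "POSIXct")) {
    as.numeric(timestamps) / 3600
  } else {
    as.numeric(timestamps)
  }
  y <- as.numeric(values)
  n <- length(y)
  if (n < 8) stop_br("need at least 8 samples")
  if (length(t_h) != n) stop_br("timestamps and values lengths differ")
  s2 <- stats::var(y)
  if (s2 == 0) stop_br("zero variance: constant series has no rhythm")
  if (is.null(grid)) {
    grid <- build_period_grid(diff(range(t_h)), oversampling = oversampling)
  }
  t_h <- t_h - mean(t_h)         # numerical conditioning; power is invariant
  y <- y - mean(y)
  omega <- 2 * pi * grid$frequency
  nf <- length(omega)
  power <- numeric(nf)
  # chunk over frequencies to bound the trig matrices at ~n x 256
  chunk <- max(1L, min(nf, as.integer(ceiling(2e6 / n))))
  for (i0 in seq(1L, nf, by = chunk)) {
    idx <- i0:min(i0 + chunk - 1L, nf)
    arg <- outer(t_h, omega[idx])
    C <- cos(arg); S <- sin(arg)
    CC <- colSums(C * C)
    SS <- n - CC
    CS <- colSums(C * S)
    YC <- as.numeric(crossprod(C, y))
    YS <- as.numeric(crossprod(S, y))
    wt <- 0.5 * atan2(2 * CS, CC - SS)       # omega * tau
    ct <- cos(wt); st <- sin(wt)
    num_c <- (YC * ct + YS * st)^2
    den_c <- CC * ct^2 + 2 * CS * ct * st + SS * st^2
    num_s <- (YS * ct - YC * st)^2
    den_s <- SS * ct^2 - 2 * CS * ct * st + CC * st^2
    power[idx] <- (num_c / den_c + num_s / den_s) / (2 * s2)
  }
  structure(list(period_hours = grid$period_hours,
                 frequency = grid$frequency,
                 power = pmax(power, 0),
                 n_samples = n, M = grid$M,
                 oversampling = grid$oversampling),
            class = "periodogram")
}

#' False-alarm probability of the highest periodogram peak
#'
#' Independent-frequency approximation: with `M` effectively independent
#' frequencies and Exponential(1) powers under the white-noise null, the
#' probability that the maximum power exceeds `z` is
#' `1 - (1 - exp(-z))^M`.
#'
#' @param z Observed peak power (>= 0).
#' @param M Effective number of independent frequencies (>= 1).
#'
#' @return The false-alarm probability in \[0, 1\].
#' @export
false_alarm_probability <- function(z, M) {
  if (any(z < 0)) stop_br("peak power must be non-negative")
  if (any(M < 1)) stop_br("M must be >= 1")
  -expm1(M * log1p(-exp(-z)))
}

#' Rhythm band of a peak period
#'
#' Classifies a (significant) peak period into the ultradian (2-18 h),
#' diel (18-36 h) or infradian (36-168 h) band.  Boundaries are half-open
#' upward: exactly 18 h is diel and exactly 36 h is infradian.
#'
#' @param period_hours Peak period(s) in hours.
#' @param edges Band edges in hours, default `c(2, 18, 36, 168)`.
#'
#' @return Character vector of band labels.
#' @export
rhythm_band <- function(period_hours, edges = RHYTHM_BAND_EDGES) {
  ifelse(period_hours < edges[2], "ultradian",
         ifelse(period_hours < edges[3], "diel", "infradian"))
}

#' Classify the rhythm of one analysis window
#'
#' Computes the Lomb-Scargle periodogram over the 2-168 h band, selects
#' the highest peak, tests it against the white-noise null, and classifies
#' the window as ultradian (2-18 h), diel (18-36 h), infradian
#' (36-168 h) or, when the peak is not significant at level `alpha`,
#' arrhythmic (the peak period is still reported).  Band boundaries are
#' half-open upward: a peak at exactly 18 h is diel.
#'
#' @param window An [analysis_window()] (or any list with `timestamps`,
#'   `values` and identification fields).
#' @param alpha Significance level for the peak (default 0.01).
#' @param oversampling Frequency oversampling factor (default 4).
#' @param band_edges Period band edges in hours (ultradian / diel /
#'   infradian), default `c(2, 18, 36, 168)`.
#'
#' @return An object of class `rhythm_call`: window identification plus
#'   `class`, `peak_period_hours`, `peak_power`, `p_value`.
#' @export
classify_window <- function(window, alpha = 0.01, oversampling = 4,
                            band_edges = RHYTHM_BAND_EDGES) {
  if (length(window$values) < 8) stop_br("window has fewer than 8 samples")
  grid <- build_period_grid(
    window_length_hours = as.numeric(window$end - window$start,
                                     units = "hours"),
    min_period = band_edges[1], max_period = band_edges[4],
    oversampling = oversampling)
  pg <- lomb_scargle_power(window$timestamps, window$values, grid)
  peak <- which.max(pg$power)
  z <- pg$power[peak]
  p <- false_alarm_probability(z, pg$M)
  cls <- if (p > alpha) "arrhythmic" else
    rhythm_band(pg$period_hours[peak], band_edges)
  structure(list(
    window_id = window$window_id, bear_id = window$bear_id,
    variable = window$variable, state = window$state,
    season = window$season,
    class = cls, peak_period_hours = pg$period_hours[peak],
    peak_power = z, p_value = p),
    class = "rhythm_call")
}

#' Tabulate rhythm calls
#'
#' @param calls List of [classify_window()] results.
#' @return Data frame with one row per call.
#' @export
calls_table <- function(calls) {
  do.call(rbind, lapply(calls, function(x) data.frame(
    window_id = x$window_id %||% NA_character_,
    bear_id = x$bear_id %||% NA_character_,
    variable = x$variable %||% NA_character_,
    state = x$state %||% NA_character_,
    season = x$season %||% NA_integer_,
    class = x$class, peak_period_hours = x$peak_period_hours,
    peak_power = x$peak_power, p_value = x$p_value,
    stringsAsFactors = FALSE)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
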