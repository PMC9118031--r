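# Double-plot raster matrices (actogram/thermogram/HR raster), solar
# overlays and period summary tables.

#' Double-plot raster matrix of a biologging series
#'
#' Bins the series by local time of day into a day-by-day raster where
#' each row shows day x on the left and day x+1 on the right (the classic
#' chronobiology double plot, which makes phase drift visible).  Empty
#' bins are missing, not zero.
#'
#' @param series A [biologging_series()].
#' @param bin_minutes Bin width in minutes (must divide 1440), default 30.
#'
#' @return An object of class `double_plot_matrix`: `matrix` (rows =
#'   days, columns = 2 x bins per day), `dates` (row dates) and
#'   `bin_minutes`.  The right half of row d equals the left half of row
#'   d+1 wherever both exist.
#' @export
double_plot_matrix <- function(series, bin_minutes = 30) {
  if (1440 %% bin_minutes != 0) stop_br("bin_minutes must divide 1440")
  nb <- 1440 %/% bin_minutes
  date <- br_date(series$timestamp)
  dates <- seq(min(date), max(date), by = "day")
  mins <- as.numeric(series$timestamp - br_midnight(date), units = "mins")
  bin <- pmin(floor(mins / bin_minutes) + 1, nb)
  day_idx <- match(date, dates)
  single <- matrix(NA_real_, length(dates), nb)
  agg <- tapply(series$value, list(day_idx, bin), mean)
  ri <- as.integer(rownames(agg))
  ci <- as.integer(colnames(agg))
  single[ri, ci] <- agg
  right <- rbind(single[-1, , drop = FALSE],
                 matrix(NA_real_, 1, nb))
  out <- cbind(single, right)
  colnames(out) <- c(sprintf("d0_b%03d", seq_len(nb)),
                     sprintf("d1_b%03d", seq_len(nb)))
  structure(list(matrix = out, dates = dates, bin_minutes = bin_minutes,
                 variable = series$variable[1], bear_id = series$bear_id[1]),
            class = "double_plot_matrix")
}

#' Sunrise and sunset instants
#'
#' Standard solar-geometry sunrise/sunset (sun centre 0.8333 degrees
#' below the horizon), using the same solar declination model as
#' [day_length()], an equation-of-time correction, and the package civil
#' time (UTC+1).  Polar dates without a sunrise/sunset return `NA`.
#'
#' @param latitude,longitude Coordinates in degrees.
#' @param date Date (scalar).
#' @param tz_offset_hours Civil-time offset from UTC (default 1).
#'
#' @return Named POSIXct vector `c(sunrise, sunset)`, with
#'   `sunset - sunrise` equal to [day_length()] for the same inputs.
#' @export
sunrise_sunset <- function(latitude, longitude, date, tz_offset_hours = 1) {
  doy <- as.integer(format(as.Date(date), "%j"))
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))
  p <- 0.8333
  lat <- latitude * pi / 180
  x <- (sin(p * pi / 180) + sin(lat) * sin(phi)) / (cos(lat) * cos(phi))
  if (x < -1 || x > 1) {
    return(stats::setNames(as.POSIXct(c(NA, NA), tz = BR_TZ),
                           c("sunrise", "sunset")))
  }
  half_day <- 12 - (12 / pi) * acos(x)      # hours from solar noon
  # equation of time (Spencer 1971), in hours
  g <- 2 * pi * (doy - 1) / 365
  eot <- (0.000075 + 0.001868 * cos(g) - 0.032077 * sin(g) -
            0.014615 * cos(2 * g) - 0.04089 * sin(2 * g)) * (24 / (2 * pi))
  solar_noon <- 12 - longitude / 15 - eot + tz_offset_hours
  midnight <- br_midnight(as.Date(date))
  stats::setNames(
    midnight + 3600 * c(solar_noon - half_day, solar_noon + half_day),
    c("sunrise", "sunset"))
}

#' Period summary table by state and rhythm class
#'
#' Aggregates rhythm calls into mean/min/max peak period lengths per
#' seasonal state and rhythm class, with the number of windows and of
#' distinct individuals.  Arrhythmic rows summarize the (non-significant)
#' highest peak and are flagged with `nonsignificant_peak = TRUE`.
#'
#' @param calls Data frame of rhythm calls ([calls_table()]), including
#'   `state`, `class`, `peak_period_hours`, `bear_id`.
#'
#' @return Data frame with columns `state`, `class`, `mean_period_hours`,
#'   `min_period_hours`, `max_period_hours`, `n`, `n_individuals`,
#'   `nonsignificant_peak`.
#' @export
period_summary <- function(calls) {
  if (nrow(calls) == 0) {
    return(data.frame(state = character(), class = character(),
                      mean_period_hours = numeric(),
                      min_period_hours = numeric(),
                      max_period_hours = numeric(),
                      n = integer(), n_individuals = integer(),
                      nonsignificant_peak = logical()))
  }
  key <- interaction(calls$state, calls$class, drop = TRUE, sep = "\r")
  rows <- lapply(levels(key), function(k) {
    sel <- calls[key == k, , drop = FALSE]
    parts <- strsplit(k, "\r", fixed = TRUE)[[1]]
    data.frame(
      state = parts[1], class = parts[2],
      mean_period_hours = mean(sel$peak_period_hours),
      min_period_hours = min(sel$peak_period_hours),
      max_period_hours = max(sel$peak_period_hours),
      n = nrow(sel),
      n_individuals = length(unique(sel$bear_id)),
      nonsignificant_peak = parts[2] == "arrhythmic",
      stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$state, out$class), , drop = FALSE]
}

#' @export
plot.double_plot_matrix <- function(x, ...) {
  m <- x$matrix
  graphics::image(t(m[rev(seq_len(nrow(m))), , drop = FALSE]),
                  col = grDevices::grey.colors(64, start = 1, end = 0),
                  axes = FALSE,
                  main = sprintf("%s double plot: %s", x$variable,
                                 x$bear_id), ...)
  invisible(x)
}
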