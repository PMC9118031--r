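# Per-window environmental and intrinsic predictors: photoperiod,
# inverse-distance-weighted weather interpolation, covariate assembly.

#' Day length (photoperiod) at a latitude and date
#'
#' Daylight hours from solar declination using the standard day-length
#' model of Forsythe et al. (1995), with the conventional sunrise/sunset
#' definition (sun centre 0.8333 degrees below the horizon, accounting for
#' refraction and the solar disc).  At polar latitudes the formula
#' saturates and is clamped to 0 or 24 h with a warning.
#'
#' @param latitude_deg Latitude in degrees (positive north).
#' @param date Date (or vector of dates).
#'
#' @return Day length in hours, in (0, 24) away from polar saturation.
#' @export
day_length <- function(latitude_deg, date) {
  doy <- as.integer(format(as.Date(date), "%j"))
  # revolution angle and solar declination (Forsythe et al. 1995)
  theta <- 0.2163108 + 2 * atan(0.9671396 * tan(0.00860 * (doy - 186)))
  phi <- asin(0.39795 * cos(theta))
  p <- 0.8333   # degrees below horizon defining sunrise/sunset
  lat <- latitude_deg * pi / 180
  x <- (sin(p * pi / 180) + sin(lat) * sin(phi)) / (cos(lat) * cos(phi))
  if (any(x < -1 | x > 1)) {
    warn_br("polar day/night: day length clamped to 0 or 24 h")
    x <- pmin(pmax(x, -1), 1)
  }
  24 - (24 / pi) * acos(x)
}

#' Direction of day length over a window
#'
#' Sign of the change in day length between the window's first and last
#' day; exact ties are classified as increasing.
#'
#' @param window An [analysis_window()], or a length-2 date vector.
#' @param latitude_deg Latitude in degrees.
#'
#' @return `"increasing"` or `"decreasing"`.
#' @export
day_length_direction <- function(window, latitude_deg) {
  dates <- if (inherits(window, "analysis_window")) {
    c(br_date(window$start), br_date(window$end - 1))
  } else {
    as.Date(window)
  }
  delta <- day_length(latitude_deg, dates[2]) -
    day_length(latitude_deg, dates[1])
  if (delta >= 0) "increasing" else "decreasing"
}

#' Inverse-distance-weighted interpolation from weather stations
#'
#' Interpolates daily station values to a target point using the `k`
#' nearest stations (great-circle distance), with weights proportional to
#' distance to the power `-power`, normalized to sum to one.  A target
#' within 1 m of a station returns that station's values exactly.
#'
#' @param stations Station table as from [simulate_weather()] (columns
#'   `station_id`, `lat`, `lon`, `date`, and value columns).
#' @param target_lat,target_lon Target coordinates (degrees).
#' @param date The date to interpolate.
#' @param k Number of nearest stations (default 3).
#' @param power Inverse-distance exponent (default 2).
#' @param value_cols Which columns to interpolate.
#'
#' @return A named numeric vector of interpolated values (`NA` if no
#'   station reports on `date`).
#' @export
idw_interpolate <- function(stations, target_lat, target_lon, date,
                            k = 3, power = 2,
                            value_cols = c("ta_min", "ta_mean", "ta_max",
                                           "snow_depth")) {
  day <- stations[stations$date == as.Date(date), , drop = FALSE]
  empty <- stats::setNames(rep(NA_real_, length(value_cols)), value_cols)
  if (nrow(day) == 0) return(empty)
  d <- geosphere::distHaversine(
    cbind(day$lon, day$lat), c(target_lon, target_lat))
  if (any(d < 1)) {   # exact hit: return the coincident station's values
    hit <- which.min(d)
    return(stats::setNames(as.numeric(day[hit, value_cols]), value_cols))
  }
  if (nrow(day) < k) {
    warn_br("only ", nrow(day), " station(s) report on ", format(date),
            "; using all available")
    k <- nrow(day)
  }
  nearest <- order(d)[seq_len(k)]
  w <- d[nearest]^(-power)
  w <- w / sum(w)
  vals <- vapply(value_cols,
                 function(col) sum(w * day[[col]][nearest]), numeric(1))
  stats::setNames(vals, value_cols)
}

#' Assemble the covariate record for one analysis window
#'
#' Averages environmental conditions (ambient temperature, snow depth, day
#' length) over the window's days, interpolating weather to the bear's
#' position -- the summer range position for active and transition
#' windows, the den location during hibernation (switching coordinates on
#' a recorded den-change date) -- and attaches the bear's intrinsic
#' predictors.  Missing metadata fields are emitted as `NA`; downstream
#' models drop incomplete rows.
#'
#' @param window An [analysis_window()].
#' @param weather Station table (see [idw_interpolate()]).
#' @param den_records Data frame of dens: `bear_id`, `from_date`, `lat`,
#'   `lon`, `den_type`, `open_area`.  Multiple rows per bear encode den
#'   changes, switching on `from_date`.
#' @param metadata Data frame of bears: `bear_id`, `lat`, `lon` (range
#'   position), `sex`, `age_class`, `status`, `body_mass`.
#' @param k,power IDW parameters.
#'
#' @return A one-row data frame: `window_id`, `ta_mean`, `snow_depth`,
#'   `day_length`, `day_length_direction`, `den_type`, `open_area`,
#'   `body_mass`, `sex`, `age_class`, `status`.
#' @export
window_covariates <- function(window, weather, den_records, metadata,
                              k = 3, power = 2) {
  meta <- metadata[metadata$bear_id == window$bear_id, , drop = FALSE]
  if (nrow(meta) == 0) meta <- data.frame(bear_id = window$bear_id)
  pick <- function(df, col) {
    if (col %in% names(df) && nrow(df) > 0) df[[col]][1] else NA
  }
  dates <- seq(br_date(window$start), br_date(window$end - 1), by = "day")
  dens <- den_records[den_records$bear_id == window$bear_id, , drop = FALSE]
  dens <- dens[order(as.Date(dens$from_date)), , drop = FALSE]
  den_for <- function(d) {
    if (nrow(dens) == 0) return(NULL)
    active <- which(as.Date(dens$from_date) <= d)
    if (length(active) == 0) dens[1, ] else dens[max(active), ]
  }
  loc_for <- function(d) {
    if (window$state == "hibernation") {
      den <- den_for(d)
      if (!is.null(den)) return(c(den$lat, den$lon))
    }
    c(pick(meta, "lat"), pick(meta, "lon"))
  }
  wx <- t(vapply(as.list(dates), function(d) {
    loc <- loc_for(d)
    if (anyNA(loc)) return(c(ta_mean = NA_real_, snow_depth = NA_real_,
                             lat = NA_real_))
    v <- idw_interpolate(weather, loc[1], loc[2], d, k = k, power = power)
    c(ta_mean = v[["ta_mean"]], snow_depth = v[["snow_depth"]],
      lat = loc[1])
  }, numeric(3)))
  lat0 <- if (all(is.na(wx[, "lat"]))) pick(meta, "lat") else
    mean(wx[, "lat"], na.rm = TRUE)
  dl <- if (is.na(lat0)) NA_real_ else mean(day_length(lat0, dates))
  dl_dir <- if (is.na(lat0)) NA_character_ else
    day_length_direction(window, lat0)
  den_now <- den_for(br_date(window$start))
  data.frame(
    window_id = window$window_id,
    ta_mean = mean(wx[, "ta_mean"]),
    snow_depth = mean(wx[, "snow_depth"]),
    day_length = dl,
    day_length_direction = dl_dir,
    den_type = if (is.null(den_now)) NA_character_ else
      pick(den_now, "den_type"),
    open_area = if (is.null(den_now)) NA_real_ else
      as.numeric(pick(den_now, "open_area")),
    body_mass = as.numeric(pick(meta, "body_mass")),
    sex = pick(meta, "sex"),
    age_class = pick(meta, "age_class"),
    status = pick(meta, "status"),
    stringsAsFactors = FALSE)
}
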