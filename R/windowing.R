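# Exclusion filters and tiling of seasonal states into 15-25 day
# analysis windows.

WINDOW_MIN_DAYS <- 15
WINDOW_MAX_DAYS <- 25
MAX_GAP_DAYS <- 2

#' Apply data-quality exclusions to a biologging series
#'
#' Removes unrealistic body temperatures (Tb strictly below 30 degC; a
#' value of exactly 30.0 is kept), all samples in the two weeks following a
#' capture, and the three days following a known disturbance.
#'
#' @param series A [biologging_series()].
#' @param capture_dates,disturbance_dates Date vectors of events.
#' @param tb_floor Lower plausibility bound for Tb (degC), default 30.
#'
#' @return A list with `series` (the filtered series) and `log` (a data
#'   frame of per-rule removal counts).
#' @export
apply_exclusions <- function(series, capture_dates = NULL,
                             disturbance_dates = NULL, tb_floor = 30) {
  keep <- rep(TRUE, nrow(series))
  date <- br_date(series$timestamp)
  n_tb <- 0L
  if (series$variable[1] == "tb") {
    bad <- series$value < tb_floor
    n_tb <- sum(bad)
    keep <- keep & !bad
  }
  in_event <- function(dates, days) {
    hit <- rep(FALSE, length(date))
    for (d in as.list(as.Date(dates))) {
      hit <- hit | (date >= d & date < d + days)
    }
    hit
  }
  cap_hit <- if (length(capture_dates)) in_event(capture_dates, 14) else FALSE
  n_cap <- sum(keep & cap_hit)
  keep <- keep & !cap_hit
  dis_hit <- if (length(disturbance_dates)) {
    in_event(disturbance_dates, 3)
  } else FALSE
  n_dis <- sum(keep & dis_hit)
  keep <- keep & !dis_hit
  out <- series[keep, , drop = FALSE]
  class(out) <- class(series)
  list(
    series = out,
    log = data.frame(
      rule = c("tb_below_floor", "post_capture_14d", "post_disturbance_3d"),
      removed = c(n_tb, n_cap, n_dis))
  )
}

# Largest sampling gap (days) inside [start, end), counting the margins
# from the window edges to the first/last sample.
max_gap_days <- function(times, start, end) {
  if (length(times) == 0) return(as.numeric(end - start, units = "days"))
  bounds <- c(as.numeric(start), as.numeric(times), as.numeric(end))
  max(diff(bounds)) / 86400
}

#' Tile seasonal states into analysis windows
#'
#' Within each state interval, lays consecutive 25-day windows starting at
#' the state's start; a terminal remainder is kept only if it spans at
#' least 15 days.  Any window containing a sampling gap longer than 2 days
#' (including a gap at its start or end) is discarded and logged, as are
#' states shorter than 15 days.
#'
#' Each window carries a season identifier used as a grouping factor
#' downstream: the calendar year of the window start for active windows,
#' and the year of den entry for hibernation and transition windows.
#'
#' @param state_map A [seasonal_state_map()].
#' @param series The filtered [biologging_series()] for one variable
#'   present in the map.
#' @param min_days,max_days Window duration bounds (days), defaults 15/25.
#' @param max_gap Maximum tolerated sampling gap (days), default 2.
#'
#' @return A list with `windows` (a list of `analysis_window` objects) and
#'   `log` (data frame of dropped windows/states and reasons).
#' @export
tile_windows <- function(state_map, series,
                         min_days = WINDOW_MIN_DAYS,
                         max_days = WINDOW_MAX_DAYS,
                         max_gap = MAX_GAP_DAYS) {
  variable <- series$variable[1]
  intervals <- state_map$intervals[[variable]]
  if (is.null(intervals)) stop_br("state map has no intervals for ", variable)
  entry_year <- if (!is.na(state_map$den_entry)) {
    as.integer(format(state_map$den_entry, "%Y"))
  } else NA_integer_
  windows <- list()
  log <- list()
  note <- function(...) {
    log[[length(log) + 1]] <<- data.frame(..., stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(intervals))) {
    state <- intervals$state[i]
    s0 <- br_midnight(intervals$start[i])
    s1 <- br_midnight(intervals$end[i] + 1)
    len_days <- as.numeric(s1 - s0, units = "days")
    if (len_days < min_days) {
      note(state = state, start = format(intervals$start[i]),
           reason = "state_shorter_than_min")
      next
    }
    n_full <- floor(len_days / max_days)
    starts <- s0 + (seq_len(n_full) - 1) * max_days * 86400
    ends <- starts + max_days * 86400
    rem <- len_days - n_full * max_days
    if (rem >= min_days) {
      starts <- c(starts, s0 + n_full * max_days * 86400)
      ends <- c(ends, s1)
    } else if (rem > 0) {
      note(state = state,
           start = format(br_date(s0 + n_full * max_days * 86400)),
           reason = "remainder_shorter_than_min")
    }
    for (w in seq_along(starts)) {
      sel <- series$timestamp >= starts[w] & series$timestamp < ends[w]
      times <- series$timestamp[sel]
      if (max_gap_days(times, starts[w], ends[w]) > max_gap) {
        note(state = state, start = format(br_date(starts[w])),
             reason = "gap_over_limit")
        next
      }
      dur <- as.numeric(ends[w] - starts[w], units = "days")
      season <- if (state == "active" || is.na(entry_year)) {
        as.integer(format(br_date(starts[w]), "%Y"))
      } else {
        entry_year
      }
      windows[[length(windows) + 1]] <- analysis_window(
        bear_id = state_map$bear_id, variable = variable, state = state,
        start = starts[w], end = ends[w], season = season,
        timestamps = times, values = series$value[sel])
    }
  }
  list(windows = windows,
       log = if (length(log)) do.call(rbind, log) else
         data.frame(state = character(), start = character(),
                    reason = character()))
}

#' Construct an analysis window
#'
#' A 15-25 day slice of one series in one seasonal state, carrying its
#' samples and a season grouping identifier.
#'
#' @param bear_id,variable,state Identifiers.
#' @param start,end Window bounds (instants; `end` exclusive).
#' @param season Season grouping identifier (integer year).
#' @param timestamps,values The contained samples.
#'
#' @return An object of class `analysis_window`.
#' @export
analysis_window <- function(bear_id, variable, state, start, end, season,
                            timestamps, values) {
  start <- as_br_time(start); end <- as_br_time(end)
  dur <- as.numeric(end - start, units = "days")
  if (dur < WINDOW_MIN_DAYS - 1e-9 || dur > WINDOW_MAX_DAYS + 1e-9) {
    stop_br("window duration must lie in [15, 25] days")
  }
  structure(list(
    window_id = sprintf("%s_%s_%s_%s", bear_id, variable, state,
                        format(br_date(start))),
    bear_id = bear_id, variable = variable, state = state,
    start = start, end = end, duration_days = dur, season = season,
    timestamps = as_br_time(timestamps), values = as.numeric(values)),
    class = "analysis_window")
}

#' Summarise a list of analysis windows as a data frame
#'
#' @param windows List of [analysis_window()] objects.
#' @return Data frame with one row per window.
#' @export
windows_table <- function(windows) {
  do.call(rbind, lapply(windows, function(w) data.frame(
    window_id = w$window_id, bear_id = w$bear_id, variable = w$variable,
    state = w$state, start = format(w$start), end = format(w$end),
    duration_days = w$duration_days, season = w$season,
    n_samples = length(w$timestamps), stringsAsFactors = FALSE)))
}
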