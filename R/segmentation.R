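# Seasonal-state segmentation: den entry/exit detection from daily mean
# body temperature, and per-variable state interval assignment.

DEN_ENTRY_TB <- 36.4   # degC, daily mean at or below for 7 consecutive days
DEN_EXIT_TB <- 36.7    # degC, daily mean at or above for 7 consecutive days
THRESHOLD_RUN_DAYS <- 7L

#' Construct a biologging series
#'
#' A biologging series is one variable's irregular time series for one bear:
#' body temperature (`tb`, degC), heart rate (`hr`, beats/min) or activity
#' (`activity`, integer counts 0-510).  Timestamps must be strictly
#' increasing; gaps are absent rows, never stored missing values.
#'
#' @param bear_id Bear identifier.
#' @param variable One of `"tb"`, `"hr"`, `"activity"`.
#' @param timestamps POSIXct (or coercible) instants, strictly increasing.
#' @param values Numeric measurements; activity must lie in \[0, 510\].
#'
#' @return A data frame with columns `bear_id`, `variable`, `timestamp`,
#'   `value`, of class `biologging_series`.
#' @export
biologging_series <- function(bear_id, variable, timestamps, values) {
  variable <- match.arg(variable, c("tb", "hr", "activity"))
  ts <- as_br_time(timestamps)
  values <- as.numeric(values)
  if (length(ts) != length(values)) {
    stop_br("timestamps and values must have equal length")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    stop_br("values must be finite; gaps are absent rows, not NA")
  }
  if (length(ts) > 1 && any(diff(as.numeric(ts)) <= 0)) {
    stop_br("timestamps must be strictly increasing")
  }
  if (variable == "activity" && any(values < 0 | values > 510)) {
    stop_br("activity values must lie in [0, 510]")
  }
  structure(
    data.frame(bear_id = bear_id, variable = variable,
               timestamp = ts, value = values, stringsAsFactors = FALSE),
    class = c("biologging_series", "data.frame"))
}

#' Default per-variable transition offsets
#'
#' Whole-day offsets delimiting the transition states around den entry and
#' den exit for each variable: body temperature starts to decrease 13 days
#' before den entry and continues for 30 more days, activity starts 25 days
#' before entry and continues 9 more days, heart rate starts 24 days before
#' entry; before den exit, Tb, HR and activity start to increase 33, 63 and
#' 10 days ahead respectively.  Post-entry HR and all post-exit offsets are
#' package defaults (configurable), not published values.
#'
#' @return A named list (`tb`, `hr`, `activity`) of lists with elements
#'   `pre_entry`, `post_entry`, `pre_exit`, `post_exit` (days, >= 0).
#' @export
default_transition_offsets <- function() {
  list(
    tb = list(pre_entry = 13, post_entry = 30, pre_exit = 33, post_exit = 0),
    hr = list(pre_entry = 24, post_entry = 30, pre_exit = 63, post_exit = 0),
    activity = list(pre_entry = 25, post_entry = 9, pre_exit = 10,
                    post_exit = 0)
  )
}

#' Daily means of a biologging series
#'
#' @param series A [biologging_series()].
#'
#' @return A data frame with one row per calendar date having at least one
#'   sample: columns `date`, `mean`, `n`.
#' @export
daily_means <- function(series) {
  if (nrow(series) == 0) stop_br("empty series")
  date <- br_date(series$timestamp)
  agg <- tapply(series$value, date, mean)
  n <- tapply(series$value, date, length)
  out <- data.frame(date = as.Date(names(agg)),
                    mean = as.numeric(agg), n = as.integer(n))
  rownames(out) <- NULL
  out[order(out$date), , drop = FALSE]
}

# First date d in [window[1], window[2]] such that d..d+(run-1) are all
# present in the daily table and satisfy `cond`.  A missing day breaks a
# run: the definition requires seven observed daily means.
first_threshold_run <- function(daily, window, cond, run = THRESHOLD_RUN_DAYS) {
  ok_dates <- daily$date[cond(daily$mean)]
  if (length(ok_dates) == 0) return(as.Date(NA))
  candidates <- sort(ok_dates[ok_dates >= window[1] & ok_dates <= window[2]])
  for (d in as.list(candidates)) {
    if (all(seq(d, d + run - 1, by = "day") %in% ok_dates)) return(d)
  }
  as.Date(NA)
}

#' Detect den entry from daily mean body temperature
#'
#' Den entry is the first day in autumn on which the daily mean Tb is at or
#' below 36.4 degC for seven consecutive observed days.  Days without
#' samples break a candidate run.
#'
#' @param daily_tb Daily-mean table from [daily_means()] of a Tb series.
#' @param search_window Length-2 date vector bounding the candidate first
#'   day (the run itself may extend past the window end).
#' @param threshold Threshold (degC), default 36.4.
#'
#' @return The entry date, or `NA` if no qualifying run exists.
#' @export
detect_den_entry <- function(daily_tb, search_window,
                             threshold = DEN_ENTRY_TB) {
  search_window <- as.Date(search_window)
  first_threshold_run(daily_tb, search_window,
                      function(m) m <= threshold)
}

#' Detect den exit from daily mean body temperature
#'
#' Den exit is the first day in spring on which the daily mean Tb is at or
#' above 36.7 degC for seven consecutive observed days.
#'
#' @inheritParams detect_den_entry
#' @param threshold Threshold (degC), default 36.7.
#'
#' @return The exit date, or `NA` if no qualifying run exists.
#' @export
detect_den_exit <- function(daily_tb, search_window,
                            threshold = DEN_EXIT_TB) {
  search_window <- as.Date(search_window)
  first_threshold_run(daily_tb, search_window,
                      function(m) m >= threshold)
}

#' Assign seasonal state intervals for one variable
#'
#' Builds the four seasonal states of a bear's year from the detected den
#' entry/exit dates and the variable's transition offsets:
#' `transition_entry` spans `entry - pre_entry` to `entry + post_entry`,
#' `transition_exit` spans `exit - pre_exit` to `exit + post_exit`,
#' `hibernation` lies between them and `active` covers the rest of the
#' span.  When entry or exit is absent the whole span is `active`.
#' Overlapping transitions (a very short hibernation) are truncated at
#' their midpoint and a warning is recorded.
#'
#' @param entry,exit Den entry and exit dates (`NA` allowed).
#' @param variable One of `"tb"`, `"hr"`, `"activity"` (selects offsets).
#' @param offsets Per-variable offsets, see [default_transition_offsets()].
#' @param span Length-2 date vector covering the series.
#'
#' @return A data frame of disjoint, ordered, span-covering intervals with
#'   columns `state`, `start`, `end` (inclusive dates), with a `warnings`
#'   attribute listing any truncation records.
#' @export
assign_states <- function(entry, exit, variable = "tb",
                          offsets = default_transition_offsets(),
                          span) {
  span <- as.Date(span)
  offs <- offsets[[variable]]
  warnings <- character()
  interval <- function(state, start, end) {
    data.frame(state = state, start = start, end = end,
               stringsAsFactors = FALSE)
  }
  if (is.na(entry) || is.na(exit)) {
    out <- interval("active", span[1], span[2])
    attr(out, "warnings") <- warnings
    return(out)
  }
  entry <- as.Date(entry); exit <- as.Date(exit)
  if (entry >= exit) stop_br("den entry must precede den exit")
  # zero offsets mean no transition state: hibernation starts at entry /
  # ends at exit and the year splits into {active, hibernation} only
  has_te <- offs$pre_entry + offs$post_entry > 0
  has_tx <- offs$pre_exit + offs$post_exit > 0
  te_start <- max(entry - offs$pre_entry, span[1])
  te_end <- if (has_te) entry + offs$post_entry else entry - 1
  tx_start <- if (has_tx) exit - offs$pre_exit else exit + 1
  tx_end <- min(exit + offs$post_exit, span[2])
  if (te_end >= tx_start) {
    mid <- as.Date(floor((as.numeric(te_end) + as.numeric(tx_start)) / 2),
                   origin = "1970-01-01")
    warnings <- c(warnings, sprintf(
      "transitions overlap for %s; truncated at midpoint %s",
      variable, format(mid)))
    te_end <- mid
    tx_start <- mid + 1
  }
  rows <- list()
  if (te_start > span[1]) {
    rows <- c(rows, list(interval("active", span[1], te_start - 1)))
  }
  rows <- c(rows, list(interval("transition_entry", te_start, te_end)))
  if (tx_start > te_end + 1) {
    rows <- c(rows, list(interval("hibernation", te_end + 1, tx_start - 1)))
  }
  rows <- c(rows, list(interval("transition_exit", tx_start, tx_end)))
  if (tx_end < span[2]) {
    rows <- c(rows, list(interval("active", tx_end + 1, span[2])))
  }
  out <- do.call(rbind, rows)
  out <- out[out$start <= out$end, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "warnings") <- warnings
  out
}

#' Build the seasonal state map for one bear
#'
#' Runs den entry/exit detection on the bear's Tb series and assigns
#' per-variable state intervals using each variable's transition offsets.
#'
#' @param tb_series Body-temperature [biologging_series()].
#' @param offsets Per-variable transition offsets.
#' @param entry_window,exit_window Search windows for den entry (autumn)
#'   and exit (spring); defaults are Aug 1 - Jan 31 and Feb 1 - Jul 31 of
#'   the observed span.
#' @param variables Variables to assign intervals for.
#'
#' @return A list of class `seasonal_state_map`: `bear_id`, `den_entry`,
#'   `den_exit`, and `intervals` (named list of per-variable interval data
#'   frames).
#' @export
seasonal_state_map <- function(tb_series,
                               offsets = default_transition_offsets(),
                               entry_window = NULL, exit_window = NULL,
                               variables = c("tb", "hr", "activity")) {
  daily <- daily_means(tb_series)
  span <- range(daily$date)
  yr <- as.integer(format(span[1], "%Y"))
  if (is.null(entry_window)) {
    entry_window <- c(as.Date(sprintf("%d-08-01", yr)),
                      as.Date(sprintf("%d-01-31", yr + 1)))
  }
  if (is.null(exit_window)) {
    exit_window <- c(as.Date(sprintf("%d-02-01", yr + 1)),
                     as.Date(sprintf("%d-07-31", yr + 1)))
  }
  entry <- detect_den_entry(daily, entry_window)
  exit <- detect_den_exit(daily, exit_window)
  if (!is.na(entry) && !is.na(exit) && entry >= exit) {
    warn_br("detected den exit precedes entry; treating year as active")
    entry <- exit <- as.Date(NA)
  }
  intervals <- lapply(variables, function(v)
    assign_states(entry, exit, v, offsets, span))
  names(intervals) <- variables
  structure(list(bear_id = tb_series$bear_id[1],
                 den_entry = entry, den_exit = exit,
                 intervals = intervals),
            class = "seasonal_state_map")
}
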