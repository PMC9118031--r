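# CSV formats, pipeline configuration and the end-to-end driver.

#' Pipeline configuration
#'
#' Collects every tunable constant of the analysis pipeline: segmentation
#' thresholds and transition offsets, window lengths and the gap limit,
#' periodogram significance level, band edges and oversampling, IDW
#' parameters, and the candidate model list.
#'
#' @param entry_threshold,exit_threshold Daily-mean Tb thresholds (degC)
#'   for den entry/exit (defaults 36.4 / 36.7; entry must be below exit).
#' @param offsets Per-variable transition offsets.
#' @param min_window_days,max_window_days Window length bounds (15 / 25).
#' @param max_gap_days Maximum within-window sampling gap (2).
#' @param alpha Periodogram significance level (0.01).
#' @param band_edges Period band edges in hours, ordered (2, 18, 36, 168).
#' @param oversampling Periodogram oversampling factor.
#' @param idw_k,idw_power IDW neighbour count and exponent.
#' @param candidate_set Candidate model set for the modelling stage:
#'   `"active"`, `"hibernation"`, or `"none"` to skip modelling.
#' @param seed Integer seed for any stochastic stage.
#'
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(entry_threshold = 36.4,
                            exit_threshold = 36.7,
                            offsets = default_transition_offsets(),
                            min_window_days = 15,
                            max_window_days = 25,
                            max_gap_days = 2,
                            alpha = 0.01,
                            band_edges = c(2, 18, 36, 168),
                            oversampling = 4,
                            idw_k = 3, idw_power = 2,
                            candidate_set = "none",
                            seed = 1L) {
  if (entry_threshold >= exit_threshold) {
    stop_br("entry threshold must be below exit threshold")
  }
  if (any(diff(band_edges) <= 0) || length(band_edges) != 4) {
    stop_br("band edges must be four increasing values")
  }
  if (min_window_days >= max_window_days) {
    stop_br("min_window_days must be below max_window_days")
  }
  structure(list(entry_threshold = entry_threshold,
                 exit_threshold = exit_threshold, offsets = offsets,
                 min_window_days = min_window_days,
                 max_window_days = max_window_days,
                 max_gap_days = max_gap_days, alpha = alpha,
                 band_edges = band_edges, oversampling = oversampling,
                 idw_k = idw_k, idw_power = idw_power,
                 candidate_set = candidate_set, seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read biologging series from CSV
#'
#' Expects columns `bear_id`, `timestamp` (ISO 8601), `variable` (`tb`,
#' `hr` or `activity`) and `value`.  Rows are validated (parseable
#' timestamps, activity within 0-510, no duplicate timestamps within a
#' series) and each bear/variable combination is returned as a sorted
#' [biologging_series()].
#'
#' @param path CSV file path.
#'
#' @return Named list of biologging series (`<bear>.<variable>`).
#' @export
read_series_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("bear_id", "timestamp", "variable", "value")
  if (!all(need %in% names(df))) {
    stop_br("series CSV must have columns ", paste(need, collapse = ", "))
  }
  ts <- parse_iso_times(df$timestamp)
  bad <- which(is.na(ts) | !is.finite(df$value))
  if (length(bad)) {
    stop_br("unparseable rows (first 10): ",
            paste(utils::head(bad, 10), collapse = ", "))
  }
  act_bad <- which(df$variable == "activity" &
                     (df$value < 0 | df$value > 510))
  if (length(act_bad)) {
    stop_br("activity values outside [0, 510] at rows: ",
            paste(utils::head(act_bad, 10), collapse = ", "))
  }
  key <- paste(df$bear_id, df$variable)
  out <- lapply(split(seq_len(nrow(df)), key), function(idx) {
    o <- idx[order(ts[idx])]
    if (anyDuplicated(ts[o])) {
      stop_br("duplicate timestamps in series ", key[idx[1]])
    }
    biologging_series(df$bear_id[o[1]], df$variable[o[1]], ts[o],
                      df$value[o])
  })
  names(out) <- sub(" ", ".", names(out))
  out
}

#' Write biologging series to CSV
#'
#' Inverse of [read_series_csv()]; the round trip is the identity.
#'
#' @param series A [biologging_series()] or list of them.
#' @param path Output CSV path.
#' @export
write_series_csv <- function(series, path) {
  if (inherits(series, "biologging_series")) series <- list(series)
  df <- do.call(rbind, lapply(series, function(s) data.frame(
    bear_id = s$bear_id, timestamp = format(s$timestamp,
                                            "%Y-%m-%dT%H:%M:%S"),
    variable = s$variable, value = s$value, stringsAsFactors = FALSE)))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

# Parse ISO 8601 timestamps, returning NA (not an error) for bad rows so
# the caller can report their positions.
parse_iso_times <- function(x) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01",
                    tz = BR_TZ)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    need <- is.na(out)
    if (!any(need)) break
    out[need] <- as.POSIXct(strptime(x[need], fmt, tz = BR_TZ))
  }
  out
}

write_stamped_csv <- function(df, path, hash) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# config_hash: %s", hash), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Run the full rhythm-analysis pipeline on a simulated cohort
#'
#' Composes every stage in order: simulation, exclusions, daily means,
#' den entry/exit detection, state assignment, window tiling, periodogram
#' classification, covariate construction, (optionally) multinomial model
#' comparison, and the period summary table.  All outputs are written as
#' CSV files stamped with a hash of the configuration; identical
#' configuration and seed give identical outputs.
#'
#' @param sim_config A [simulation_config()] describing the cohort.
#' @param config A [pipeline_config()].
#' @param output_dir Directory for output CSVs (created if needed).
#' @param variables Which variables to simulate and analyse.
#'
#' @return Invisibly, a list with `states`, `windows`, `calls`,
#'   `covariates`, `period_summary`, optional `model` comparison, and
#'   `run_log`.
#' @export
run_pipeline <- function(sim_config, config = pipeline_config(),
                         output_dir = tempfile("bearrhythms_run_"),
                         variables = c("tb", "hr", "activity")) {
  stopifnot(inherits(sim_config, "simulation_config"),
            inherits(config, "pipeline_config"))
  dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
  hash <- config_hash(list(sim_config, config))
  log <- list(config_hash = hash, seed = config$seed, stages = list())
  stage <- function(name, n_in, n_out, notes = "") {
    log$stages[[name]] <<- data.frame(stage = name, records_in = n_in,
                                      records_out = n_out, notes = notes)
  }

  weather <- simulate_weather(sim_config, n_stations = 5)
  bear_ids <- sprintf("bear%02d", seq_len(sim_config$n_bears))
  metadata <- with_seed(sim_config$seed + 5L, data.frame(
    bear_id = bear_ids,
    lat = sim_config$latitude + stats::runif(sim_config$n_bears, -0.3, 0.3),
    lon = sim_config$longitude + stats::runif(sim_config$n_bears, -0.6, 0.6),
    sex = sample(c("Male", "Female"), sim_config$n_bears, replace = TRUE),
    age_class = sample(c("adult", "subadult"), sim_config$n_bears,
                       replace = TRUE, prob = c(0.7, 0.3)),
    status = sample(c("solitary", "pregnant", "with cubs"),
                    sim_config$n_bears, replace = TRUE,
                    prob = c(0.5, 0.25, 0.25)),
    body_mass = round(stats::runif(sim_config$n_bears, 17, 233)),
    stringsAsFactors = FALSE))
  den_records <- with_seed(sim_config$seed + 6L, data.frame(
    bear_id = bear_ids,
    from_date = format(sim_config$start_date),
    lat = metadata$lat + stats::runif(sim_config$n_bears, -0.05, 0.05),
    lon = metadata$lon + stats::runif(sim_config$n_bears, -0.1, 0.1),
    den_type = sample(c("anthill", "nest", "rock", "soil", "uprooted tree"),
                      sim_config$n_bears, replace = TRUE),
    open_area = round(stats::runif(sim_config$n_bears, 1, 100)),
    stringsAsFactors = FALSE))

  all_states <- list(); all_windows <- list(); all_calls <- list()
  all_covs <- list()
  for (b in seq_along(bear_ids)) {
    sim <- simulate_bear_year(sim_config, bear_ids[b], bear_index = b,
                              variables = unique(c("tb", variables)))
    caps <- event_dates(sim_config$capture_dates, b)
    dist <- event_dates(sim_config$disturbance_dates, b)
    filtered <- lapply(sim$series, function(s) {
      apply_exclusions(s, caps, dist)$series
    })
    smap <- seasonal_state_map(filtered$tb, offsets = config$offsets)
    filtered <- filtered[intersect(names(filtered), variables)]
    for (v in names(filtered)) {
      iv <- smap$intervals[[v]]
      iv$bear_id <- bear_ids[b]; iv$variable <- v
      all_states[[length(all_states) + 1]] <- iv
      tw <- tile_windows(smap, filtered[[v]],
                         min_days = config$min_window_days,
                         max_days = config$max_window_days,
                         max_gap = config$max_gap_days)
      for (w in tw$windows) {
        all_windows[[length(all_windows) + 1]] <- w
        call <- classify_window(w, alpha = config$alpha,
                                oversampling = config$oversampling,
                                band_edges = config$band_edges)
        all_calls[[length(all_calls) + 1]] <- call
        all_covs[[length(all_covs) + 1]] <- suppressWarnings(
          window_covariates(w, weather, den_records, metadata,
                            k = config$idw_k, power = config$idw_power))
      }
    }
  }

  states <- do.call(rbind, all_states)
  windows <- windows_table(all_windows)
  calls <- calls_table(all_calls)
  covariates <- do.call(rbind, all_covs)
  stage("simulate", NA, sim_config$n_bears)
  stage("segment", sim_config$n_bears, nrow(states))
  stage("windows", nrow(states), nrow(windows))
  stage("classify", nrow(windows), nrow(calls))
  stage("covariates", nrow(calls), nrow(covariates))

  summary_tab <- period_summary(calls)

  model <- NULL
  if (config$candidate_set %in% c("active", "hibernation")) {
    merged <- merge(merge(calls, windows[, c("window_id", "duration_days")],
                          by = "window_id"),
                    covariates, by = "window_id")
    sel <- merged[merged$state ==
                    if (config$candidate_set == "active") "active" else
                      "hibernation", , drop = FALSE]
    if (nrow(sel) >= 30 && length(unique(sel$class)) >= 2) {
      specs <- candidate_models(config$candidate_set)
      specs <- specs[c("m0", "m6")]   # null and day-length smooth
      model <- compare_models(specs, sel, n_folds = 5)
      stage("model", nrow(sel), nrow(model$table))
    } else {
      stage("model", nrow(sel), 0, "too few windows or classes; skipped")
    }
  }

  write_stamped_csv(states, file.path(output_dir, "states.csv"), hash)
  write_stamped_csv(windows, file.path(output_dir, "windows.csv"), hash)
  write_stamped_csv(calls, file.path(output_dir, "calls.csv"), hash)
  write_stamped_csv(covariates, file.path(output_dir, "covariates.csv"),
                    hash)
  write_stamped_csv(summary_tab,
                    file.path(output_dir, "period_summary.csv"), hash)
  if (!is.null(model)) {
    write_stamped_csv(model$table,
                      file.path(output_dir, "model_comparison.csv"), hash)
  }
  run_log <- do.call(rbind, log$stages)
  run_log$config_hash <- hash
  write_stamped_csv(run_log, file.path(output_dir, "run_log.csv"), hash)

  invisible(list(states = states, windows = windows, calls = calls,
                 covariates = covariates, period_summary = summary_tab,
                 model = model, run_log = run_log,
                 output_dir = output_dir, config_hash = hash))
}
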