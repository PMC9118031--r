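test_that("exclusions remove implausible Tb and post-event periods", {
  s <- regular_tb_series("2014-06-01", 20)
  out <- apply_exclusions(s)
  expect_identical(out$series$value, s$value)   # identity when clean
  # Tb below 30 is removed; exactly 30.0 is kept
  t0 <- as.POSIXct("2014-06-01 00:00:00", tz = br_timezone())
  s2 <- biologging_series("b", "tb", t0 + 3600 * (0:3),
                          c(29.9, 30.0, 35, 37))
  f <- apply_exclusions(s2)
  expect_equal(f$series$value, c(30.0, 35, 37))
  expect_equal(f$log$removed[f$log$rule == "tb_below_floor"], 1L)
  # activity series are not subject to the Tb floor
  a <- biologging_series("b", "activity", t0 + 3600 * (0:2), c(0, 5, 10))
  expect_equal(nrow(apply_exclusions(a)$series), 3L)
})

test_that("a capture removes fourteen days of data", {
  s <- regular_tb_series("2014-06-01", 20)
  f <- apply_exclusions(s, capture_dates = as.Date("2014-06-04"))
  left_days <- unique(as.Date(f$series$timestamp, tz = br_timezone()))
  expect_equal(length(left_days), 6L)          # 20 - 14 interior days
  expect_false(as.Date("2014-06-04") %in% left_days)
  expect_true(as.Date("2014-06-18") %in% left_days)
  # disturbances remove three days
  f2 <- apply_exclusions(s, disturbance_dates = as.Date("2014-06-04"))
  expect_equal(length(unique(as.Date(f2$series$timestamp,
                                     tz = br_timezone()))), 17L)
})

make_map <- function(state_days, start = "2014-06-01") {
  start <- as.Date(start)
  structure(list(
    bear_id = "bear01", den_entry = as.Date(NA), den_exit = as.Date(NA),
    intervals = list(tb = data.frame(
      state = "active", start = start, end = start + state_days - 1))),
    class = "seasonal_state_map")
}

test_that("window tiling follows the 25-day / 15-day floor arithmetic", {
  s100 <- regular_tb_series("2014-06-01", 100)
  tw <- tile_windows(make_map(100), s100)
  expect_length(tw$windows, 4L)
  expect_true(all(vapply(tw$windows, `[[`, 0, "duration_days") == 25))

  s60 <- regular_tb_series("2014-06-01", 60)
  tw60 <- tile_windows(make_map(60), s60)
  expect_length(tw60$windows, 2L)   # 25 + 25; the 10-day remainder drops
  expect_true("remainder_shorter_than_min" %in% tw60$log$reason)

  # an 18-day remainder is kept
  s68 <- regular_tb_series("2014-06-01", 68)
  tw68 <- tile_windows(make_map(68), s68)
  expect_length(tw68$windows, 3L)
  expect_equal(tw68$windows[[3]]$duration_days, 18)

  # states shorter than 15 days contribute nothing
  s10 <- regular_tb_series("2014-06-01", 10)
  expect_length(tile_windows(make_map(10), s10)$windows, 0L)
})

test_that("windows containing a gap over two days are discarded", {
  s <- regular_tb_series("2014-06-01", 50)
  dates <- as.Date(s$timestamp, tz = br_timezone())
  gap_days <- seq(as.Date("2014-06-11"), as.Date("2014-06-13"), by = "day")
  s_gap <- s[!dates %in% gap_days, ]
  class(s_gap) <- class(s)
  tw <- tile_windows(make_map(50), s_gap)
  expect_length(tw$windows, 1L)          # first window dropped, second kept
  expect_equal(as.Date(tw$windows[[1]]$start, tz = br_timezone()),
               as.Date("2014-06-26"))
  expect_true("gap_over_limit" %in% tw$log$reason)
})

test_that("tiled windows never overlap and stay within state budgets", {
  cfg <- simulation_config(n_bears = 1, seed = 21, tb_cadence_minutes = 30)
  tb <- simulate_bear_year(cfg, "b1", variables = "tb")$series$tb
  smap <- seasonal_state_map(tb)
  tw <- tile_windows(smap, tb)
  info <- windows_table(tw$windows)
  expect_true(all(info$duration_days >= 15 & info$duration_days <= 25))
  starts <- as.POSIXct(info$start, tz = br_timezone())
  ends <- as.POSIXct(info$end, tz = br_timezone())
  o <- order(starts)
  expect_true(all(as.numeric(starts[o][-1]) >=
                    as.numeric(ends[o][-length(ends)])))
  state_days <- sum(as.numeric(smap$intervals$tb$end -
                                 smap$intervals$tb$start) + 1)
  expect_lte(sum(info$duration_days), state_days)
})

test_that("season is the start year for active, den-entry year otherwise", {
  cfg <- simulation_config(n_bears = 1, seed = 22, tb_cadence_minutes = 30)
  tb <- simulate_bear_year(cfg, "b1", variables = "tb")$series$tb
  smap <- seasonal_state_map(tb)
  tw <- tile_windows(smap, tb)
  info <- windows_table(tw$windows)
  active_2015 <- info$state == "active" & startsWith(info$start, "2015")
  expect_true(all(info$season[active_2015] == 2015L))
  expect_true(all(info$season[info$state == "hibernation"] == 2014L))
  expect_true(all(info$season[info$state == "transition_exit"] == 2014L))
})
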