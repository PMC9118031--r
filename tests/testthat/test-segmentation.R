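test_that("daily means aggregate per calendar date", {
  s <- regular_tb_series("2014-10-01", 1, value = 37)
  dm <- daily_means(s)
  expect_equal(nrow(dm), 1L)
  expect_equal(dm$mean, 37)
  t0 <- as.POSIXct("2014-10-01 06:00:00", tz = br_timezone())
  s2 <- biologging_series("b", "tb", c(t0, t0 + 3600), c(36, 38))
  expect_equal(daily_means(s2)$mean, 37)
  expect_error(daily_means(s2[0, ]), "empty")
})

test_that("den entry is the first day of a 7-day run at or below 36.4", {
  win <- c(as.Date("2014-08-01"), as.Date("2015-01-31"))
  expect_true(is.na(detect_den_entry(daily_table("2014-10-01",
                                                 rep(37, 30)), win)))
  d <- daily_table("2014-10-01", c(37, 37, rep(36.3, 7), rep(37, 5)))
  expect_equal(detect_den_entry(d, win), as.Date("2014-10-03"))
  # a missing day breaks the run
  d_gap <- d[-6, ]
  expect_true(is.na(detect_den_entry(d_gap, win)))
  # six consecutive days are not enough
  d6 <- daily_table("2014-10-01", c(37, rep(36.3, 6), rep(37, 6)))
  expect_true(is.na(detect_den_entry(d6, win)))
})

test_that("den exit mirrors entry with the 36.7 threshold", {
  win <- c(as.Date("2015-02-01"), as.Date("2015-07-31"))
  expect_true(is.na(detect_den_exit(daily_table("2015-04-01",
                                                rep(33, 30)), win)))
  d <- daily_table("2015-04-01", c(rep(33, 9), rep(36.8, 7), rep(37, 4)))
  expect_equal(detect_den_exit(d, win), as.Date("2015-04-10"))
})

test_that("lowering all daily means never delays den entry", {
  win <- c(as.Date("2014-08-01"), as.Date("2015-01-31"))
  set.seed(11)
  for (i in 1:25) {
    means <- 36.5 + cumsum(rnorm(60, -0.03, 0.2))
    d <- daily_table("2014-10-01", means)
    e1 <- detect_den_entry(d, win)
    d2 <- d; d2$mean <- d2$mean - runif(1, 0, 1)
    e2 <- detect_den_entry(d2, win)
    if (!is.na(e1)) {
      expect_false(is.na(e2))
      expect_lte(as.numeric(e2), as.numeric(e1))
    }
  }
})

test_that("state intervals follow the per-variable transition offsets", {
  span <- c(as.Date("2014-06-01"), as.Date("2015-07-31"))
  iv <- assign_states(as.Date("2014-11-01"), as.Date("2015-04-10"),
                      "tb", span = span)
  te <- iv[iv$state == "transition_entry", ]
  expect_equal(te$start, as.Date("2014-10-19"))   # entry - 13 days
  expect_equal(te$end, as.Date("2014-12-01"))     # entry + 30 days
  # intervals are disjoint, ordered and cover the span
  expect_true(all(diff(as.numeric(iv$start)) > 0))
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1))
  expect_equal(iv$start[1], span[1])
  expect_equal(iv$end[nrow(iv)], span[2])
  expect_lt(max(iv$end[iv$state == "transition_entry"]),
            min(iv$start[iv$state == "transition_exit"]))
})

test_that("zero offsets split the year into active and hibernation only", {
  offs0 <- list(tb = list(pre_entry = 0, post_entry = 0,
                          pre_exit = 0, post_exit = 0))
  span <- c(as.Date("2014-06-01"), as.Date("2015-07-31"))
  iv <- assign_states(as.Date("2014-11-01"), as.Date("2015-04-10"),
                      "tb", offsets = offs0, span = span)
  expect_setequal(unique(iv$state), c("active", "hibernation"))
  hib <- iv[iv$state == "hibernation", ]
  expect_equal(hib$start, as.Date("2014-11-01"))
  expect_equal(hib$end, as.Date("2015-04-10"))
})

test_that("absent entry or exit labels the whole span active", {
  span <- c(as.Date("2014-06-01"), as.Date("2015-07-31"))
  iv <- assign_states(as.Date(NA), as.Date(NA), "tb", span = span)
  expect_equal(iv$state, "active")
  expect_equal(iv$start, span[1])
  expect_equal(iv$end, span[2])
})

test_that("overlapping transitions are truncated at the midpoint", {
  span <- c(as.Date("2014-06-01"), as.Date("2015-07-31"))
  iv <- assign_states(as.Date("2014-12-01"), as.Date("2015-01-10"),
                      "tb", span = span)
  expect_gt(length(attr(iv, "warnings")), 0)
  expect_lt(max(iv$end[iv$state == "transition_entry"]),
            min(iv$start[iv$state == "transition_exit"]))
  expect_true(all(iv$start[-1] == iv$end[-nrow(iv)] + 1))
})

test_that("segmentation recovers planted phenology and is idempotent", {
  cfg <- simulation_config(n_bears = 1, noise_sd = 0, seed = 13)
  tb <- simulate_bear_year(cfg, "b1", variables = "tb")$series$tb
  m1 <- seasonal_state_map(tb)
  m2 <- seasonal_state_map(tb)
  expect_identical(m1, m2)
  expect_equal(m1$den_entry, cfg$den_entry_day[1])
  expect_equal(m1$den_exit, cfg$den_exit_day[1])
  # activity offsets give a hibernation interval consistent with truth
  act_iv <- m1$intervals$activity
  hib <- act_iv[act_iv$state == "hibernation", ]
  expect_equal(hib$start, cfg$den_entry_day[1] + 9 + 1)
  expect_equal(hib$end, cfg$den_exit_day[1] - 10 - 1)
})
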