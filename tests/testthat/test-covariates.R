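test_that("day length matches the standard photoperiod model", {
  expect_lt(abs(day_length(0, as.Date("2015-05-10")) - 12), 0.2)
  expect_lt(abs(day_length(61, as.Date("2015-03-20")) - 12), 0.3)
  # strictly increasing from New Year to the June solstice at 61 N
  dl <- day_length(61, seq(as.Date("2015-01-01"), as.Date("2015-06-20"),
                           by = "day"))
  expect_true(all(diff(dl) > 0))
  # agreement with the geosphere implementation of the same model
  days <- seq(as.Date("2015-01-01"), as.Date("2015-12-31"), by = "day")
  expect_lt(max(abs(day_length(61, days) -
                      geosphere::daylength(61, seq_along(days)))), 1e-9)
  # 365-day periodicity and solstice symmetry
  expect_lt(max(abs(day_length(61, days) - day_length(61, days + 365))),
            0.06)
  dl15 <- day_length(61, days)
  sol <- days[which.max(dl15)]
  expect_lt(max(abs(day_length(61, sol - 1:10) -
                      day_length(61, sol + 1:10))), 0.05)
})

test_that("day-length direction uses window endpoints with ties increasing", {
  expect_equal(day_length_direction(as.Date(c("2015-05-01", "2015-05-25")),
                                    61), "increasing")
  expect_equal(day_length_direction(as.Date(c("2015-08-01", "2015-08-25")),
                                    61), "decreasing")
  # symmetric straddle of the solstice is a tie, classified increasing
  sol <- as.Date("2015-06-21")
  expect_equal(day_length_direction(c(sol - 12, sol + 12), 61),
               "increasing")
})

test_that("IDW interpolation honours exact hits, symmetry and bounds", {
  wx <- data.frame(
    station_id = c("a", "b"), lat = c(61, 61), lon = c(14.9, 15.1),
    date = as.Date("2014-12-01"), ta_min = c(-5, 5), ta_mean = c(0, 10),
    ta_max = c(5, 15), snow_depth = c(0.2, 0.4))
  hit <- idw_interpolate(wx, 61, 14.9, "2014-12-01", k = 2)
  expect_equal(hit[["ta_mean"]], 0)
  mid <- idw_interpolate(wx, 61, 15.0, "2014-12-01", k = 2)
  expect_equal(mid[["ta_mean"]], 5, tolerance = 1e-6)
  expect_equal(mid[["snow_depth"]], 0.3, tolerance = 1e-6)
  # fewer stations than requested warns and uses all available
  expect_warning(idw_interpolate(wx, 61.5, 15, "2014-12-01", k = 3),
                 "available")
  # absent date yields missing values
  expect_true(all(is.na(idw_interpolate(wx, 61, 15, "2014-12-02"))))
})

test_that("random IDW queries stay within the neighbour value range", {
  cfg <- simulation_config()
  wx <- simulate_weather(cfg, 5)
  set.seed(3)
  for (i in 1:20) {
    d <- sample(unique(wx$date), 1)
    v <- idw_interpolate(wx, 61.2 + runif(1, -0.5, 0.5),
                         15 + runif(1, -1, 1), d)
    day <- wx[wx$date == d, ]
    expect_gte(v[["ta_mean"]], min(day$ta_mean))
    expect_lte(v[["ta_mean"]], max(day$ta_mean))
  }
})

test_that("window covariates average the window's daily conditions", {
  cfg <- simulation_config()
  wx <- simulate_weather(cfg, 4)
  w <- tone_window(24, amp = 1, sd = 0, start = as.Date("2015-05-01"))
  metadata <- data.frame(bear_id = "bear01", lat = 61.2, lon = 15,
                         sex = "Female", age_class = "adult",
                         status = "solitary", body_mass = 90)
  dens <- data.frame(bear_id = "bear01", from_date = "2014-10-01",
                     lat = 61.25, lon = 15.05, den_type = "anthill",
                     open_area = 20)
  cov <- window_covariates(w, wx, dens, metadata)
  days <- seq(as.Date("2015-05-01"), as.Date("2015-05-25"), by = "day")
  expect_equal(cov$day_length, mean(day_length(61.2, days)),
               tolerance = 1e-9)
  expect_equal(cov$day_length_direction, "increasing")
  expect_equal(cov$body_mass, 90)
  expect_equal(cov$den_type, "anthill")
  # daily IDW means match a direct recomputation
  direct <- mean(vapply(as.list(days), function(d)
    idw_interpolate(wx, 61.2, 15, d)[["ta_mean"]], 0))
  expect_equal(cov$ta_mean, direct, tolerance = 1e-9)
  # hibernation windows use the den location
  wh <- tone_window(120, amp = 1, sd = 0, start = as.Date("2015-01-10"),
                    state = "hibernation")
  covh <- window_covariates(wh, wx, dens, metadata)
  daysh <- seq(as.Date("2015-01-10"), as.Date("2015-02-03"), by = "day")
  direct_h <- mean(vapply(as.list(daysh), function(d)
    idw_interpolate(wx, 61.25, 15.05, d)[["snow_depth"]], 0))
  expect_equal(covh$snow_depth, direct_h, tolerance = 1e-9)
})
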