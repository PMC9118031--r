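test_that("the thin-plate penalty shrinks the smooth to a straight line", {
  set.seed(4)
  x <- runif(400, 0, 10)
  sb <- spline_basis(x, 8)
  ev <- eigen(sb$S, symmetric = TRUE, only.values = TRUE)$values
  expect_true(all(ev > -1e-8))                     # positive semidefinite
  expect_lt(max(abs(sb$S - t(sb$S))), 1e-10)       # symmetric
  cls <- ifelse(runif(400) < plogis(-2 + 0.4 * x + sin(x)),
                "ultradian", "diel")
  dat <- data.frame(class = cls, x = x)
  fit <- fit_multinomial(model_spec("sm", "s(x)", groups = character()),
                         dat, lambda = 1e8)
  xs <- seq(0, 10, length.out = 60)
  P <- predict_probs(fit, data.frame(x = xs))
  lp <- log(P[, 2] / P[, 1])    # log odds are affine when the smooth dies
  expect_gt(summary(stats::lm(lp ~ xs))$r.squared, 0.999)
  expect_error(spline_basis(rep(1, 30)), "constant")
})

test_that("a full-rank basis interpolates values at its construction points", {
  x <- seq(0, 1, length.out = 8)
  sb <- spline_basis(x, 8)
  X <- cbind(1, sb$X)
  y <- sin(2 * x) + x^2
  beta <- solve(X, y)
  expect_lt(max(abs(X %*% beta - y)), 1e-6)
})

test_that("intercept-only fits reproduce class frequencies exactly", {
  dat <- data.frame(class = rep(c("diel", "ultradian", "infradian"),
                                c(60, 30, 10)))
  fit <- fit_multinomial(model_spec("m0", groups = character()), dat)
  expect_true(fit$converged)
  expect_equal(unname(fit$fitted[1, c("diel", "ultradian", "infradian")]),
               c(0.6, 0.3, 0.1), tolerance = 1e-8)
  # balanced four-class data predicts uniform probabilities
  dat4 <- data.frame(class = rep(c("diel", "ultradian", "infradian",
                                   "arrhythmic"), each = 10))
  fit4 <- fit_multinomial(model_spec("m0", groups = character()), dat4)
  expect_equal(unname(fit4$fitted[1, ]), rep(0.25, 4), tolerance = 1e-8)
})

test_that("duplicating every observation leaves estimates unchanged", {
  rc <- recovery_cohort(n = 300, seed = 6)
  sp <- model_spec("sm", "s(day_length)", groups = character())
  f1 <- fit_multinomial(sp, rc$data, lambda = 1)
  f2 <- fit_multinomial(sp, rbind(rc$data, rc$data), lambda = 1)
  expect_equal(f1$coefficients, f2$coefficients, tolerance = 1e-6)
})

test_that("known slopes are recovered within sampling error", {
  rc <- recovery_cohort(n = 2000, seed = 7)
  sp <- model_spec("lin", "day_length", groups = character())
  fit <- fit_multinomial(sp, rc$data)
  expect_true(fit$converged)
  est <- fit$coefficients["day_length", ]
  se <- fit$se["day_length", ]
  truth <- rc$coefs["day_length", names(est)]
  expect_true(all(abs(est - truth) < 3 * se))
  P <- predict_probs(fit, rc$data)
  expect_lt(mean(abs(P - rc$sim$probabilities)), 0.03)
  expect_lt(max(abs(rowSums(P) - 1)), 1e-12)
})

test_that("predicted probabilities are monotone in a positive slope", {
  rc <- recovery_cohort(n = 1000, seed = 8)
  fit <- fit_multinomial(model_spec("lin", "day_length",
                                    groups = character()), rc$data)
  xs <- data.frame(day_length = seq(6, 19, length.out = 40))
  P <- predict_probs(fit, xs)
  expect_true(all(diff(P[, "ultradian"] /
                         (P[, "ultradian"] + P[, "diel"])) > 0))
})

test_that("unseen factor levels are rejected by name, unseen groups are not", {
  set.seed(10)
  dat <- data.frame(
    class = sample(c("diel", "ultradian"), 120, replace = TRUE),
    sex = sample(c("Male", "Female"), 120, replace = TRUE),
    bear_id = sample(sprintf("b%d", 1:6), 120, replace = TRUE))
  fit <- fit_multinomial(model_spec("sx", "sex", groups = "bear_id"), dat)
  expect_error(predict_probs(fit, data.frame(sex = "Unknown",
                                             bear_id = "b1")),
               "Unknown")
  # a new bear falls back to the population level, no error
  P <- predict_probs(fit, data.frame(sex = "Male", bear_id = "b99"))
  expect_equal(sum(P), 1, tolerance = 1e-12)
})

test_that("group ridge effects shrink toward the population level", {
  set.seed(12)
  n <- 400
  bear <- sample(sprintf("b%d", 1:8), n, replace = TRUE)
  eta <- ifelse(bear %in% c("b1", "b2"), 1.5, -0.5)
  cls <- ifelse(runif(n) < plogis(eta), "ultradian", "diel")
  dat <- data.frame(class = cls, bear_id = bear)
  fit_r <- fit_multinomial(model_spec("g", groups = "bear_id"), dat,
                           ridge_lambda = 1e6)
  fit_f <- fit_multinomial(model_spec("g", groups = "bear_id"), dat,
                           ridge_lambda = 1e-3)
  co_r <- fit_r$coefficients[grep("bear_id", rownames(fit_r$coefficients)), ]
  co_f <- fit_f$coefficients[grep("bear_id", rownames(fit_f$coefficients)), ]
  expect_lt(max(abs(co_r)), 0.01)       # heavy ridge: no group effects
  expect_gt(max(abs(co_f)), 0.2)        # light ridge: bears differ
})

test_that("separation is detected and reported", {
  dat <- data.frame(class = rep(c("diel", "ultradian"), each = 20),
                    x = rep(c(0, 1), each = 20))
  expect_warning(
    fit <- fit_multinomial(model_spec("sep", "x", groups = character()),
                           dat),
    "separation")
  expect_true(fit$separated)
})

test_that("cross-validated elpd matches its closed forms", {
  # uniform four-class predictor: elpd = n log(1/4)
  dat4 <- data.frame(class = rep(c("diel", "ultradian", "infradian",
                                   "arrhythmic"), each = 10))
  cv <- cv_elpd(model_spec("m0", groups = character()), dat4,
                n_folds = 5, grouping = NULL)
  expect_equal(cv$elpd, 40 * log(0.25), tolerance = 1e-6)
  # a perfectly separable predictor drives elpd to its upper bound 0
  datp <- data.frame(class = rep(c("diel", "ultradian"), each = 40),
                     x = rep(c(-1, 1), each = 40))
  cvp <- suppressWarnings(
    cv_elpd(model_spec("lin", "x", groups = character()), datp,
            n_folds = 4, grouping = NULL))
  expect_gt(cvp$elpd, -0.01)
  expect_lte(cvp$elpd, 0)
})

test_that("stacking weights solve the simplex log-score problem", {
  p <- matrix(runif(200, 0.2, 0.9), 100, 2,
              dimnames = list(NULL, c("a", "b")))
  st1 <- stacking_weights(p[, 1, drop = FALSE])
  expect_equal(unname(st1$weights), 1)
  st2 <- stacking_weights(cbind(a = p[, 1], b = p[, 1]))
  expect_equal(unname(st2$weights), c(0.5, 0.5))
  # a dominating model takes all the weight
  good <- rep(0.9, 100); bad <- rep(0.2, 100)
  st3 <- stacking_weights(cbind(good = good, bad = bad))
  expect_gt(st3$weights[["good"]], 0.999)
  expect_equal(sum(st3$weights), 1, tolerance = 1e-9)
  expect_true(all(st3$weights >= 0))
})

test_that("model comparison ranks the generating model first", {
  rc <- recovery_cohort(n = 800, seed = 14)
  specs <- list(m0 = model_spec("m0", groups = character()),
                m1 = model_spec("m1", "day_length", groups = character()))
  cmp <- compare_models(specs, rc$data, n_folds = 5, grouping = NULL)
  expect_equal(cmp$table$model[1], "m1")
  expect_gt(cmp$table$stacking_weight[cmp$table$model == "m1"], 0.6)
  expect_equal(sum(cmp$table$stacking_weight), 1, tolerance = 1e-9)
})

test_that("the printed candidate sets are constructible by name", {
  hib <- candidate_models("hibernation")
  act <- candidate_models("active")
  expect_length(hib, 15L)
  expect_length(act, 13L)
  expect_named(hib, sprintf("m%d", 0:14))
  expect_named(act, sprintf("m%d", 0:12))
  expect_true(all(c("day_length_direction",
                    "s(day_length):day_length_direction") %in%
                    act$m11$terms))
  expect_identical(hib$m5$terms, "s(snow_depth)")
})
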