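test_that("single-point estimator inverts the progress model", {
  r <- kapp_single_point(0.50, 15)
  expect_equal(r$k_app, log(2) / 15)
  expect_identical(r$provenance, "single-point")
  expect_equal(kapp_single_point(0, 120)$k_app, 0)
  # exact round trip on random (f, t)
  set.seed(11)
  for (i in 1:50) {
    f <- runif(1, 0.001, 0.999)
    t <- runif(1, 0.1, 500)
    expect_equal(fraction_cleaved(kapp_single_point(f, t), t), f,
                 tolerance = 1e-10)
  }
})

test_that("saturated single points yield a censored lower bound, not a rate", {
  r <- kapp_single_point(1, 30)
  expect_true(r$lower_bound)
  expect_true(is.na(r$k_app))
  expect_error(kapp_single_point(1.2, 30), "domain error")
  expect_error(kapp_single_point(0.5, 0), "t")
})

test_that("exponential fit recovers the generating rate from noiseless data", {
  k_true <- 0.0462
  for (times in list(c(5, 15, 30, 60), c(1, 2, 4), c(40, 90, 180, 400))) {
    tc <- time_course(times, 1 - exp(-k_true * times))
    fit <- kapp_fit(tc)
    expect_equal(fit$k_app, k_true, tolerance = 1e-7)
    expect_identical(fit$provenance, "fitted")
  }
})

test_that("fit handles the on-column release pair and saturated points", {
  # two-point course mirroring fast on-column release (80% at 15 min)
  tc <- time_course(c(15, 30), c(0.80, 0.96))
  fit <- kapp_fit(tc)
  expect_equal(fit$k_app, log(5) / 15, tolerance = 0.01)
  expect_gte(fraction_cleaved(fit, 30), 0.90)
  # saturated lanes are dropped when enough unsaturated points remain
  k <- 0.1
  times <- c(5, 10, 20, 240, 480)
  f <- pmin(1, round(1 - exp(-k * times), 2))
  tc2 <- time_course(times, f)
  expect_equal(kapp_fit(tc2, sat_eps = 0.005)$k_app, k, tolerance = 0.05)
  # all saturated -> unidentifiable
  tc3 <- time_course(c(60, 120), c(1, 1))
  expect_error(kapp_fit(tc3), "saturated|unidentifiable")
  expect_error(kapp_fit(time_course(30, 0.5)), "2 usable")
})

test_that("fitted rates are unbiased and well-calibrated on noisy synthetic courses", {
  k_true <- 0.05
  times <- c(5, 10, 15, 25, 40, 60, 90, 140)
  n_ok <- 0
  rel_err <- numeric(200)
  ks <- numeric(200)
  set.seed(202)
  for (i in 1:200) {
    f <- pmin(pmax(1 - exp(-k_true * times) + rnorm(8, sd = 0.02), 0), 1)
    fit <- kapp_fit(time_course(times, f))
    ks[i] <- fit$k_app
    rel_err[i] <- abs(fit$k_app - k_true) / k_true
    if (is.finite(fit$se) &&
        abs(fit$k_app - k_true) <= 3 * fit$se) n_ok <- n_ok + 1
  }
  expect_lt(median(rel_err), 0.10)
  expect_lt(abs(mean(ks) - k_true) / k_true, 0.02)
  expect_gte(n_ok / 200, 0.95)
})

test_that("fold excess reports the molar substrate:enzyme ratio", {
  expect_equal(fold_excess(100, 0.001), 1e5)
  expect_equal(fold_excess(50, 50), 1)
  expect_equal(fold_excess(100, 0.3), 1000 / 3, tolerance = 1e-12)
  expect_error(fold_excess(100, 0), "E0")
})

test_that("minimal complete concentration follows the lowest-passing-lane rule", {
  ts <- titration_series(c(0.01, 0.03, 0.1, 0.3, 1, 3),
                         c(0.10, 0.30, 0.70, 0.94, 0.97, 1.0))
  res <- min_complete_conc(ts, threshold = 0.95)
  expect_equal(res$conc_uM, 1)
  expect_false(res$censored)
  expect_false(res$upper_bound_only)
  expect_false(res$nonmonotone_warning)
  # censored when nothing passes
  low <- titration_series(c(0.1, 1), c(0.2, 0.5))
  expect_true(min_complete_conc(low)$censored)
  # lowest lane already passing is only an upper bound
  hi <- titration_series(c(0.1, 1), c(0.97, 1))
  expect_true(min_complete_conc(hi)$upper_bound_only)
  # noise-induced dip above the passing lane raises the quality flag
  dip <- titration_series(c(0.1, 0.3, 1, 3), c(0.2, 0.96, 0.93, 0.99))
  r2 <- min_complete_conc(dip)
  expect_equal(r2$conc_uM, 0.3)
  expect_true(r2$nonmonotone_warning)
  expect_error(min_complete_conc(data.frame()), "titration_series")
})

test_that("minimal concentration is monotone in the threshold", {
  ts <- titration_series(c(0.01, 0.03, 0.1, 0.3, 1, 3),
                         c(0.10, 0.30, 0.70, 0.94, 0.97, 1.0))
  concs <- sapply(c(0.25, 0.5, 0.8, 0.95, 0.99),
                  function(th) min_complete_conc(ts, th)$conc_uM)
  expect_true(all(diff(concs) >= 0))
})

test_that("activity comparisons give folds with direction and honor condition matching", {
  a <- apparent_rate(0.04, "fitted", conditions = list(substrate = "xLC3B",
                                                       temp_C = 25))
  b <- apparent_rate(0.01, "fitted", conditions = list(substrate = "xLC3B",
                                                       temp_C = 25))
  cmp <- compare_activity(a, b)
  expect_equal(cmp$fold, 4)
  expect_identical(cmp$faster, "a")
  expect_false(cmp$is_bound)
  # min-conc comparisons invert: lower concentration = more active
  m1 <- min_complete_conc(titration_series(c(0.25, 1, 4), c(0.2, 0.96, 1)))
  m2 <- min_complete_conc(titration_series(c(0.1, 0.25, 1), c(0.3, 0.97, 1)))
  cmp2 <- compare_activity(m1, m2)
  expect_equal(cmp2$fold, 4)
  expect_identical(cmp2$faster, "b")
  # censored vs numeric becomes a bound
  mc <- min_complete_conc(titration_series(c(1, 3), c(0.2, 0.4)))
  cmp3 <- compare_activity(m2, mc)
  expect_true(cmp3$is_bound)
  expect_identical(cmp3$faster, "a")
  # mismatched conditions are refused, naming the axis
  c_hot <- apparent_rate(0.02, "fitted", conditions = list(substrate = "xLC3B",
                                                           temp_C = 37))
  expect_error(compare_activity(a, c_hot), "temp_C")
  expect_error(compare_activity(a, m1), "comparison error")
})

test_that("over-digestion fold divides applied by minimal sufficient enzyme", {
  expect_equal(overdigestion_fold(20, 0.001)$fold, 20000)
  expect_equal(overdigestion_fold(5, 5)$fold, 1)
  # minimal conc known only as an upper bound ("< x") -> fold is a lower bound
  ub <- min_complete_conc(titration_series(c(0.01, 0.1), c(0.99, 1)))
  res <- overdigestion_fold(20, ub)
  expect_equal(res$fold, 2000)
  expect_identical(res$bound, "lower")
  cens <- min_complete_conc(titration_series(c(0.01, 0.1), c(0.1, 0.2)))
  expect_error(overdigestion_fold(20, cens), "censored")
})
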