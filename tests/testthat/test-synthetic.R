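test_that("generators are deterministic in the seed and independent across streams", {
  p <- base_params()
  noisy <- noise_model(fraction_sigma = 0.03)
  a <- gen_timecourse(p, c(0, 15, 30, 60), noisy, seed = 9)
  b <- gen_timecourse(p, c(0, 15, 30, 60), noisy, seed = 9)
  expect_identical(a, b)
  c <- gen_timecourse(p, c(0, 15, 30, 60), noisy, seed = 10)
  expect_false(identical(a$fraction_cleaved, c$fraction_cleaved))
  t1 <- gen_titration(1, 10, 100, c(0.01, 0.1, 1), 1200, noisy, seed = 9)
  t2 <- gen_titration(1, 10, 100, c(0.01, 0.1, 1), 1200, noisy, seed = 9)
  expect_identical(t1, t2)
  s1 <- gen_standards(seed = 9)
  expect_identical(s1, gen_standards(seed = 9))
})

test_that("noiseless time courses equal the integrated model and the closed form", {
  p <- base_params()
  times <- c(0, 10, 30, 90, 240)
  tc <- gen_timecourse(p, times, noise_model(0, 0, 0), seed = 1)
  expect_equal(tc$fraction_cleaved,
               simulate_ode(p, times)$course$fraction_cleaved)
  expect_equal(tc$fraction_cleaved,
               fraction_cleaved(kapp_from_params(p), times),
               tolerance = 1e-6)
  # band synthesis reproduces the fractions through the calibration
  tcb <- gen_timecourse(p, times, noise_model(0, 0, 0), seed = 1,
                        bands = TRUE, response_factor = 0.8)
  cv <- build_standard_curve(gen_standards(response_factor = 0.8,
                                           noise = noise_model(0, 0, 0)))
  f_hat <- fraction_from_bands(tcb$intensity_fl[-1], tcb$intensity_ccp[-1],
                               cv)
  expect_equal(f_hat, tc$fraction_cleaved[-1], tolerance = 1e-6)
})

test_that("noiseless titrations rise strictly with enzyme and start at zero", {
  ts <- gen_titration(kcat = 1, K_M = 10, S0 = 100,
                      enzyme_concs = c(0, 0.001, 0.01, 0.1, 1),
                      time = 1200, noise = noise_model(0, 0, 0), seed = 2)
  expect_equal(ts$fraction_cleaved[1], 0)
  expect_true(all(diff(ts$fraction_cleaved) > 0))
})

test_that("planted minimal concentrations are recovered from noisy titrations", {
  # plant k so that the 0.95 threshold is crossed inside the tested range
  concs <- 10^seq(-3, 1, by = 0.5)
  quiet <- gen_titration(1, 10, 100, concs, time = 1200,
                         noise = noise_model(0, 0, 0), seed = 1)
  planted <- min_complete_conc(quiet)$conc_uM
  grid_step <- 1  # half-decade spacing: one step in index terms
  hits <- 0
  for (s in 1:100) {
    ts <- gen_titration(1, 10, 100, concs, time = 1200,
                        noise = noise_model(fraction_sigma = 0.02), seed = s)
    got <- min_complete_conc(ts)
    if (!got$censored &&
        abs(log10(got$conc_uM) - log10(planted)) <= 0.5 + 1e-9) {
      hits <- hits + 1
    }
  }
  expect_gte(hits / 100, 0.95)
})

test_that("planted cross-reactivity orderings survive generation", {
  # cognate >> near-cognate >> none, as in graded titration panels
  spec <- matrix(c(1, 0.01, 0,
                   0, 1, 0,
                   0, 0, 1), 3, 3, byrow = TRUE,
                 dimnames = list(paste0("P", 1:3), paste0("S", 1:3)))
  cog <- setNames(rownames(spec), colnames(spec))
  g <- gen_crossreact(spec, cog, noise = noise_model(0, 0, 0), seed = 4,
                      conditions = list(kcat = 1, K_M = 10, S0 = 100,
                                        E0 = 0.05, time_min = 180,
                                        temp_C = 25))
  d <- g$data
  f <- function(p, s) d$fraction_cleaved[d$protease == p & d$substrate == s]
  expect_gt(f("P1", "S1"), f("P1", "S2"))
  expect_gt(f("P1", "S2"), f("P1", "S3"))
  expect_equal(f("P1", "S3"), 0)
})

test_that("noiseless generation then estimation is the identity end-to-end", {
  p <- base_params()
  k_true <- kapp_from_params(p)$k_app
  times <- c(0, 20, 60, 150, 400)
  tc <- gen_timecourse(p, times, noise_model(0, 0, 0), seed = 1)
  expect_equal(kapp_fit(tc)$k_app, k_true, tolerance = 1e-5)
  std <- gen_standards(response_factor = 1.3, noise = noise_model(0, 0, 0))
  expect_equal(build_standard_curve(std)$r, 1.3, tolerance = 1e-3)
})
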