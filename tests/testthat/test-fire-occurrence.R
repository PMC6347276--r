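test_that("Chapman-Richards constant matches its closed form", {
  expect_equal(chapman_k(0.6, 0.99), -log(0.01) / 0.39, tolerance = 1e-12)
  expect_equal(chapman_k(0.6, 0.99), 11.809, tolerance = 1e-4)
  expect_equal(chapman_k(0.6, 1.0), -log(0.01) / 0.40, tolerance = 1e-12)
  expect_equal(chapman_k(0.6, 1.0), 11.513, tolerance = 1e-4)
  expect_error(chapman_k(0.6, 0.6), "degenerate")
  expect_error(chapman_k(0.7, 0.6), "degenerate")
  p <- ignition_params()
  expect_identical(p$k, chapman_k(p$ffmc_min_frac, p$ffmc_max_frac))
})

test_that("initiation probability is zero up to the minimum fraction and near one at the maximum", {
  p <- ignition_params()
  expect_identical(initiation_probability(0.5, p), 0)
  expect_identical(initiation_probability(0.6, p), 0)
  expect_identical(initiation_probability(0, p), 0)
  # k * (0.99 - 0.6) = -ln(0.01) makes s = (1 - 0.01)^2 exactly
  expect_equal(initiation_probability(0.99, p), 0.9801, tolerance = 1e-12)
})

test_that("initiation probability is continuous, monotone, and below one", {
  p <- ignition_params()
  x <- seq(0, 2, by = 1e-3)
  s <- initiation_probability(x, p)
  expect_true(all(diff(s) >= 0))
  expect_true(all(s >= 0 & s < 1))
  expect_lt(max(abs(diff(s))), 0.03)   # no jumps at the clamp boundary
})

test_that("unlimited ignition fires only when both codes exceed their thresholds", {
  veg <- default_veg_params()[1, ]
  p <- ignition_params(suppression_factor = 1.03)
  expect_true(unlimited_check(veg$ffmc_threshold + 1, veg$bui_threshold + 1,
                              veg, FALSE, p))
  expect_false(unlimited_check(veg$ffmc_threshold + 1, veg$bui_threshold - 1,
                               veg, FALSE, p))
  expect_false(unlimited_check(veg$ffmc_threshold - 1, veg$bui_threshold + 1,
                               veg, FALSE, p))
  # ties do not ignite
  expect_false(unlimited_check(veg$ffmc_threshold, veg$bui_threshold + 1,
                               veg, FALSE, p))
  # marginally above base thresholds but below suppression-scaled ones
  f <- veg$ffmc_threshold * 1.01; b <- veg$bui_threshold * 1.01
  expect_true(unlimited_check(f, b, veg, FALSE, p))
  expect_false(unlimited_check(f, b, veg, TRUE, p))
})

test_that("stochastic stages gate as specified", {
  veg <- default_veg_params()[1, ]
  p0 <- ignition_params(p_ignition_source = 0)
  set.seed(41)
  expect_false(any(stochastic_decide(rep(101, 5000), rep(1e4, 5000), veg, p0)))
  # stage-two gate: half the threshold never fires even with forced draws
  p <- ignition_params()
  expect_false(any(stochastic_decide(veg$ffmc_threshold * 0.5,
                                     veg$bui_threshold * 10, veg, p,
                                     u1 = 0, u3 = 0)))
  expect_false(any(stochastic_decide(veg$ffmc_threshold * 10,
                                     veg$bui_threshold * 0.5, veg, p,
                                     u1 = 0, u3 = 0)))
})

test_that("stochastic mode ignites between the fractional and full thresholds where unlimited cannot", {
  veg <- default_veg_params()[1, ]
  p <- ignition_params()
  ffmc <- veg$ffmc_threshold * 0.8
  bui <- veg$bui_threshold * 0.8
  expect_false(unlimited_check(ffmc, bui, veg, FALSE, p))
  expect_true(stochastic_decide(ffmc, bui, veg, p, u1 = 0, u3 = 0))
  # and per-day probability is bounded by the ignition-source probability
  s <- initiation_probability(10, p)
  expect_lte(p$p_ignition_source * s, p$p_ignition_source)
})

test_that("stage-one exposure frequency matches its Bernoulli rate", {
  veg <- default_veg_params()[1, ]
  p <- ignition_params()
  n <- 1e6
  set.seed(42)
  # fuels far above thresholds force the initiation probability to ~1,
  # isolating the stage-one draw
  fires <- stochastic_decide(rep(veg$ffmc_threshold * 2, n),
                             rep(veg$bui_threshold * 2, n), veg, p)
  se <- sqrt(0.001 * 0.999 / n)
  expect_lt(abs(mean(fires) - 0.001), 3 * se)
})

test_that("the fire calendar is reproducible and mode occurrence is ordered", {
  cfg <- vf_config(grid = list(nx = 4, ny = 4), years = c(1990, 2009))
  f <- gen_monthly_climate(cfg, seed = 5)
  cal1 <- build_fire_calendar(f, seed = 5)
  cal2 <- build_fire_calendar(f, seed = 5)
  expect_identical(cal1$FF$fire, cal2$FF$fire)
  expect_identical(cal1$SF$severity, cal2$SF$severity)
  # suppression can only remove fires relative to unlimited ignitions
  expect_true(all(cal1$FF$fire | !cal1$FS$fire))
  # severity defined exactly where fires occur, and within [0, 1]
  for (m in c("FF", "FS", "SF")) {
    sev <- cal1[[m]]$severity[cal1[[m]]$fire]
    expect_true(all(!is.na(sev) & sev >= 0 & sev <= 1))
    expect_true(all(is.na(cal1[[m]]$severity[!cal1[[m]]$fire])))
  }
})
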