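test_that("precipitation disaggregation conserves monthly totals", {
  set.seed(11)
  expect_equal(disaggregate_precip(0, 30, 0.4), numeric(30))
  for (i in 1:25) {
    tot <- runif(1, 0, 400)
    r <- disaggregate_precip(tot, 31, runif(1, 0.05, 1))
    expect_true(all(r >= 0))
    expect_equal(sum(r), tot, tolerance = 1e-12)
  }
  expect_error(disaggregate_precip(10, 0, 0.5), "n_days")
  expect_error(disaggregate_precip(-1, 30, 0.5), "nonnegative")
  expect_error(disaggregate_precip(10, 30, 0), "wet_day_prob")
})

test_that("mean wet-day count matches the binomial expectation", {
  set.seed(12)
  n_months <- 5000
  p <- 0.3
  n_days <- 30
  wet <- replicate(n_months, sum(disaggregate_precip(100, n_days, p) > 0))
  se <- sqrt(n_days * p * (1 - p) / n_months)
  expect_lt(abs(mean(wet) - n_days * p), 4 * se)
})

test_that("rain wets fine fuels: FFMC lower with heavy rain, all else equal", {
  dry <- update_ffmc(85, 25, 40, 15, 0)
  wet <- update_ffmc(85, 25, 40, 15, 12)
  expect_lt(wet, dry)
})

test_that("FFMC stays in [0, 101] and drying days are monotone in temperature and humidity", {
  drying_ed <- function(temp, rh) {
    0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
      0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  }
  set.seed(13)
  checked <- 0
  for (i in 1:300) {
    f0 <- runif(1, 0, 101)
    wx <- random_weather(1, seed = 1300 + i)
    f <- update_ffmc(f0, wx$temp, wx$rh, wx$wind, wx$rain)
    expect_true(f >= 0 && f <= 101)
    # in the drying regime (fuel moisture above the drying equilibrium at
    # both settings, no rain) hotter never decreases FFMC and more humid
    # never increases it; in the wetting regime a hotter/drier day can
    # legitimately speed the approach to the wetting equilibrium instead
    mo <- 147.2 * (101 - f0) / (59.5 + f0)
    if (wx$rain > 0.5) next
    rh_hum <- min(wx$rh + 10, 100)
    if (mo > drying_ed(wx$temp + 5, wx$rh) &&
        mo > drying_ed(wx$temp, rh_hum) && mo > drying_ed(wx$temp, wx$rh)) {
      f_hot <- update_ffmc(f0, wx$temp + 5, wx$rh, wx$wind, wx$rain)
      f_hum <- update_ffmc(f0, wx$temp, rh_hum, wx$wind, wx$rain)
      expect_gte(f_hot, f - 1e-9)
      expect_lte(f_hum, f + 1e-9)
      checked <- checked + 1
    }
  }
  expect_gt(checked, 50)   # the sweep actually exercises the property
})

test_that("constant hot dry weather converges to the reference fixed point", {
  temp <- 30; rh <- 20; wind <- 10
  f_pkg <- 60
  for (d in 1:200) f_pkg <- update_ffmc(f_pkg, temp, rh, wind, 0)
  # fixed-point iteration oracle: drive the independent transcription to
  # its equilibrium under the same constant weather
  f_ref <- 95
  for (d in 1:200) f_ref <- ref_ffmc(f_ref, temp, rh, wind, 0)
  expect_equal(f_pkg, f_ref, tolerance = 1e-6)
  # the fixed point sits at the FF-scale image of the drying equilibrium
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  expect_equal(f_pkg, 59.5 * (250 - ed) / (147.2 + ed), tolerance = 0.05)
})

test_that("moisture codes match the independent reference transcription on random weather", {
  for (seed in c(21, 22, 23)) {
    wx <- random_weather(30, seed)
    f_pkg <- 85; d_pkg <- 6; c_pkg <- 15
    f_ref <- 85; d_ref <- 6; c_ref <- 15
    for (i in seq_len(30)) {
      month <- ((i - 1) %/% 3) %% 12 + 1
      f_pkg <- update_ffmc(f_pkg, wx$temp[i], wx$rh[i], wx$wind[i], wx$rain[i])
      d_pkg <- update_dmc(d_pkg, wx$temp[i], wx$rh[i], wx$rain[i], month)
      c_pkg <- update_dc(c_pkg, wx$temp[i], wx$rain[i], month)
      f_ref <- ref_ffmc(f_ref, wx$temp[i], wx$rh[i], wx$wind[i], wx$rain[i])
      d_ref <- ref_dmc(d_ref, wx$temp[i], wx$rh[i], wx$rain[i], month)
      c_ref <- ref_dc(c_ref, wx$temp[i], wx$rain[i], month)
      expect_equal(f_pkg, f_ref, tolerance = 1e-6)
      expect_equal(d_pkg, d_ref, tolerance = 1e-6)
      expect_equal(c_pkg, c_ref, tolerance = 1e-6)
      expect_equal(compute_bui(d_pkg, c_pkg), ref_bui(d_ref, c_ref),
                   tolerance = 1e-6)
    }
  }
})

test_that("BUI is zero at zero DMC and monotone in both codes", {
  expect_equal(compute_bui(0, 300), 0)
  expect_equal(compute_bui(0, 0), 0)
  dmc_grid <- seq(1, 300, by = 10)
  for (dc in c(20, 150, 600)) {
    b <- compute_bui(dmc_grid, dc)
    expect_true(all(diff(b) >= 0))
    expect_true(all(b >= 0))
  }
  for (dmc in c(5, 60, 200)) {
    b <- compute_bui(dmc, seq(0, 800, by = 25))
    expect_true(all(diff(b) >= -1e-12))
  }
  # direct formula spot checks
  expect_equal(compute_bui(60, 300), ref_bui(60, 300), tolerance = 1e-9)
  expect_equal(compute_bui(200, 100), ref_bui(200, 100), tolerance = 1e-9)
})

test_that("codes remain bounded for arbitrary admissible weather sequences", {
  for (seed in c(31, 32)) {
    wx <- random_weather(120, seed)
    f <- 85; d <- 6; cc <- 15
    for (i in seq_len(120)) {
      m <- (i - 1) %% 12 + 1
      f <- update_ffmc(f, wx$temp[i], wx$rh[i], wx$wind[i], wx$rain[i])
      d <- update_dmc(d, wx$temp[i], wx$rh[i], wx$rain[i], m)
      cc <- update_dc(cc, wx$temp[i], wx$rain[i], m)
      expect_true(f >= 0 && f <= 101)
      expect_true(d >= 0 && cc >= 0)
      expect_gte(compute_bui(d, cc), 0)
    }
  }
})
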