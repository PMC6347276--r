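test_that("CO2 multiplier hits its anchor points and is monotone", {
  expect_equal(co2_multiplier(350), 1.0)
  expect_equal(co2_multiplier(700), 1.25)
  expect_equal(co2_multiplier(280), 1 + 0.25 * log2(280 / 350),
               tolerance = 1e-12)
  conc <- seq(200, 1000, by = 5)
  m <- co2_multiplier(conc)
  expect_true(all(diff(m) > 0))
  expect_true(all(m[conc < 350] < 1))
  expect_true(all(m[conc > 350] > 1))
  expect_error(co2_multiplier(0), "positive")
  # disabled state: effect parameter exactly 1
  expect_equal(co2_multiplier(c(200, 900), co2_params(effect_param = 1)),
               c(1, 1))
})

test_that("potential evapotranspiration is zero when frozen and monotone in temperature", {
  expect_equal(pet_monthly(-5, 12, 30), 0)
  expect_equal(pet_monthly(0, 12, 30), 0)
  t_grid <- seq(1, 35, by = 1)
  p <- pet_monthly(t_grid, 12, 30)
  expect_true(all(diff(p) > 0))
  # hand evaluation of the Hamon-type formula at three sample inputs
  hamon <- function(t, dl, nd) 29.8 * (dl / 12) *
    (0.6108 * exp(17.27 * t / (t + 237.3))) / (t + 273.2) * nd
  expect_equal(pet_monthly(10, 12, 30), hamon(10, 12, 30))
  expect_equal(pet_monthly(20, 15, 31), hamon(20, 15, 31))
  expect_equal(pet_monthly(5, 9, 28), hamon(5, 9, 28))
})

test_that("the soil-water bucket caps at capacity and responds to the CO2 multiplier", {
  st <- soil_water_step(50, 0, 0, 100)
  expect_equal(st$soil_water, 50)
  expect_equal(st$aet, 0)
  expect_equal(soil_water_step(50, 1e4, 20, 100)$soil_water, 80)
  # reduced demand under a higher multiplier leaves weakly more water
  lo <- soil_water_step(60, 30, 80, 100, multiplier = 1)
  hi <- soil_water_step(60, 30, 80, 100, multiplier = 1.25)
  expect_gte(hi$soil_water, lo$soil_water)
  expect_error(soil_water_step(10, 0, 0, 0), "whc")
})

test_that("production is the product of its scalars", {
  expect_equal(compute_npp(1, 1, 1, 1300), 1300)
  expect_equal(compute_npp(0.5, 1, 1.25, 1300),
               1.25 * compute_npp(0.5, 1, 1, 1300))
  expect_equal(compute_npp(1, 0, 1.25, 1300), 0)
  expect_error(compute_npp(1.5, 1, 1, 1300), "scalars")
  # triangular temperature response
  expect_equal(npp_temp_scalar(18), 1)
  expect_equal(npp_temp_scalar(0), 0)
  expect_equal(npp_temp_scalar(38), 0)
  expect_equal(npp_temp_scalar(9), 0.5)
})

test_that("a zero-rate zero-production step is the identity", {
  cc <- vf_config()$carbon
  cc[c("k_leaf", "k_wood", "k_root", "k_standing_dead", "k_litter",
       "k_soil")] <- 0
  p <- carbon_pools(100, 200, 50, 80, 60, 500)
  st <- step_carbon(p, 0, 10, 0.5, cc)
  expect_equal(unclass(st$pools), unclass(p))
  expect_equal(unlist(st$fluxes), c(npp = 0, rh = 0, nep = 0, nbp = 0,
                                    consumed = 0))
  cc$k_leaf <- -0.1
  expect_error(step_carbon(p, 0, 10, 0.5, cc), "negative rate")
})

test_that("a closed no-fire run obeys the carbon ledger identity", {
  cc <- vf_config()$carbon
  set.seed(61)
  p <- steady_state_pools(1000, cc, 0.7)
  eco0 <- ecosystem_c(p)
  nep_sum <- 0
  for (y in 1:100) {
    st <- step_carbon(p, runif(1, 500, 1500), runif(1, 5, 15),
                      runif(1, 0.3, 1), cc)
    p <- st$pools
    nep_sum <- nep_sum + st$fluxes$nep
    expect_equal(st$fluxes$nep, st$fluxes$npp - st$fluxes$rh)
  }
  expect_equal((ecosystem_c(p) - eco0) / nep_sum, 1, tolerance = 1e-6)
})

test_that("constant forcing drives pools to the analytic steady state", {
  cc <- vf_config()$carbon
  npp <- 1200; tavg <- 10; moist <- 0.7
  g <- cc$q10^((tavg - cc$t_ref) / 10) * moist
  target <- steady_state_pools(npp, cc, g)
  p <- carbon_pools(10, 10, 10, 10, 10, 10)
  for (y in 1:1500) p <- step_carbon(p, npp, tavg, moist, cc)$pools
  for (nm in names(target)) {
    expect_equal(p[[nm]], target[[nm]], tolerance = 1e-4)
  }
})

test_that("raising the CO2 trajectory never decreases cumulative production", {
  cc <- vf_config()$carbon
  set.seed(62)
  for (rep in 1:5) {
    precip <- runif(12, 10, 150)
    temp <- runif(12, 0, 25)
    run_one <- function(mult) {
      sw <- 100; total <- 0
      for (y in 1:20) for (m in 1:12) {
        pet <- pet_monthly(temp[m], 12, 30)
        st <- soil_water_step(sw, precip[m], pet, 180, mult)
        sw <- st$soil_water
        ws <- if (st$demand > 0) st$aet / st$demand else 1
        total <- total + compute_npp(0.8, ws, mult, cc$npp_max) / 12
      }
      total
    }
    expect_gte(run_one(1.25), run_one(1.0))
    expect_gte(run_one(1.0), run_one(0.92))
  }
})
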