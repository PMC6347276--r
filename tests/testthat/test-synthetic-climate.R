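# a small grid keeps the generator tests fast; trend contrasts are driven
# by the regional noise, so they behave the same as at full grid size
small_cfg <- vf_config(grid = list(nx = 6, ny = 6))

test_that("identical seed and config give bitwise-identical forcing", {
  f1 <- gen_monthly_climate(small_cfg, seed = 7)
  f2 <- gen_monthly_climate(small_cfg, seed = 7)
  expect_identical(f1$tmax, f2$tmax)
  expect_identical(f1$precip, f2$precip)
  expect_identical(f1$rh, f2$rh)
  f3 <- gen_monthly_climate(small_cfg, seed = 8)
  expect_false(identical(f1$precip, f3$precip))
})

test_that("generated fields respect physical bounds across seeds", {
  cfg <- vf_config(grid = list(nx = 4, ny = 4), years = c(1990, 2009))
  for (s in 1:5) {
    f <- gen_monthly_climate(cfg, seed = s)
    expect_true(all(f$precip >= 0))
    expect_true(all(f$rh >= 0 & f$rh <= 100))
    expect_true(all(f$tmax >= f$tmin))
    expect_true(all(f$wind >= 0))
  }
})

test_that("seasonal cycle is wet-winter / dry-summer", {
  f <- gen_monthly_climate(small_cfg, seed = 2)
  winter <- apply(f$precip[c(1, 2, 12), , ], 1, mean)
  summer <- apply(f$precip[6:8, , ], 1, mean)
  expect_gt(min(winter), max(summer))
  # and warm summers
  expect_gt(mean(f$tmax[7, , ]), mean(f$tmax[1, , ]) + 10)
})

test_that("period-mean contrasts recover the configured trend targets", {
  tr <- climate_trend_summary(gen_monthly_climate(small_cfg, seed = 3))
  expect_equal(tr$tmax_delta_late21, 4.4, tolerance = 0.2 / 4.4)
  expect_equal(tr$tavg_summer_delta_late21, 4.8, tolerance = 0.2 / 4.8)
  # Apr-Sep precipitation in the mid 21st c. ~15% below the late 20th c.
  expect_equal(tr$precip_summer_ratio_mid21, 0.85, tolerance = 0.05 / 0.85)
  expect_equal(tr$precip_annual_ratio_20c, 1.04, tolerance = 0.05)
  expect_equal(tr$precip_annual_ratio_21c, 1.06, tolerance = 0.05)
})

test_that("invalid configurations raise configuration errors", {
  expect_error(vf_config(years = c(2000, 1990)), "year range")
  expect_error(vf_config(climate = list(temp_sd_regional = -1)),
               "negative variance")
  expect_error(vf_config(grid = list(nx = 0)), "grid dimensions")
})

test_that("constant CO2 mode holds every year at the preindustrial value", {
  co2 <- gen_co2_trajectory("constant", 1895:2100)
  expect_true(all(co2$ppm == 280))
})

test_that("rising CO2 is nondecreasing after 1950 and crosses 350 ppm late in the 20th century", {
  co2 <- gen_co2_trajectory("rising", 1895:2100)
  post1950 <- co2$ppm[co2$years >= 1950]
  expect_true(all(diff(post1950) >= 0))
  expect_lt(co2$ppm[co2$years == 1895], 350)
  expect_gt(co2$ppm[co2$years == 2100], 350)
  cross <- min(co2$years[co2$ppm > 350])
  expect_true(cross >= 1970 && cross <= 2000)
  expect_error(gen_co2_trajectory("sideways"), "unknown CO2 mode")
})

test_that("soil and NHA generators honor homogeneity, bounds, and grid checks", {
  cfg <- vf_config(grid = list(nx = 3, ny = 3),
                   soil = list(depth_lsd = 0), nha = list(fraction = 1))
  soil <- gen_soil_grid(cfg, seed = 1)
  expect_true(all(soil$depth == soil$depth[1]))
  expect_equal(soil$whc, soil$depth * cfg$soil$texture_fraction)
  expect_true(all(gen_nha_mask(cfg, seed = 1) == 1))

  het <- vf_config(grid = list(nx = 3, ny = 3),
                   soil = list(depth_lsd = 0.3), nha = list(sd = 0.4))
  expect_identical(gen_soil_grid(het, 5)$depth, gen_soil_grid(het, 5)$depth)
  expect_gt(stats::var(gen_soil_grid(het, 5)$depth), 0)
  m <- gen_nha_mask(het, seed = 2)
  expect_true(all(m >= 0 & m <= 1))

  f_big <- gen_monthly_climate(vf_config(grid = list(nx = 4, ny = 4),
                                         years = c(2000, 2001)), 1)
  expect_error(gen_soil_grid(cfg, 1, f_big), "do not match")
  expect_error(gen_nha_mask(cfg, 1, f_big), "do not match")
})

test_that("configurations round-trip through YAML", {
  cfg <- vf_config(grid = list(nx = 3, ny = 2))
  path <- withr::local_tempfile(fileext = ".yml")
  write_config(cfg, path)
  cfg2 <- read_config(path)
  expect_equal(cfg2$grid$nx, 3)
  expect_equal(cfg2$carbon$npp_max, cfg$carbon$npp_max)
  f1 <- gen_monthly_climate(cfg, 4)
  f2 <- gen_monthly_climate(cfg2, 4)
  expect_equal(f1$precip, f2$precip)
})
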