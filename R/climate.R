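#' Generate the synthetic monthly climate forcing
#'
#' Produces a seeded gridded monthly climate with maritime seasonality (wet
#' winters, dry summers), a flat 20th-century temperature history followed
#' by a late-century warming ramp, and piecewise-linear seasonal
#' precipitation trends. The trend ramps are derived from the configured
#' period-contrast targets, so the generated forcing recovers them in
#' expectation: by default the 2071-2100 mean annual maximum temperature is
#' 4.4 degrees C above 1971-2000, Apr-Sep mean temperature 4.8 degrees C
#' above, annual precipitation rises 4% across the 20th century and a
#' further 6% by the late 21st, while Apr-Sep precipitation falls 15%
#' between the late 20th and mid 21st century.
#'
#' @param config a [vf_config()] list.
#' @param seed integer master seed; the `climate` substream is derived from
#'   it, so identical seed and config give bitwise-identical output.
#' @return an object of class `vf_forcing`: a list with `years`, grid
#'   geometry (`nx`, `ny`, `ncell`, `cell_area_km2`, `cell_x`, `cell_y`),
#'   and arrays `tmax`, `tmin`, `precip`, `rh`, `wind` of dimension
#'   `c(12, n_years, ncell)` (degrees C, mm per month, percent, km/h).
#' @export
#' @examples
#' f <- gen_monthly_climate(vf_config(grid = list(nx = 2, ny = 2),
#'                                    years = c(1990, 1999)), seed = 1)
#' dim(f$precip)
gen_monthly_climate <- function(config = vf_config(), seed = 1L) {
  validate_config(config)
  cl <- config$climate
  g <- config$grid
  years <- seq(config$years[1], config$years[2])
  ny_yr <- length(years)
  ncell <- g$nx * g$ny

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(substream_seed(seed, "climate"))

  # static spatial structure
  cell_x <- rep(seq_len(g$nx), times = g$ny)
  cell_y <- rep(seq_len(g$ny), each = g$nx)
  t_off <- seq(g$temp_offset_range[1], g$temp_offset_range[2],
               length.out = max(g$ny, 2))[cell_y] +
    rnorm(ncell, 0, g$temp_cell_sd)
  p_fac <- seq(g$precip_factor_range[1], g$precip_factor_range[2],
               length.out = max(g$nx, 2))[cell_x] *
    exp(rnorm(ncell, 0, g$precip_cell_lsd) - g$precip_cell_lsd^2 / 2)

  # trend ramps derived from period-contrast targets
  ramp <- warming_ramp(years, cl)
  pfac <- precip_trend_factors(years, cl)   # list(summer, winter) per year

  summer <- month_in(4:9)

  # interannual anomalies: regional (shared) then cell-level
  t_reg <- matrix(rnorm(12 * ny_yr, 0, cl$temp_sd_regional), 12, ny_yr)
  p_reg <- matrix(rnorm(12 * ny_yr, 0, cl$precip_lsd_regional), 12, ny_yr)
  rh_reg <- matrix(rnorm(12 * ny_yr, 0, cl$rh_sd), 12, ny_yr)
  w_reg <- matrix(rnorm(12 * ny_yr, 0, cl$wind_sd), 12, ny_yr)
  t_cell <- array(rnorm(12 * ny_yr * ncell, 0, cl$temp_sd_cell),
                  c(12, ny_yr, ncell))
  p_cell <- array(rnorm(12 * ny_yr * ncell, 0, cl$precip_lsd_cell),
                  c(12, ny_yr, ncell))

  dims <- c(12, ny_yr, ncell)
  tmax <- array(cl$tmax_monthly, dims)
  tmax <- tmax + rep(ramp$tmax, each = 12) +            # warming (year-wise)
    as.vector(t_reg) + t_cell
  tmax <- tmax + rep(t_off, each = 12 * ny_yr)          # spatial offset

  dtr <- array(cl$dtr_monthly, dims)
  tmin_ramp_extra <- ramp$tmin - ramp$tmax              # tmin warms faster
  tmin <- tmax - pmax(dtr, 0.5) + rep(tmin_ramp_extra, each = 12)
  tmin <- pmin(tmin, tmax)                              # physical bound

  # precipitation: climatology x seasonal trend x mean-one lognormal noise
  lsd2 <- cl$precip_lsd_regional^2 + cl$precip_lsd_cell^2
  noise <- exp(as.vector(p_reg) + p_cell - lsd2 / 2)
  season_fac <- matrix(0, 12, ny_yr)
  season_fac[summer, ] <- rep(pfac$summer, each = sum(summer))
  season_fac[!summer, ] <- rep(pfac$winter, each = sum(!summer))
  precip <- array(cl$precip_monthly, dims) * as.vector(season_fac) * noise
  precip <- precip * rep(p_fac, each = 12 * ny_yr)
  precip[precip < 0] <- 0

  rh <- array(cl$rh_monthly, dims) +
    cl$rh_temp_coupling * (as.vector(t_reg) + t_cell) + as.vector(rh_reg)
  rh <- pmin(pmax(rh, 0), 100)

  wind <- array(cl$wind_monthly, dims) + as.vector(w_reg)
  wind <- pmax(wind, 0)

  structure(list(
    years = years, nx = g$nx, ny = g$ny, ncell = ncell,
    cell_area_km2 = rep(g$cell_area_km2, ncell),
    cell_x = cell_x, cell_y = cell_y,
    tmax = tmax, tmin = tmin, precip = precip, rh = rh, wind = wind,
    config = config, seed = seed
  ), class = "vf_forcing")
}

month_in <- function(months) seq_len(12) %in% months

restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

# Linear post-2010 warming ramps whose 2071-2100 means hit the configured
# late-century contrasts (the 1971-2000 reference lies on the flat segment).
warming_ramp <- function(years, cl) {
  late21 <- 2071:2100
  span <- 2100 - cl$warming_start + 1
  mean_frac <- mean(pmax(late21 - cl$warming_start + 1, 0)) / span
  amp_tmax <- cl$tmax_delta_late21 / mean_frac
  amp_tavg <- cl$tavg_summer_delta_late21 / mean_frac
  amp_tmin <- 2 * amp_tavg - amp_tmax
  frac <- pmax(years - cl$warming_start + 1, 0) / span
  list(tmax = amp_tmax * frac, tmin = amp_tmin * frac)
}

# Piecewise-linear seasonal precipitation factors (Apr-Sep vs Oct-Mar),
# anchored so period means match the configured contrasts. Winter anchors
# are solved from the annual targets given the climatological seasonal split.
precip_trend_factors <- function(years, cl) {
  fs <- sum(cl$precip_monthly[4:9]) / sum(cl$precip_monthly)
  fw <- 1 - fs
  s1 <- 1 + cl$precip_summer_change_20c
  s2 <- s1 * (1 + cl$precip_summer_change_21c)
  a1 <- 1 + cl$precip_annual_change_20c
  a2 <- a1 * (1 + cl$precip_annual_change_21c)
  w1 <- (a1 - fs * s1) / fw
  w2 <- (a2 - fs * s2) / fw
  anchors <- c(1895, 1924, 1971, 2000, 2036, 2100)
  s_anch <- c(1, 1, s1, s1, s2, s2)
  w_anch <- c(1, 1, w1, w1, w2, w2)
  list(
    summer = approx(anchors, s_anch, xout = years, rule = 2)$y,
    winter = approx(anchors, w_anch, xout = years, rule = 2)$y
  )
}

#' Summarize generated climate trends against their targets
#'
#' Computes the period-contrast diagnostics the generator is calibrated to:
#' late-21st minus late-20th century mean annual maximum temperature and
#' Apr-Sep mean temperature, annual and Apr-Sep precipitation ratios
#' between analysis periods.
#'
#' @param forcing a `vf_forcing`.
#' @return a named list of contrasts.
#' @export
climate_trend_summary <- function(forcing) {
  yr <- forcing$years
  idx <- function(a, b) which(yr >= a & yr <= b)
  summer <- month_in(4:9)
  ann_tmax <- apply(forcing$tmax, 2, mean)
  tavg <- (forcing$tmax + forcing$tmin) / 2
  sum_tavg <- apply(tavg[summer, , , drop = FALSE], 2, mean)
  ann_pr <- apply(forcing$precip, 2, mean) * 12
  sum_pr <- apply(forcing$precip[summer, , , drop = FALSE], 2, mean) * 6
  pm <- function(x, a, b) mean(x[idx(a, b)])
  list(
    tmax_delta_late21 = pm(ann_tmax, 2071, 2100) - pm(ann_tmax, 1971, 2000),
    tavg_summer_delta_late21 = pm(sum_tavg, 2071, 2100) - pm(sum_tavg, 1971, 2000),
    precip_annual_ratio_20c = pm(ann_pr, 1971, 2000) / pm(ann_pr, 1895, 1924),
    precip_annual_ratio_21c = pm(ann_pr, 2071, 2100) / pm(ann_pr, 1971, 2000),
    precip_summer_ratio_mid21 = pm(sum_pr, 2036, 2065) / pm(sum_pr, 1971, 2000),
    mc_tolerance = list(temp_c = 0.2, precip_ratio = 0.05)
  )
}

days_in_month <- function() c(31, 28, 31, 30, 31, 30, 31, 31, 30, 31, 30, 31)

#' Generate a CO2 concentration trajectory
#'
#' In `"rising"` mode, piecewise-linear interpolation of an embedded table
#' approximating the observed historical record joined to an RCP 8.5-like
#' concentration pathway (reaching ~936 ppm in 2100). In `"constant"` mode
#' every year is held at the preindustrial value (280 ppm by default).
#'
#' @param mode `"rising"` or `"constant"`.
#' @param years integer vector of simulation years.
#' @param config a [vf_config()]; `config$co2$table` (data frame with
#'   columns `year`, `ppm`) overrides the built-in table.
#' @param seed unused (the trajectory is deterministic); kept for interface
#'   symmetry with the other generators.
#' @return an object of class `vf_co2`: list with `years`, `ppm`, `mode`.
#' @export
gen_co2_trajectory <- function(mode = c("rising", "constant"),
                               years = 1895:2100,
                               config = vf_config(), seed = NULL) {
  if (!is.character(mode) || !mode[1] %in% c("rising", "constant"))
    stop("configuration error: unknown CO2 mode")
  mode <- match.arg(mode)
  if (mode == "constant") {
    ppm <- rep(config$co2$preindustrial_ppm, length(years))
  } else {
    tab <- config$co2$table
    if (is.null(tab)) tab <- co2_default_table()
    ppm <- approx(tab$year, tab$ppm, xout = years, rule = 2)$y
  }
  structure(list(years = years, ppm = ppm, mode = mode), class = "vf_co2")
}

#' Built-in CO2 concentration table
#'
#' Historical concentrations to 2010 joined to an RCP 8.5-like pathway
#' thereafter; used by [gen_co2_trajectory()] under `"rising"` mode and
#' overridable via `config$co2$table`.
#'
#' @return data frame with columns `year` and `ppm`.
#' @export
co2_default_table <- function() {
  data.frame(
    year = c(1895, 1900, 1910, 1920, 1930, 1940, 1950, 1960, 1970, 1980,
             1990, 2000, 2010, 2020, 2030, 2040, 2050, 2060, 2070, 2080,
             2090, 2100),
    ppm = c(294, 296, 298, 303, 307, 311, 311, 317, 325, 339,
            354, 369, 390, 416, 449, 489, 541, 611, 677, 758,
            845, 936)
  )
}

#' Generate soil depth and water-holding capacity
#'
#' @param config a [vf_config()]; `soil$depth_lsd = 0` gives a homogeneous
#'   grid, otherwise depths are lognormal around `depth_mean_mm`.
#'   Plant-available water-holding capacity is `depth * texture_fraction`.
#' @param seed master seed (soil substream).
#' @param forcing optional `vf_forcing` whose grid must match the config.
#' @return list of class `vf_soil` with `depth` and `whc` (mm) per cell.
#' @export
gen_soil_grid <- function(config = vf_config(), seed = 1L, forcing = NULL) {
  ncell <- config$grid$nx * config$grid$ny
  if (!is.null(forcing) && forcing$ncell != ncell)
    stop("configuration error: soil grid dimensions do not match climate grid")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(substream_seed(seed, "soil"))
  s <- config$soil
  depth <- if (s$depth_lsd > 0) {
    s$depth_mean_mm * exp(rnorm(ncell, 0, s$depth_lsd) - s$depth_lsd^2 / 2)
  } else rep(s$depth_mean_mm, ncell)
  depth <- pmax(depth, 1)
  structure(list(depth = depth, whc = depth * s$texture_fraction),
            class = "vf_soil")
}

#' Generate a non-human-affected (NHA) area-fraction mask
#'
#' @param config a [vf_config()]; `nha$fraction` is the mean fraction and
#'   `nha$sd > 0` adds seeded cell-level heterogeneity (clamped to `[0,1]`).
#' @param seed master seed (nha substream).
#' @param forcing optional `vf_forcing` for a grid-dimension check.
#' @return numeric vector of per-cell NHA fractions in `[0, 1]`.
#' @export
gen_nha_mask <- function(config = vf_config(), seed = 1L, forcing = NULL) {
  ncell <- config$grid$nx * config$grid$ny
  if (!is.null(forcing) && forcing$ncell != ncell)
    stop("configuration error: mask dimensions do not match climate grid")
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)
  set.seed(substream_seed(seed, "nha"))
  f <- rep(config$nha$fraction, length.out = ncell)
  if (config$nha$sd > 0) f <- f + rnorm(ncell, 0, config$nha$sd)
  pmin(pmax(f, 0), 1)
}
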