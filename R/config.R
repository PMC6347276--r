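#' Default simulation configuration
#'
#' Builds the nested configuration list that drives every module: grid
#' geometry, synthetic-climate climatology and trend targets, CO2 trajectory
#' settings, fire-weather and ignition parameters, vegetation type table,
#' and the carbon-surrogate rate constants. All values can be overridden by
#' passing replacement elements, or via a YAML file ([read_config()]).
#'
#' Trend targets are expressed as the period contrasts they must produce
#' (e.g. `tmax_delta_late21 = 4.4` degrees C between the 1971-2000 and
#' 2071-2100 mean annual maximum temperature); the generator derives the
#' underlying linear ramps from them, so the configured numbers are directly
#' the quantities recovered by [climate_trend_summary()].
#'
#' @param ... named elements to override, nested lists are merged
#'   recursively (e.g. `climate = list(temp_sd_regional = 0)`).
#' @return a list of class `vf_config`.
#' @export
#' @examples
#' cfg <- vf_config(grid = list(nx = 4, ny = 4))
#' cfg$grid$nx
vf_config <- function(...) {
  cfg <- list(
    grid = list(
      nx = 20, ny = 20,
      cell_area_km2 = 16,
      # static spatial structure: north-south temperature gradient and
      # west-east precipitation gradient, plus seeded cell-level texture
      temp_offset_range = c(1.5, -1.5),     # degrees C, row 1 -> row ny
      precip_factor_range = c(0.70, 1.40),  # multiplicative, col 1 -> col nx
      temp_cell_sd = 0.3,
      precip_cell_lsd = 0.10
    ),
    years = c(1895L, 2100L),
    climate = list(
      # monthly climatology (Jan..Dec) of a maritime wet-winter/dry-summer
      # regime: noon maximum temperature, diurnal range, precipitation,
      # noon relative humidity, wind, wet-day probability
      tmax_monthly   = c(7, 9, 12, 15, 19, 22, 26, 26, 23, 16, 10, 7),
      dtr_monthly    = c(6, 6, 7, 8, 9, 10, 12, 12, 10, 8, 6, 6),
      precip_monthly = c(220, 180, 160, 90, 70, 45, 15, 20, 45, 120, 230, 240),
      rh_monthly     = c(85, 80, 72, 65, 60, 55, 45, 45, 52, 68, 83, 87),
      wind_monthly   = c(12, 12, 12, 11, 10, 10, 9, 9, 9, 10, 12, 12),
      wet_day_prob   = c(0.60, 0.55, 0.55, 0.45, 0.35, 0.30,
                         0.12, 0.12, 0.25, 0.40, 0.60, 0.62),
      # interannual noise: regional (shared across cells) and cell-level
      temp_sd_regional = 0.8,
      temp_sd_cell = 0.3,
      precip_lsd_regional = 0.25,
      precip_lsd_cell = 0.30,
      rh_sd = 5,
      rh_temp_coupling = -3,   # % RH per degree C of temperature anomaly
      wind_sd = 1.5,
      # trend targets (period contrasts the generated forcing must show)
      warming_start = 2011,
      tmax_delta_late21 = 4.4,        # late-21st minus late-20th mean annual tmax
      tavg_summer_delta_late21 = 4.8, # same contrast for Apr-Sep mean temperature
      precip_annual_change_20c = 0.04,   # early-20th -> late-20th
      precip_annual_change_21c = 0.06,   # late-20th -> late-21st
      precip_summer_change_20c = 0.06,   # early-20th -> late-20th, Apr-Sep
      precip_summer_change_21c = -0.15   # late-20th -> mid/late-21st, Apr-Sep
    ),
    co2 = list(
      mode = "rising",
      preindustrial_ppm = 280,
      table = NULL                # NULL -> built-in trajectory table
    ),
    soil = list(
      depth_mean_mm = 1200,
      depth_lsd = 0.25,           # lognormal spatial spread; 0 -> uniform
      texture_fraction = 0.15     # plant-available water per mm of depth
    ),
    nha = list(
      fraction = 1,               # scalar -> homogeneous mask
      sd = 0                      # >0 -> seeded heterogeneous mask in [0,1]
    ),
    fire = list(
      season_months = 4:10,
      start_ffmc = 85, start_dmc = 6, start_dc = 15,
      p_ignition_source = 0.001,
      threshold_fraction = 0.6,
      ffmc_min_frac = 0.6,
      ffmc_max_frac = 0.99,
      suppression_factor = 1.03
    ),
    veg = default_veg_params(),
    veg_class = list(
      # warmth index = exponentially smoothed Apr-Sep mean temperature;
      # boundaries calibrated against the default synthetic climate (see
      # methods vignette): conifer below t1, temperate mixed [t1, t2),
      # subtropical mixed at/above t2
      warmth_t1 = 20.20,
      warmth_t2 = 21.20,
      forest_wood_c_min = 500,    # g C m-2 live wood; below -> "other"
      gdd_forest_min = 500,       # degree-days base 5; below -> "other"
      smoothing_efold_yr = 15
    ),
    carbon = list(
      npp_max = 1300,             # g C m-2 yr-1 at unit scalars
      temp_opt = 18, temp_lo = 0, temp_hi = 38,  # Apr-Sep mean temperature
      alloc = c(leaf = 0.3, wood = 0.5, root = 0.2),
      k_leaf = 0.25, k_wood = 0.03, k_root = 0.12,  # live turnover, yr-1
      k_standing_dead = 0.08, k_litter = 0.12, k_soil = 0.012,
      f_sd_to_litter = 0.5,       # humification fractions, rest respired
      f_litter_to_soil = 0.3,
      q10 = 2, t_ref = 10,        # decomposition temperature response
      consumption = list(
        leaf = 0.9, litter = 0.7, standing_dead = 0.5,
        wood_kill = 0.15, wood_kill_consumed = 0.1
      ),
      tsf_init = 10
    ),
    spinup_years = 50
  )
  cfg <- merge_config(cfg, list(...))
  # YAML round-trips drop names on plain numeric vectors
  cfg$carbon$alloc <- stats::setNames(unlist(cfg$carbon$alloc),
                                      c("leaf", "wood", "root"))
  validate_config(cfg)
  class(cfg) <- c("vf_config", "list")
  cfg
}

# recursive merge: replacement wins, lists merge element-wise
merge_config <- function(base, repl) {
  for (nm in names(repl)) {
    if (is.list(repl[[nm]]) && is.list(base[[nm]]) && !is.null(names(repl[[nm]]))) {
      base[[nm]] <- merge_config(base[[nm]], repl[[nm]])
    } else {
      base[[nm]] <- repl[[nm]]
    }
  }
  base
}

validate_config <- function(cfg) {
  g <- cfg$grid
  if (g$nx < 1 || g$ny < 1)
    stop("configuration error: grid dimensions must be at least 1x1")
  y <- cfg$years
  if (length(y) != 2 || y[1] > y[2])
    stop("configuration error: invalid year range")
  cl <- cfg$climate
  for (nm in c("temp_sd_regional", "temp_sd_cell", "precip_lsd_regional",
               "precip_lsd_cell", "rh_sd", "wind_sd")) {
    if (cl[[nm]] < 0)
      stop("configuration error: negative variance parameter ", nm)
  }
  if (any(cl$precip_monthly < 0))
    stop("configuration error: negative climatological precipitation")
  if (any(cl$wet_day_prob <= 0 | cl$wet_day_prob > 1))
    stop("configuration error: wet_day_prob must be in (0, 1]")
  fi <- cfg$fire
  if (fi$p_ignition_source < 0 || fi$p_ignition_source > 1)
    stop("configuration error: p_ignition_source must be in [0, 1]")
  if (fi$ffmc_min_frac >= fi$ffmc_max_frac)
    stop("configuration error: ffmc_min_frac must be below ffmc_max_frac")
  invisible(cfg)
}

#' Read / write a configuration as YAML
#'
#' @param path file path.
#' @param cfg a `vf_config` list.
#' @return `read_config()` returns a `vf_config`; `write_config()` the path,
#'   invisibly.
#' @export
read_config <- function(path) {
  do.call(vf_config, yaml::read_yaml(path))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' Derive a reproducible substream seed
#'
#' Named random-number substreams (climate, precipitation disaggregation,
#' ignition stages) are derived deterministically from the master seed so
#' that toggling one stochastic mechanism does not perturb another's draws,
#' and so that all scenarios of a factorial share identical climate and
#' ignition-exposure draws (common random numbers).
#'
#' @param seed master integer seed.
#' @param stream one of `"climate"`, `"precip_disagg"`, `"ignition_stage1"`,
#'   `"ignition_stage3"`, `"soil"`, `"nha"`.
#' @return an integer seed below 2^31.
#' @export
substream_seed <- function(seed, stream) {
  codes <- c(climate = 1, precip_disagg = 2, ignition_stage1 = 3,
             ignition_stage3 = 4, soil = 5, nha = 6)
  stream <- match.arg(stream, names(codes))
  as.integer((abs(as.numeric(seed)) %% 1e6) * 2039 + codes[[stream]] * 7919) %% 2147483647L
}

#' The five 30-year analysis periods
#'
#' @return a data frame with columns `label`, `start`, `end`.
#' @export
analysis_periods <- function() {
  data.frame(
    label = c("1895-1924", "1936-1965", "1971-2000", "2036-2065", "2071-2100"),
    start = c(1895L, 1936L, 1971L, 2036L, 2071L),
    end   = c(1924L, 1965L, 2000L, 2065L, 2100L),
    stringsAsFactors = FALSE
  )
}
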