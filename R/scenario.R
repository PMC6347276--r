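#' Scenario definitions
#'
#' The factorial crosses four fire modes (FF unlimited ignitions, FS
#' unlimited with suppression, SF three-stage stochastic, NF no fire) with
#' two CO2 modes (WCE rising trajectory, NCE constant preindustrial). The
#' six modeled combinations are FF-WCE, FS-WCE, SF-WCE, NF-WCE, FF-NCE,
#' NF-NCE (FS-NCE and SF-NCE are not modeled by default).
#'
#' @param name scenario name like `"FF-WCE"`, or pass `fire_mode` /
#'   `co2_mode` explicitly.
#' @param fire_mode one of `"FF"`, `"FS"`, `"SF"`, `"NF"`.
#' @param co2_mode one of `"WCE"`, `"NCE"`.
#' @return list of class `vf_scenario` with `name`, `fire_mode`,
#'   `co2_mode`.
#' @export
scenario_config <- function(name = NULL, fire_mode = NULL, co2_mode = NULL) {
  if (!is.null(name)) {
    parts <- strsplit(name, "-", fixed = TRUE)[[1]]
    if (length(parts) != 2) stop("unknown scenario name: ", name)
    fire_mode <- parts[1]; co2_mode <- parts[2]
  }
  if (!fire_mode %in% c("FF", "FS", "SF", "NF"))
    stop("unknown fire mode: ", fire_mode)
  if (!co2_mode %in% c("WCE", "NCE"))
    stop("unknown CO2 mode: ", co2_mode)
  structure(list(name = paste(fire_mode, co2_mode, sep = "-"),
                 fire_mode = fire_mode, co2_mode = co2_mode),
            class = "vf_scenario")
}

#' @rdname scenario_config
#' @export
default_scenarios <- function() {
  c("FF-WCE", "FS-WCE", "SF-WCE", "NF-WCE", "FF-NCE", "NF-NCE")
}

#' Run one scenario
#'
#' Annual loop per cell over the simulation window: vegetation
#' classification from the smoothed climate summary, fire occurrence from
#' the precomputed fire calendar (for the scenario's fire mode), fire
#' effects (burned fraction limited by FRI and time since fire,
#' consumption and mortality), monthly soil-water bucket, production with
#' temperature/water/CO2 scalars, and the annual carbon-pool step. A
#' 50-year spin-up cycling the first 30 years of (detrended early-period)
#' climate equilibrates the pools before reporting starts; the spin-up is
#' fire-free and excluded from outputs.
#'
#' @param scenario a scenario name or [scenario_config()].
#' @param forcing a `vf_forcing` from [gen_monthly_climate()].
#' @param soil a `vf_soil` from [gen_soil_grid()].
#' @param config a [vf_config()]; defaults to the forcing's.
#' @param seed master seed (must match the forcing/calendar seed for
#'   common random numbers across scenarios).
#' @param calendar optional precomputed [build_fire_calendar()] (shared
#'   across scenarios by [run_matrix()]); built on demand for fire modes.
#' @param clim_sum optional precomputed [summarize_climate()].
#' @return an object of class `vf_run`: list with `annual` (data frame of
#'   study-area series: fire metrics in percent, fluxes and pools in
#'   g C m-2 (yr-1)), `veg` and `frac_burned` matrices `[n_years x ncell]`,
#'   per-cell `live_c`/`dead_c` matrices, `final_pools`, and a `manifest`.
#' @export
run_scenario <- function(scenario, forcing, soil = NULL,
                         config = forcing$config, seed = 1L,
                         calendar = NULL, clim_sum = NULL) {
  if (is.character(scenario)) scenario <- scenario_config(scenario)
  years <- forcing$years
  n_yr <- length(years)
  ncell <- forcing$ncell
  areas <- forcing$cell_area_km2
  if (is.null(soil)) soil <- gen_soil_grid(config, seed, forcing)
  if (length(soil$whc) != ncell)
    stop("configuration error: soil grid does not match forcing grid")

  params <- do.call(ignition_params, config$fire[
    c("p_ignition_source", "threshold_fraction", "ffmc_min_frac",
      "ffmc_max_frac", "suppression_factor")])
  veg_tab <- config$veg
  needs_fire <- scenario$fire_mode != "NF"
  if (needs_fire && is.null(calendar)) {
    calendar <- build_fire_calendar(forcing, params, veg_tab[1, ], seed,
                                    config)
  }
  if (is.null(clim_sum)) {
    clim_sum <- summarize_climate(forcing, config$veg_class$smoothing_efold_yr)
  }

  co2 <- gen_co2_trajectory(if (scenario$co2_mode == "WCE") "rising"
                            else "constant",
                            years, config)
  mult <- co2_multiplier(co2$ppm, co2_params())

  mdays <- days_in_month()
  cc <- config$carbon
  whc <- soil$whc

  # per-year per-cell drivers
  annual_drivers <- function(y, multiplier) {
    tavg_m <- matrix((forcing$tmax[, y, ] + forcing$tmin[, y, ]) / 2,
                     12, ncell)
    pr_m <- matrix(forcing$precip[, y, ], 12, ncell)
    sw <- driver_state$soil_water
    aet_tot <- dem_tot <- numeric(ncell)
    for (m in 1:12) {
      pet <- pet_monthly(tavg_m[m, ], daylength_hours[m], mdays[m])
      st <- soil_water_step(sw, pr_m[m, ], pet, whc, multiplier)
      sw <- st$soil_water
      aet_tot <- aet_tot + st$aet
      dem_tot <- dem_tot + st$demand
    }
    driver_state$soil_water <<- sw
    water <- ifelse(dem_tot > 0, aet_tot / dem_tot, 1)
    list(water = pmin(water, 1), tavg = colMeans(tavg_m))
  }
  driver_state <- new.env()
  driver_state$soil_water <- whc

  temp_sc <- function(y) {
    npp_temp_scalar(clim_sum$summer_tavg[y, ], cc$temp_opt, cc$temp_lo,
                    cc$temp_hi)
  }

  # spin-up: initialize at analytic steady state, then cycle early climate
  d1 <- annual_drivers(1, mult[1])
  g0 <- cc$q10^((d1$tavg - cc$t_ref) / 10) * d1$water
  npp0 <- compute_npp(temp_sc(1), d1$water, mult[1], cc$npp_max)
  pools <- steady_state_pools(npp0, cc, pmax(g0, 0.05))
  n_cycle <- min(30, n_yr)
  for (s in seq_len(config$spinup_years)) {
    y <- (s - 1) %% n_cycle + 1
    d <- annual_drivers(y, mult[1])
    npp <- compute_npp(temp_sc(y), d$water, mult[1], cc$npp_max)
    pools <- step_carbon(pools, npp, d$tavg, d$water, cc)$pools
  }

  tsf <- rep(cc$tsf_init, ncell)
  veg_id <- matrix(NA_integer_, n_yr, ncell)
  frac_burned <- matrix(0, n_yr, ncell)
  live_m <- dead_m <- matrix(NA_real_, n_yr, ncell)
  cols <- c("npp", "rh", "nep", "nbp", "consumed", "live_c", "dead_c",
            "ecosystem_c", "leaf_c", "wood_c", "root_c", "standing_dead_c",
            "litter_c", "soil_c")
  ann <- matrix(NA_real_, n_yr, length(cols), dimnames = list(NULL, cols))
  wmean <- function(x) sum(x * areas) / sum(areas)

  for (y in seq_len(n_yr)) {
    veg_id[y, ] <- classify_veg(clim_sum$warmth[y, ], clim_sum$gdd[y, ],
                                pools$live_wood_above_c, config$veg_class)
    consumed <- numeric(ncell)
    if (needs_fire) {
      cal <- calendar[[scenario$fire_mode]]
      fire <- cal$fire[y, ]
      if (any(fire)) {
        fri <- veg_tab$fri[veg_id[y, ]]
        frac <- ifelse(fire, max_burn_fraction(tsf, fri), 0)
        sev <- ifelse(fire, cal$severity[y, ], 0)
        fk <- consume_and_kill(pools, frac, sev, cc$consumption)
        pools <- fk$pools
        consumed <- fk$event$consumed_c
        frac_burned[y, ] <- frac
      }
      tsf <- ifelse(fire, 0, tsf) + 1
    }
    d <- annual_drivers(y, mult[y])
    npp <- compute_npp(temp_sc(y), d$water, mult[y], cc$npp_max)
    st <- step_carbon(pools, npp, d$tavg, d$water, cc, consumed)
    pools <- st$pools
    live_m[y, ] <- live_c(pools)
    dead_m[y, ] <- dead_c(pools)
    ann[y, ] <- c(wmean(st$fluxes$npp), wmean(st$fluxes$rh),
                  wmean(st$fluxes$nep), wmean(st$fluxes$nbp),
                  wmean(consumed), wmean(live_m[y, ]), wmean(dead_m[y, ]),
                  wmean(live_m[y, ] + dead_m[y, ]),
                  wmean(pools$leaf_c), wmean(pools$live_wood_above_c),
                  wmean(pools$live_root_c), wmean(pools$standing_dead_c),
                  wmean(pools$litter_c), wmean(pools$soil_c))
  }

  fm <- fire_metrics(frac_burned, areas, years)
  annual <- cbind(data.frame(scenario = scenario$name), fm,
                  as.data.frame(ann))
  manifest <- list(scenario = scenario$name, seed = seed,
                   years = range(years), grid = c(forcing$nx, forcing$ny),
                   package = as.character(utils::packageVersion("vegfire")))
  structure(list(annual = annual, veg = veg_id, frac_burned = frac_burned,
                 live_c = live_m, dead_c = dead_m, final_pools = pools,
                 scenario = scenario, years = years, cell_areas = areas,
                 manifest = manifest),
            class = "vf_run")
}

#' Run the scenario factorial
#'
#' Generates the shared forcing, soil, fire calendar, and climate summary
#' once from the master seed, then runs every requested scenario against
#' them, so that climate and ignition-exposure draws are identical across
#' scenarios (common random numbers) and differences are attributable to
#' the fire/CO2 switches alone.
#'
#' @param config a [vf_config()].
#' @param seed master seed.
#' @param scenarios character vector of scenario names
#'   ([default_scenarios()] by default).
#' @return an object of class `vf_matrix`: list with `runs` (named list of
#'   `vf_run`), `annual` (combined data frame), `period_tables` (fire
#'   metrics, fluxes, pools, vegetation distribution per period x
#'   scenario), and the shared `forcing`, `soil`, `calendar`.
#' @export
run_matrix <- function(config = vf_config(), seed = 1L,
                       scenarios = default_scenarios()) {
  if (length(scenarios) < 1) stop("at least one scenario is required")
  scens <- lapply(scenarios, scenario_config)   # errors early on bad names
  forcing <- gen_monthly_climate(config, seed)
  soil <- gen_soil_grid(config, seed, forcing)
  params <- do.call(ignition_params, config$fire[
    c("p_ignition_source", "threshold_fraction", "ffmc_min_frac",
      "ffmc_max_frac", "suppression_factor")])
  needs_fire <- any(vapply(scens, function(s) s$fire_mode != "NF",
                           logical(1)))
  calendar <- if (needs_fire) {
    build_fire_calendar(forcing, params, config$veg[1, ], seed, config)
  }
  clim_sum <- summarize_climate(forcing, config$veg_class$smoothing_efold_yr)

  runs <- lapply(scens, function(s) {
    run_scenario(s, forcing, soil, config, seed, calendar, clim_sum)
  })
  names(runs) <- vapply(scens, `[[`, character(1), "name")

  annual <- do.call(rbind, lapply(runs, `[[`, "annual"))
  rownames(annual) <- NULL
  structure(list(runs = runs, annual = annual,
                 period_tables = matrix_period_tables(runs),
                 forcing = forcing, soil = soil, calendar = calendar,
                 seed = seed, config = config),
            class = "vf_matrix")
}

# cross-scenario period tables (fire, fluxes, pools, vegetation), limited
# to the analysis periods the simulation window covers
matrix_period_tables <- function(runs) {
  periods <- analysis_periods()
  yrs <- runs[[1]]$years
  periods <- periods[periods$start >= min(yrs) & periods$end <= max(yrs), ]
  if (nrow(periods) == 0) {
    periods <- data.frame(label = paste0(min(yrs), "-", max(yrs)),
                          start = min(yrs), end = max(yrs))
  }
  per <- function(run, vars) {
    ps <- period_summary(run$annual, vars, periods)
    cbind(data.frame(scenario = run$scenario$name), ps)
  }
  fire <- do.call(rbind, lapply(runs, per, c("awf", "fab", "tab")))
  flux <- do.call(rbind, lapply(runs, per,
                                c("npp", "nep", "nbp", "consumed")))
  pool <- do.call(rbind, lapply(runs, per,
                                c("live_c", "dead_c", "ecosystem_c")))
  veg <- do.call(rbind, lapply(runs, function(run) {
    do.call(rbind, lapply(seq_len(nrow(periods)), function(i) {
      ids <- period_mode(run$veg, run$years,
                         c(periods$start[i], periods$end[i]))
      pct <- category_distribution(ids, run$cell_areas)
      data.frame(scenario = run$scenario$name, period = periods$label[i],
                 category = names(pct), percent = unname(pct))
    }))
  }))
  rownames(fire) <- rownames(flux) <- rownames(pool) <- rownames(veg) <- NULL
  list(fire = fire, fluxes = flux, pools = pool, vegetation = veg)
}

#' Write factorial outputs to CSV (+ JSON manifest)
#'
#' Writes the combined annual series, the four cross-scenario period
#' tables, and a JSON run manifest into a directory.
#'
#' @param mat a `vf_matrix` from [run_matrix()].
#' @param dir output directory (created if missing).
#' @return the directory, invisibly.
#' @export
write_outputs <- function(mat, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(mat$annual, file.path(dir, "annual.csv"),
                   row.names = FALSE)
  for (nm in names(mat$period_tables)) {
    utils::write.csv(mat$period_tables[[nm]],
                     file.path(dir, paste0("periods_", nm, ".csv")),
                     row.names = FALSE)
  }
  manifest <- list(seed = mat$seed,
                   scenarios = names(mat$runs),
                   years = range(mat$forcing$years),
                   grid = c(nx = mat$forcing$nx, ny = mat$forcing$ny),
                   package = as.character(utils::packageVersion("vegfire")))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Optional NetCDF export of a forcing
#'
#' Writes the monthly climate arrays to a CF-style NetCDF file
#' (dimensions time, y, x). Requires the `ncdf4` package; CSV output
#' ([write_outputs()]) is the primary interface.
#'
#' @param forcing a `vf_forcing`.
#' @param path output file path.
#' @return the path, invisibly.
#' @export
write_forcing_netcdf <- function(forcing, path) {
  if (!requireNamespace("ncdf4", quietly = TRUE))
    stop("the ncdf4 package is required for NetCDF export")
  n_time <- 12 * length(forcing$years)
  dim_t <- ncdf4::ncdim_def("time", "months since start", seq_len(n_time) - 1)
  dim_x <- ncdf4::ncdim_def("x", "cell", seq_len(forcing$nx))
  dim_y <- ncdf4::ncdim_def("y", "cell", seq_len(forcing$ny))
  dims <- list(dim_x, dim_y, dim_t)
  vars <- list(
    tmax = ncdf4::ncvar_def("tmax", "degC", dims),
    tmin = ncdf4::ncvar_def("tmin", "degC", dims),
    precip = ncdf4::ncvar_def("precip", "mm", dims),
    rh = ncdf4::ncvar_def("rh", "percent", dims),
    wind = ncdf4::ncvar_def("wind", "km h-1", dims)
  )
  nc <- ncdf4::nc_create(path, vars)
  on.exit(ncdf4::nc_close(nc))
  for (nm in names(vars)) {
    a <- forcing[[nm]]                       # [12, nyr, ncell]
    arr <- aperm(array(aperm(a, c(3, 1, 2)),
                       c(forcing$nx, forcing$ny, n_time)), c(1, 2, 3))
    ncdf4::ncvar_put(nc, vars[[nm]], arr)
  }
  invisible(path)
}
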