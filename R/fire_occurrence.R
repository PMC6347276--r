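#' Ignition and threshold parameters
#'
#' Bundles the parameters of the three fire-occurrence algorithms. The
#' Chapman-Richards constant `k` is always derived from the minimum and
#' maximum FFMC threshold fractions via [chapman_k()], never set directly.
#' Defaults: daily ignition source probability
#' 0.001, stage-two threshold fraction 0.6, FFMC fractions 0.6 and 0.99.
#'
#' @param p_ignition_source per cell-day probability of ignition-source
#'   exposure, in `[0, 1]`.
#' @param threshold_fraction fraction of the FFMC and BUI thresholds that
#'   fuel conditions must exceed at stage two of the stochastic algorithm.
#' @param ffmc_min_frac FFMC threshold fraction at/below which the
#'   initiation probability is zero.
#' @param ffmc_max_frac FFMC threshold fraction where it approaches one.
#' @param suppression_factor multiplier (`> 1`) applied to both thresholds
#'   under the suppression mode.
#' @return list of class `vf_ignition_params` including the derived `k`.
#' @export
ignition_params <- function(p_ignition_source = 0.001,
                            threshold_fraction = 0.6,
                            ffmc_min_frac = 0.6,
                            ffmc_max_frac = 0.99,
                            suppression_factor = 1.03) {
  if (p_ignition_source < 0 || p_ignition_source > 1)
    stop("p_ignition_source must be in [0, 1]")
  structure(list(
    p_ignition_source = p_ignition_source,
    threshold_fraction = threshold_fraction,
    ffmc_min_frac = ffmc_min_frac,
    ffmc_max_frac = ffmc_max_frac,
    k = chapman_k(ffmc_min_frac, ffmc_max_frac),
    suppression_factor = suppression_factor
  ), class = "vf_ignition_params")
}

#' Chapman-Richards constant for the initiation-probability curve
#'
#' `k = -ln(1 - 0.99) / (ffmc_max_frac - ffmc_min_frac)`, so that the
#' initiation probability reaches `(1 - 0.01)^2` at the maximum threshold
#' fraction.
#'
#' @param ffmc_min_frac,ffmc_max_frac FFMC threshold fractions with
#'   `ffmc_max_frac > ffmc_min_frac`.
#' @return the positive constant `k`.
#' @export
#' @examples
#' chapman_k(0.6, 0.99)
chapman_k <- function(ffmc_min_frac, ffmc_max_frac) {
  if (ffmc_max_frac <= ffmc_min_frac)
    stop("degenerate parameters: ffmc_max_frac must exceed ffmc_min_frac")
  -log(1 - 0.99) / (ffmc_max_frac - ffmc_min_frac)
}

#' Fire initiation probability (Chapman-Richards stage)
#'
#' `s = (1 - exp(-k * max(ffmc_frac - ffmc_min_frac, 0)))^2`, where
#' `ffmc_frac` is the current FFMC as a fraction of the vegetation type's
#' FFMC threshold. The offset clamp makes `s` zero at and below the minimum
#' threshold fraction and the derived `k` brings it near one at the maximum.
#' Continuous and monotone nondecreasing in `ffmc_frac`; always in `[0, 1)`.
#'
#' @param ffmc_frac FFMC as a fraction of the FFMC threshold, `>= 0`.
#'   Vectorized.
#' @param params an [ignition_params()] list.
#' @return initiation probability in `[0, 1)`.
#' @export
#' @examples
#' initiation_probability(c(0.5, 0.6, 0.99), ignition_params())
initiation_probability <- function(ffmc_frac, params = ignition_params()) {
  off <- pmax(ffmc_frac - params$ffmc_min_frac, 0)
  (1 - exp(-params$k * off))^2
}

#' Fire occurrence under unlimited ignitions
#'
#' A fire occurs if and only if both FFMC and BUI strictly exceed the
#' vegetation type's thresholds (scaled by `suppression_factor` when
#' `suppression = TRUE`): fuel conditions alone decide, ignition sources
#' are assumed unlimited.
#'
#' @param ffmc,bui current index values, `>= 0`. Vectorized.
#' @param veg a list or one-row data frame with `ffmc_threshold` and
#'   `bui_threshold` (per-cell vectors allowed).
#' @param suppression logical; scale both thresholds by
#'   `params$suppression_factor`.
#' @param params an [ignition_params()] list.
#' @return logical: fire / no fire.
#' @export
unlimited_check <- function(ffmc, bui, veg, suppression = FALSE,
                            params = ignition_params()) {
  fac <- if (suppression) params$suppression_factor else 1
  ffmc > veg$ffmc_threshold * fac & bui > veg$bui_threshold * fac
}

#' Fire occurrence under the three-stage stochastic ignition algorithm
#'
#' Stage one: a Bernoulli draw with the daily ignition source probability
#' decides whether the cell is exposed to an ignition source. Stage two:
#' both FFMC and BUI must strictly exceed `threshold_fraction` times their
#' thresholds. Stage three: a second Bernoulli draw against the
#' Chapman-Richards initiation probability (a function of the FFMC fraction
#' only) decides whether the source starts a fire.
#'
#' @inheritParams unlimited_check
#' @param u1,u3 optional uniform draws for stages one and three (supplied
#'   by the scenario runner so that all scenarios share the same streams);
#'   drawn from the current RNG state when `NULL`.
#' @return logical: fire / no fire.
#' @export
stochastic_decide <- function(ffmc, bui, veg, params = ignition_params(),
                              u1 = NULL, u3 = NULL) {
  n <- length(ffmc)
  if (is.null(u1)) u1 <- runif(n)
  if (is.null(u3)) u3 <- runif(n)
  exposed <- u1 < params$p_ignition_source
  gate <- ffmc > params$threshold_fraction * veg$ffmc_threshold &
    bui > params$threshold_fraction * veg$bui_threshold
  s <- initiation_probability(ffmc / veg$ffmc_threshold, params)
  exposed & gate & (u3 < s)
}

#' Default vegetation type parameters
#'
#' One row per vegetation category. The conifer FFMC threshold is 86; the
#' BUI threshold (which has no published per-type value here) is
#' a calibrated default shared by all categories, which also makes fire
#' occurrence independent of the (climate-driven) vegetation category so
#' that scenarios sharing weather share occurrence maps. Fire return
#' intervals (FRI) do differ by category and limit the burnable fraction.
#'
#' @return data frame with columns `veg_id`, `category`, `ffmc_threshold`,
#'   `bui_threshold`, `fri`.
#' @export
default_veg_params <- function() {
  data.frame(
    veg_id = 1:4,
    category = c("conifer", "temperate mixed", "subtropical mixed", "other"),
    ffmc_threshold = 86,
    bui_threshold = 200,
    fri = c(150, 100, 50, 30),
    stringsAsFactors = FALSE
  )
}

# per-year substream seed within a named stream
year_seed <- function(seed, stream, year_index) {
  (substream_seed(seed, stream) + year_index * 1009) %% 2147483647L
}

#' Build the per-mode fire calendar from monthly climate
#'
#' Runs the pseudo-daily fire-weather engine once over the whole simulation:
#' monthly temperature, humidity, and wind are interpolated to days with a
#' cubic-spline basis, monthly precipitation is stochastically disaggregated
#' to daily amounts (conserving monthly totals), and the FFMC/DMC/DC/BUI
#' codes are stepped daily through the fire season (start-up values applied
#' at each season opening). For every cell-year it records, for each of the
#' three fire modes (FF unlimited, FS suppression, SF stochastic), the first
#' qualifying day and the fuel-dryness severity at that day. Stage-one and
#' stage-three uniforms come from dedicated substreams so the calendar is
#' identical across scenarios sharing a master seed.
#'
#' Fire is treated as a discrete annual event: at most one fire per cell
#' per year, at the first qualifying day.
#'
#' @param forcing a `vf_forcing` from [gen_monthly_climate()].
#' @param params an [ignition_params()] list.
#' @param veg vegetation parameters (thresholds used for occurrence); a
#'   list/data frame with `ffmc_threshold`, `bui_threshold` (scalar or
#'   per-cell).
#' @param seed master seed (disaggregation and ignition substreams).
#' @param config a [vf_config()] (fire-season window, start-up codes).
#' @return list of class `vf_fire_calendar` with elements `FF`, `FS`, `SF`,
#'   each a list of matrices `[n_years x ncell]`: `fire` (logical),
#'   `severity` (fuel-dryness scalar in `[0, 1]` at the fire day, `NA`
#'   where no fire), plus `season_days` and diagnostic per-year mean index
#'   summaries.
#' @export
build_fire_calendar <- function(forcing, params = ignition_params(),
                                veg = default_veg_params()[1, ],
                                seed = 1L, config = forcing$config) {
  fire_cfg <- config$fire
  months <- fire_cfg$season_months
  mdays <- days_in_month()
  doy_m <- doy_month()
  season_doys <- which(doy_m %in% months)
  n_sd <- length(season_doys)
  B <- daily_basis()[season_doys, , drop = FALSE]
  years <- forcing$years
  n_yr <- length(years)
  ncell <- forcing$ncell

  thr_f <- rep(veg$ffmc_threshold, length.out = ncell)
  thr_b <- rep(veg$bui_threshold, length.out = ncell)
  sf <- params$suppression_factor
  tf <- params$threshold_fraction

  modes <- c("FF", "FS", "SF")
  out <- lapply(modes, function(m) list(
    fire = matrix(FALSE, n_yr, ncell),
    severity = matrix(NA_real_, n_yr, ncell)
  ))
  names(out) <- modes
  mean_ffmc <- matrix(NA_real_, n_yr, ncell)
  mean_bui <- matrix(NA_real_, n_yr, ncell)

  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit(restore_rng(old), add = TRUE)

  month_of_day <- doy_m[season_doys]
  sev <- function(ffmc, bui) {
    pmin((pmin(ffmc / thr_f, 1) + pmin(bui / thr_b, 1)) / 2, 1)
  }

  for (y in seq_len(n_yr)) {
    tmx <- forcing$tmax[, y, , drop = TRUE]
    if (is.null(dim(tmx))) tmx <- matrix(tmx, 12, ncell)
    rhm <- matrix(forcing$rh[, y, ], 12, ncell)
    wnd <- matrix(forcing$wind[, y, ], 12, ncell)
    prm <- matrix(forcing$precip[, y, ], 12, ncell)

    temp_d <- B %*% matrix(tmx, 12, ncell)
    rh_d <- pmin(pmax(B %*% rhm, 0), 100)
    wind_d <- pmax(B %*% wnd, 0)

    set.seed(year_seed(seed, "precip_disagg", y))
    rain_d <- matrix(0, n_sd, ncell)
    row0 <- 0
    for (m in months) {
      nd <- mdays[m]
      rain_d[row0 + seq_len(nd), ] <-
        disaggregate_precip_matrix(prm[m, ], nd, config$climate$wet_day_prob[m])
      row0 <- row0 + nd
    }

    set.seed(year_seed(seed, "ignition_stage1", y))
    u1 <- matrix(runif(n_sd * ncell), n_sd, ncell)
    set.seed(year_seed(seed, "ignition_stage3", y))
    u3 <- matrix(runif(n_sd * ncell), n_sd, ncell)

    ffmc <- rep(fire_cfg$start_ffmc, ncell)
    dmc <- rep(fire_cfg$start_dmc, ncell)
    dc <- rep(fire_cfg$start_dc, ncell)
    alive <- list(FF = rep(TRUE, ncell), FS = rep(TRUE, ncell),
                  SF = rep(TRUE, ncell))
    acc_f <- numeric(ncell); acc_b <- numeric(ncell)

    for (d in seq_len(n_sd)) {
      mo <- month_of_day[d]
      ffmc <- update_ffmc(ffmc, temp_d[d, ], rh_d[d, ], wind_d[d, ],
                          rain_d[d, ])
      dmc <- update_dmc(dmc, temp_d[d, ], rh_d[d, ], rain_d[d, ], mo)
      dc <- update_dc(dc, temp_d[d, ], rain_d[d, ], mo)
      bui <- compute_bui(dmc, dc)
      acc_f <- acc_f + ffmc; acc_b <- acc_b + bui

      ff_new <- alive$FF & ffmc > thr_f & bui > thr_b
      if (any(ff_new)) {
        out$FF$fire[y, ff_new] <- TRUE
        out$FF$severity[y, ff_new] <- sev(ffmc, bui)[ff_new]
        alive$FF[ff_new] <- FALSE
      }
      fs_new <- alive$FS & ffmc > thr_f * sf & bui > thr_b * sf
      if (any(fs_new)) {
        out$FS$fire[y, fs_new] <- TRUE
        out$FS$severity[y, fs_new] <- sev(ffmc, bui)[fs_new]
        alive$FS[fs_new] <- FALSE
      }
      gate <- ffmc > tf * thr_f & bui > tf * thr_b
      if (any(gate)) {
        s <- initiation_probability(ffmc / thr_f, params)
        sf_new <- alive$SF & (u1[d, ] < params$p_ignition_source) & gate &
          (u3[d, ] < s)
        if (any(sf_new)) {
          out$SF$fire[y, sf_new] <- TRUE
          out$SF$severity[y, sf_new] <- sev(ffmc, bui)[sf_new]
          alive$SF[sf_new] <- FALSE
        }
      }
    }
    mean_ffmc[y, ] <- acc_f / n_sd
    mean_bui[y, ] <- acc_b / n_sd
  }

  structure(list(FF = out$FF, FS = out$FS, SF = out$SF,
                 years = years, season_days = n_sd,
                 mean_ffmc = mean_ffmc, mean_bui = mean_bui,
                 params = params, seed = seed),
            class = "vf_fire_calendar")
}
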