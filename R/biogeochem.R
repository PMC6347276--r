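#' CO2 fertilization parameters
#'
#' @param effect_param dimensionless effect strength; `1` disables the
#'   effect exactly.
#' @param baseline_co2_conc ppm concentration at which the multiplier is 1
#'   (350 ppm by default).
#' @return list of class `vf_co2_params`.
#' @export
co2_params <- function(effect_param = 1.25, baseline_co2_conc = 350) {
  if (baseline_co2_conc <= 0) stop("baseline_co2_conc must be positive")
  structure(list(effect_param = effect_param,
                 baseline_co2_conc = baseline_co2_conc),
            class = "vf_co2_params")
}

#' CO2 multiplier on production and transpiration
#'
#' `multiplier = 1 + (effect_param - 1) * log2(current / baseline)`.
#' Concentrations above the baseline yield a multiplier above one (a
#' positive effect on production and on water-use efficiency), below the
#' baseline a multiplier below one. With the default effect parameter of
#' 1.25, doubling the 350 ppm baseline gives exactly 1.25.
#'
#' @param current_co2_conc ppm, `> 0`. Vectorized.
#' @param params a [co2_params()] list.
#' @return the dimensionless multiplier.
#' @export
#' @examples
#' co2_multiplier(c(280, 350, 700))
co2_multiplier <- function(current_co2_conc, params = co2_params()) {
  if (any(current_co2_conc <= 0))
    stop("current_co2_conc must be positive")
  1 + (params$effect_param - 1) *
    log2(current_co2_conc / params$baseline_co2_conc)
}

# approximate daylength hours by month at mid-latitudes (~46 N)
daylength_hours <- c(8.9, 10.2, 11.8, 13.6, 15.1, 15.9, 15.5, 14.2,
                     12.5, 10.8, 9.3, 8.5)

#' Monthly potential evapotranspiration (temperature-based)
#'
#' A Hamon-type formulation: daily PET proportional to daylength and to
#' saturation vapor density at the monthly mean temperature; zero for
#' months at or below freezing. Monotone nondecreasing in temperature.
#'
#' @param temp monthly mean temperature, degrees C. Vectorized.
#' @param daylength daylength in hours (e.g. `vegfire:::daylength_hours`).
#' @param days days in the month.
#' @return PET in mm per month, `>= 0`.
#' @export
#' @examples
#' pet_monthly(c(-2, 5, 20), 12, 30)
pet_monthly <- function(temp, daylength = 12, days = 30) {
  es <- 0.6108 * exp(17.27 * temp / (temp + 237.3))        # kPa
  pet <- 29.8 * (daylength / 12) * es / (temp + 273.2) * days
  ifelse(temp <= 0, 0, pmax(pet, 0))
}

#' One month of the soil water bucket
#'
#' Precipitation fills the bucket to the water-holding capacity (excess
#' runs off), then evapotranspiration extracts the smaller of the demand
#' and the stored water. Transpiration demand is divided by the CO2
#' multiplier: higher CO2 raises water-use efficiency, so the same
#' potential demand draws less water.
#'
#' @param soil_water stored plant-available water, mm. Vectorized.
#' @param precip monthly precipitation, mm.
#' @param pet monthly potential evapotranspiration, mm.
#' @param whc water-holding capacity, mm, `> 0`.
#' @param multiplier CO2 multiplier (see [co2_multiplier()]).
#' @return list with `soil_water` (updated, in `[0, whc]`), `aet` (actual
#'   evapotranspiration, mm), `demand` (mm).
#' @export
soil_water_step <- function(soil_water, precip, pet, whc, multiplier = 1) {
  if (any(whc <= 0)) stop("configuration error: whc must be positive")
  demand <- pet / multiplier
  sw <- pmin(soil_water + precip, whc)
  aet <- pmin(demand, sw)
  list(soil_water = sw - aet, aet = aet, demand = demand)
}

#' Triangular temperature scalar for production
#'
#' Rises linearly from 0 at `lo` to 1 at `opt`, falls linearly back to 0
#' at `hi`; evaluated on the Apr-Sep mean temperature by the scenario
#' runner.
#'
#' @param temp degrees C. Vectorized.
#' @param opt,lo,hi optimum and zero-production limits, degrees C.
#' @return scalar in `[0, 1]`.
#' @export
npp_temp_scalar <- function(temp, opt = 18, lo = 0, hi = 38) {
  up <- (temp - lo) / (opt - lo)
  down <- (hi - temp) / (hi - opt)
  pmin(pmax(pmin(up, down), 0), 1)
}

#' Net primary production from its scalars
#'
#' Product-form surrogate: `npp = npp_max * temp_scalar * water_scalar *
#' multiplier`, linear in the CO2 multiplier.
#'
#' @param temp_scalar,water_scalar scalars in `[0, 1]`.
#' @param multiplier CO2 multiplier.
#' @param npp_max maximum production, g C m-2 yr-1.
#' @return NPP, g C m-2 yr-1, `>= 0`.
#' @export
compute_npp <- function(temp_scalar, water_scalar, multiplier = 1,
                        npp_max = 2500) {
  if (any(temp_scalar < 0 | temp_scalar > 1) ||
      any(water_scalar < 0 | water_scalar > 1))
    stop("scalars must be in [0, 1]")
  npp_max * temp_scalar * water_scalar * multiplier
}

#' One annual carbon-pool step
#'
#' Allocates NPP to leaf/wood/root pools, applies first-order live
#' turnover (leaf and root litterfall, wood mortality to standing dead),
#' and decomposes the dead pools with a Q10 temperature response and a
#' linear moisture response. A configurable fraction of each dead pool's
#' decay is humified to the next pool (standing dead to litter, litter to
#' soil); the remainder is heterotrophic respiration. Flux identities hold
#' exactly: `nep = npp - rh`, `nbp = nep - consumed`, and the ecosystem
#' carbon change over the step equals `nep` (fire consumption is applied
#' by the caller before the step).
#'
#' @param pools a [carbon_pools()] list (vectors over cells).
#' @param npp annual NPP, g C m-2 yr-1.
#' @param tavg annual mean temperature, degrees C (drives the Q10
#'   response).
#' @param moisture decomposition moisture scalar in `[0, 1]`.
#' @param params the `carbon` element of a [vf_config()].
#' @param consumed fire-consumed carbon for the year (enters `nbp` only).
#' @return list with `pools` (updated) and `fluxes`: `npp`, `rh`, `nep`,
#'   `nbp`, `consumed` (g C m-2 yr-1).
#' @export
step_carbon <- function(pools, npp, tavg, moisture, params = vf_config()$carbon,
                        consumed = 0) {
  ks <- c(params$k_leaf, params$k_wood, params$k_root,
          params$k_standing_dead, params$k_litter, params$k_soil)
  if (any(ks < 0)) stop("configuration error: negative rate constant")
  g <- params$q10^((tavg - params$t_ref) / 10) * pmin(pmax(moisture, 0), 1)
  g <- pmin(g, 1 / max(params$k_standing_dead, params$k_litter, 1e-9))

  leaf_fall <- params$k_leaf * pools$leaf_c
  wood_mort <- params$k_wood * pools$live_wood_above_c
  root_turn <- params$k_root * pools$live_root_c
  sd_out <- params$k_standing_dead * g * pools$standing_dead_c
  lit_out <- params$k_litter * g * pools$litter_c
  soil_out <- params$k_soil * g * pools$soil_c

  al <- params$alloc
  pools$leaf_c <- pools$leaf_c + npp * al[["leaf"]] - leaf_fall
  pools$live_wood_above_c <- pools$live_wood_above_c +
    npp * al[["wood"]] - wood_mort
  pools$live_root_c <- pools$live_root_c + npp * al[["root"]] - root_turn
  pools$standing_dead_c <- pools$standing_dead_c + wood_mort - sd_out
  pools$litter_c <- pools$litter_c + leaf_fall + root_turn +
    params$f_sd_to_litter * sd_out - lit_out
  pools$soil_c <- pools$soil_c + params$f_litter_to_soil * lit_out - soil_out

  rh <- (1 - params$f_sd_to_litter) * sd_out +
    (1 - params$f_litter_to_soil) * lit_out + soil_out
  nep <- npp - rh
  list(pools = pools,
       fluxes = list(npp = npp, rh = rh, nep = nep,
                     nbp = nep - consumed, consumed = consumed))
}

#' Analytic steady-state pools under constant forcing
#'
#' Closed-form fixed point of the first-order pool system at constant NPP
#' and decomposition modifier: each pool equals its input divided by its
#' effective rate. Used to initialize the spin-up and as the reference in
#' convergence checks.
#'
#' @inheritParams step_carbon
#' @param g_dead decomposition modifier (Q10 times moisture) treated as
#'   constant.
#' @return a [carbon_pools()] list.
#' @export
steady_state_pools <- function(npp, params = vf_config()$carbon, g_dead = 0.7) {
  al <- params$alloc
  leaf <- npp * al[["leaf"]] / params$k_leaf
  wood <- npp * al[["wood"]] / params$k_wood
  root <- npp * al[["root"]] / params$k_root
  sd_in <- npp * al[["wood"]]
  sd <- sd_in / (params$k_standing_dead * g_dead)
  lit_in <- npp * al[["leaf"]] + npp * al[["root"]] +
    params$f_sd_to_litter * sd_in
  lit <- lit_in / (params$k_litter * g_dead)
  soil_in <- params$f_litter_to_soil * lit_in
  soil <- soil_in / (params$k_soil * g_dead)
  carbon_pools(leaf, wood, root, sd, lit, soil)
}
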