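#' Vegetation category labels
#'
#' The four reporting categories, in tie-break order.
#'
#' @return character vector of length 4.
#' @export
veg_categories <- function() {
  c("conifer", "temperate mixed", "subtropical mixed", "other")
}

#' Per-year climate summaries for vegetation typing
#'
#' Computes, for every cell-year of a forcing: growing degree-days (base
#' 5 degrees C, from monthly mean temperatures), the coldest-month mean
#' minimum temperature, Apr-Sep precipitation, Apr-Sep mean temperature,
#' and an annual moisture index (precipitation over PET). The Apr-Sep mean
#' temperature is also exponentially smoothed across years (e-folding time
#' `efold_yr`) into the `warmth` field used by [classify_veg()] --
#' representing the inertia with which vegetation tracks climate.
#'
#' @param forcing a `vf_forcing`.
#' @param efold_yr e-folding time of the exponential smoothing, years.
#' @return list of class `vf_climate_summary` of matrices
#'   `[n_years x ncell]`: `gdd`, `tmin_winter`, `precip_summer`,
#'   `summer_tavg`, `moisture_index`, `warmth`.
#' @export
summarize_climate <- function(forcing, efold_yr = 15) {
  if (length(forcing$years) < 1) stop("empty climate window")
  mdays <- days_in_month()
  tavg <- (forcing$tmax + forcing$tmin) / 2
  n_yr <- length(forcing$years)
  ncell <- forcing$ncell
  summer <- month_in(4:9)

  gdd_m <- pmax(tavg - 5, 0) * mdays           # recycles mdays over dim 1
  gdd <- matrix(colSums(matrix(gdd_m, 12)), n_yr, ncell)
  tmin_winter <- matrix(apply(forcing$tmin, c(2, 3), min), n_yr, ncell)
  pr_su <- matrix(colSums(matrix(forcing$precip[summer, , ],
                                 sum(summer))), n_yr, ncell)
  t_su <- matrix(colMeans(matrix(tavg[summer, , ], sum(summer))), n_yr, ncell)
  pet_m <- pet_monthly(tavg, rep(daylength_hours, n_yr * ncell), mdays)
  pet_yr <- matrix(colSums(matrix(pet_m, 12)), n_yr, ncell)
  pr_yr <- matrix(colSums(matrix(forcing$precip, 12)), n_yr, ncell)
  mi <- pr_yr / pmax(pet_yr, 1)

  alpha <- 1 - exp(-1 / efold_yr)
  warmth <- t_su
  if (n_yr > 1) {
    for (y in 2:n_yr) {
      warmth[y, ] <- warmth[y - 1, ] + alpha * (t_su[y, ] - warmth[y - 1, ])
    }
  }
  structure(list(gdd = gdd, tmin_winter = tmin_winter,
                 precip_summer = pr_su, summer_tavg = t_su,
                 moisture_index = mi, warmth = warmth,
                 years = forcing$years),
            class = "vf_climate_summary")
}

#' Classify vegetation from climate summary and carbon
#'
#' Carbon-gated, warmth-indexed typing: cells whose live woody carbon is
#' below the forest threshold (or whose growing season is too short) are
#' `other`; among forests, the smoothed warmth index selects conifer
#' (coolest), temperate mixed, or subtropical mixed (warmest). Threshold
#' values are calibrated defaults of the configuration (see the methods
#' vignette).
#'
#' @param warmth smoothed Apr-Sep mean temperature per cell (one year's
#'   row of `summarize_climate()$warmth`).
#' @param gdd growing degree-days per cell.
#' @param wood_c live aboveground woody carbon per cell, g C m-2.
#' @param thresholds the `veg_class` element of a [vf_config()].
#' @return integer vector of category ids (1 conifer, 2 temperate mixed,
#'   3 subtropical mixed, 4 other), see [veg_categories()].
#' @export
classify_veg <- function(warmth, gdd, wood_c,
                         thresholds = vf_config()$veg_class) {
  if (thresholds$warmth_t1 >= thresholds$warmth_t2)
    stop("configuration error: overlapping warmth thresholds")
  id <- ifelse(warmth < thresholds$warmth_t1, 1L,
               ifelse(warmth < thresholds$warmth_t2, 2L, 3L))
  id[wood_c < thresholds$forest_wood_c_min |
       gdd < thresholds$gdd_forest_min] <- 4L
  id
}

#' Modal vegetation category over a period
#'
#' The most frequent category of each cell across the period's years; ties
#' break to the lowest category index (the first-listed category).
#'
#' @param categories integer matrix `[n_years x ncell]` of category ids.
#' @param years the years of the rows.
#' @param period two-element numeric `c(start, end)` or a row label of
#'   [analysis_periods()].
#' @return integer vector of per-cell modal category ids.
#' @export
period_mode <- function(categories, years, period) {
  if (is.character(period)) {
    p <- analysis_periods()
    period <- unlist(p[p$label == period, c("start", "end")])
    if (!length(period)) stop("unknown period label")
  }
  rows <- which(years >= period[1] & years <= period[2])
  if (!length(rows)) stop("period outside the simulation window")
  apply(categories[rows, , drop = FALSE], 2, function(v) {
    counts <- tabulate(v, nbins = 4)
    which.max(counts)   # first maximum = lowest index on ties
  })
}

#' Area-weighted category distribution
#'
#' @param mode_ids integer vector of per-cell category ids.
#' @param cell_areas per-cell areas (any unit).
#' @return named numeric vector of percentages per category, summing
#'   to 100.
#' @export
#' @examples
#' category_distribution(c(1, 2, 2), c(1, 1, 2))
category_distribution <- function(mode_ids, cell_areas) {
  if (length(mode_ids) != length(cell_areas))
    stop("mode map and cell areas must conform")
  tot <- sum(cell_areas)
  pct <- vapply(1:4, function(k) sum(cell_areas[mode_ids == k]) / tot * 100,
                numeric(1))
  names(pct) <- veg_categories()
  pct
}
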