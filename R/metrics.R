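#' Annual fire metrics: AWF, FAB, TAB
#'
#' From per-cell burned fractions: AWF (area with fire) is the percentage
#' of study area in cells with any fire; FAB (fraction area burned) the
#' area-weighted mean burned fraction among cells with fire; TAB (total
#' area burned) the percentage of study area burned. In fractional form
#' `tab = awf * fab` identically. In zero-fire years FAB is undefined and
#' reported as 0 with `fab_defined = FALSE`.
#'
#' @param frac_burned matrix `[n_years x ncell]` of burned fractions in
#'   `[0, 1]` (0 = no fire).
#' @param cell_areas per-cell areas.
#' @param years optional year labels.
#' @return data frame with columns `year`, `awf`, `fab`, `tab` (percent)
#'   and `fab_defined`.
#' @export
#' @examples
#' fire_metrics(matrix(c(0.5, 0, 1), 1), c(1, 1, 1))
fire_metrics <- function(frac_burned, cell_areas, years = NULL) {
  frac_burned <- rbind(frac_burned)
  if (any(frac_burned < 0 | frac_burned > 1))
    stop("burned fractions must be in [0, 1]")
  n_yr <- nrow(frac_burned)
  total <- sum(cell_areas)
  awf <- fab <- tab <- numeric(n_yr)
  defined <- logical(n_yr)
  for (y in seq_len(n_yr)) {
    f <- frac_burned[y, ]
    hit <- f > 0
    area_fire <- sum(cell_areas[hit])
    burned <- sum(cell_areas * f)
    awf[y] <- area_fire / total * 100
    tab[y] <- burned / total * 100
    defined[y] <- area_fire > 0
    fab[y] <- if (defined[y]) burned / area_fire * 100 else 0
  }
  data.frame(year = if (is.null(years)) seq_len(n_yr) else years,
             awf = awf, fab = fab, tab = tab, fab_defined = defined)
}

#' Per-period means and standard deviations
#'
#' Summarizes annual series over the five 30-year analysis periods (or any
#' supplied periods): mean and standard deviation across years. Errors if
#' a period is not fully covered by the series.
#'
#' @param df data frame with a `year` column and numeric series columns.
#' @param vars names of columns to summarize; defaults to all numeric
#'   columns except `year`.
#' @param periods data frame like [analysis_periods()].
#' @return data frame: one row per period x variable with `mean` and `sd`.
#' @export
period_summary <- function(df, vars = NULL, periods = analysis_periods()) {
  if (is.null(vars)) {
    vars <- setdiff(names(df)[vapply(df, is.numeric, logical(1))], "year")
  }
  out <- list()
  for (i in seq_len(nrow(periods))) {
    yrs <- periods$start[i]:periods$end[i]
    if (!all(yrs %in% df$year))
      stop("missing years for period ", periods$label[i])
    sub <- df[df$year %in% yrs, , drop = FALSE]
    for (v in vars) {
      x <- sub[[v]]
      if (v == "fab" && "fab_defined" %in% names(sub)) {
        x <- x[sub$fab_defined]        # FAB defined only in fire years
        if (!length(x)) x <- NA_real_
      }
      out[[length(out) + 1]] <- data.frame(
        period = periods$label[i], variable = v,
        mean = mean(x), sd = if (length(x) > 1) sd(x) else 0
      )
    }
  }
  do.call(rbind, out)
}

#' Triangle smoothing of an annual series
#'
#' Weighted moving average with triangular weights
#' `w(d) = half_width + 1 - |d|` over lags `d` in
#' `[-half_width, half_width]`, renormalized where the window is clipped
#' at the series edges. Preserves constants; the identity at
#' `half_width = 0`.
#'
#' @param x numeric series.
#' @param half_width window half-width in years (8 by default).
#' @return smoothed series, same length as `x`.
#' @export
#' @examples
#' triangle_smooth(c(0, 0, 1, 0, 0), half_width = 1)
triangle_smooth <- function(x, half_width = 8) {
  if (half_width < 0) stop("half_width must be nonnegative")
  if (half_width == 0) return(x)
  n <- length(x)
  w <- half_width + 1 - abs(-half_width:half_width)
  out <- numeric(n)
  for (i in seq_len(n)) {
    j <- max(1, i - half_width):min(n, i + half_width)
    wj <- w[j - i + half_width + 1]
    out[i] <- sum(x[j] * wj) / sum(wj)
  }
  out
}

#' Weight a per-cell field by an area-fraction mask
#'
#' Elementwise product of a density field with a mask in `[0, 1]`, e.g.
#' scaling carbon densities by the non-human-affected fraction of each
#' cell.
#'
#' @param field numeric vector/matrix.
#' @param mask same shape, values in `[0, 1]`.
#' @return the weighted field.
#' @export
mask_weight <- function(field, mask) {
  if (length(field) != length(mask))
    stop("field and mask shapes do not match")
  if (any(mask < 0 | mask > 1)) stop("mask values must be in [0, 1]")
  field * mask
}

#' Aboveground woody carbon summary
#'
#' AGB (aboveground live woody carbon), AGD (standing dead plus the woody
#' share of litter), AGT = AGB + AGD, and the live:dead ratio of all
#' pools. When dead carbon is zero the ratio is undefined and returned as
#' `NA` with `ratio_defined = FALSE`.
#'
#' @param pools a [carbon_pools()] list.
#' @param litter_woody_frac share of the litter pool counted as woody.
#' @return list with `agb`, `agd`, `agt` (g C m-2, vectors over cells),
#'   `live_dead_ratio`, `ratio_defined`.
#' @export
carbon_summary <- function(pools, litter_woody_frac = 0.3) {
  agb <- pools$live_wood_above_c
  agd <- pools$standing_dead_c + litter_woody_frac * pools$litter_c
  dead <- dead_c(pools)
  defined <- dead > 0
  ratio <- ifelse(defined, live_c(pools) / dead, NA_real_)
  list(agb = agb, agd = agd, agt = agb + agd,
       live_dead_ratio = ratio, ratio_defined = defined)
}
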