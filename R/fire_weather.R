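#' Disaggregate a monthly precipitation total into daily amounts
#'
#' Wet days are drawn Bernoulli(`wet_day_prob`); wet-day amounts are drawn
#' from an exponential distribution and rescaled so the daily vector sums
#' exactly to the monthly total (conservation by construction). If no wet
#' day is drawn for a wet month, the whole total falls on one uniformly
#' chosen day.
#'
#' @param monthly_total mm, `>= 0`.
#' @param n_days number of days in the month.
#' @param wet_day_prob probability a given day is wet, in `(0, 1]`.
#' @return numeric vector of length `n_days`, nonnegative, summing to
#'   `monthly_total`. Consumes draws from the current RNG state; seed the
#'   `precip_disagg` substream before calling for reproducibility.
#' @export
#' @examples
#' set.seed(1); r <- disaggregate_precip(120, 30, 0.4)
#' sum(r)
disaggregate_precip <- function(monthly_total, n_days, wet_day_prob) {
  if (n_days < 1) stop("n_days must be at least 1")
  if (monthly_total < 0) stop("monthly_total must be nonnegative")
  if (wet_day_prob <= 0 || wet_day_prob > 1)
    stop("wet_day_prob must be in (0, 1]")
  wet <- runif(n_days) < wet_day_prob
  amt <- rexp(n_days)
  if (monthly_total == 0) return(numeric(n_days))
  w <- ifelse(wet, amt, 0)
  if (sum(w) == 0) w[sample.int(n_days, 1)] <- 1
  w / sum(w) * monthly_total
}

# Matrix form used by the daily engine: disaggregates one month for all
# cells at once. Draw order is fixed (day-major per cell block) so the
# stream is identical across scenarios.
disaggregate_precip_matrix <- function(monthly_totals, n_days, wet_day_prob) {
  ncell <- length(monthly_totals)
  wet <- matrix(runif(n_days * ncell) < wet_day_prob, n_days, ncell)
  amt <- matrix(rexp(n_days * ncell), n_days, ncell)
  pick <- sample.int(n_days, ncell, replace = TRUE)
  w <- wet * amt
  cs <- colSums(w)
  fix <- which(cs == 0)
  if (length(fix)) {
    w[cbind(pick[fix], fix)] <- 1
    cs[fix] <- 1
  }
  sweep(w, 2, monthly_totals / cs, `*`)
}

#' Daily update of the Fine Fuel Moisture Code (FFMC)
#'
#' The standard daily FFMC of the Canadian Fire Weather Index system:
#' yesterday's code is converted to a fine-fuel moisture content, rain
#' (above the 0.5 mm canopy trap) wets it with a diminishing-returns term,
#' and the moisture then moves toward the wetting or drying equilibrium at
#' a rate set by temperature, relative humidity, and wind.
#'
#' All arguments are vectorized (the simulator updates every grid cell in
#' one call).
#'
#' @param ffmc_prev previous day's FFMC, in `[0, 101]`.
#' @param temp noon temperature, degrees C.
#' @param rh noon relative humidity, percent.
#' @param wind wind speed, km/h.
#' @param rain 24-h rainfall, mm.
#' @return updated FFMC in `[0, 101]`.
#' @export
update_ffmc <- function(ffmc_prev, temp, rh, wind, rain) {
  n <- max(length(ffmc_prev), length(temp), length(rh), length(wind),
           length(rain))
  mo <- rep_len(147.2 * (101 - ffmc_prev) / (59.5 + ffmc_prev), n)
  rf <- pmax(rep_len(rain, n) - 0.5, 0)
  w <- which(rf > 0)
  if (length(w)) {
    mw <- mo[w]; rw <- rf[w]
    mr <- mw + 42.5 * rw * exp(-100 / (251 - mw)) * (1 - exp(-6.93 / rw))
    hi <- mw > 150
    mr[hi] <- mr[hi] + 0.0015 * (mw[hi] - 150)^2 * sqrt(rw[hi])
    mo[w] <- pmin(mr, 250)
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  h100 <- rh / 100
  kd <- (0.424 * (1 - h100^1.7) +
           0.0694 * sqrt(wind) * (1 - h100^8)) * 0.581 * exp(0.0365 * temp)
  kw <- (0.424 * (1 - (1 - h100)^1.7) +
           0.0694 * sqrt(wind) * (1 - (1 - h100)^8)) * 0.581 * exp(0.0365 * temp)
  m <- ifelse(mo > ed, ed + (mo - ed) * 10^(-kd),
              ifelse(mo < ew, ew - (ew - mo) * 10^(-kw), mo))
  pmin(pmax(59.5 * (250 - m) / (147.2 + m), 0), 101)
}

# DMC day-length factors, mid northern latitudes
dmc_day_length <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4,
                    8.0, 7.0, 6.0)
# DC seasonal day-length adjustment
dc_day_length <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4,
                   0.4, -1.6, -1.6)

#' Daily update of the Duff Moisture Code (DMC)
#'
#' @param dmc_prev previous day's DMC, `>= 0`.
#' @param temp,rh,rain noon temperature (degrees C), relative humidity (%),
#'   24-h rain (mm). Vectorized.
#' @param month calendar month 1-12 (scalar), selecting the day-length
#'   factor.
#' @return updated DMC, `>= 0`.
#' @export
update_dmc <- function(dmc_prev, temp, rh, rain, month) {
  n <- max(length(dmc_prev), length(temp), length(rh), length(rain))
  p0 <- rep_len(dmc_prev, n)
  rain <- rep_len(rain, n)
  w <- which(rain > 1.5)
  if (length(w)) {
    pw <- p0[w]
    re <- 0.92 * rain[w] - 1.27
    mo <- 20 + 280 / exp(0.023 * pw)
    b <- 100 / (0.5 + 0.3 * pw)
    mid <- pw > 33 & pw <= 65
    b[mid] <- 14 - 1.3 * log(pw[mid])
    hi <- pw > 65
    b[hi] <- 6.2 * log(pw[hi]) - 17.2
    mr <- mo + 1000 * re / (48.77 + b * re)
    p0[w] <- pmax(43.43 * (5.6348 - log(mr - 20)), 0)
  }
  k <- ifelse(temp > -1.1,
              1.894 * (temp + 1.1) * (100 - rh) * dmc_day_length[month] * 1e-6,
              0)
  pmax(p0 + 100 * k, 0)
}

#' Daily update of the Drought Code (DC)
#'
#' @param dc_prev previous day's DC, `>= 0`.
#' @param temp,rain noon temperature (degrees C) and 24-h rain (mm).
#'   Vectorized.
#' @param month calendar month 1-12 (scalar).
#' @return updated DC, `>= 0`.
#' @export
update_dc <- function(dc_prev, temp, rain, month) {
  n <- max(length(dc_prev), length(temp), length(rain))
  d0 <- rep_len(dc_prev, n)
  rain <- rep_len(rain, n)
  w <- which(rain > 2.8)
  if (length(w)) {
    rd <- 0.83 * rain[w] - 1.27
    qo <- 800 * exp(-d0[w] / 400)
    d0[w] <- pmax(400 * log(800 / (qo + 3.937 * rd)), 0)
  }
  v <- pmax(ifelse(temp > -2.8, 0.36 * (temp + 2.8), 0) +
              dc_day_length[month], 0)
  pmax(d0 + 0.5 * v, 0)
}

#' Buildup Index from DMC and DC
#'
#' Deterministic, monotone nondecreasing in each argument; zero when DMC is
#' zero.
#'
#' @param dmc,dc moisture codes, `>= 0`. Vectorized.
#' @return BUI, `>= 0`.
#' @export
#' @examples
#' compute_bui(60, 300)
compute_bui <- function(dmc, dc) {
  bui <- ifelse(dmc <= 0.4 * dc,
                0.8 * dmc * dc / pmax(dmc + 0.4 * dc, 1e-12),
                dmc - (1 - 0.8 * dc / pmax(dmc + 0.4 * dc, 1e-12)) *
                  (0.92 + (0.0114 * dmc)^1.7))
  bui[dmc == 0] <- 0
  pmax(bui, 0)
}

# Cubic-spline basis mapping 12 monthly values (at month midpoints) to the
# 365 days of a fixed no-leap calendar. The spline is linear in the data, so
# daily fields are a single matrix product B %*% monthly.
daily_basis <- function() {
  mdays <- days_in_month()
  mid <- cumsum(mdays) - mdays / 2
  B <- matrix(0, 365, 12)
  for (j in seq_len(12)) {
    e <- numeric(12); e[j] <- 1
    B[, j] <- spline(mid, e, xout = seq_len(365), method = "natural")$y
  }
  B
}

# day-of-year -> month lookup for the fixed calendar
doy_month <- function() rep(seq_len(12), days_in_month())
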