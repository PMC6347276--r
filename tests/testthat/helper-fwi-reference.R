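# Independent scalar transcription of the daily Canadian FWI moisture-code
# equations (Van Wagner's published formulation), coded step by step with
# explicit branches. Serves as the dual-implementation oracle for the
# package's vectorised versions: same published equations, independently
# structured code.

ref_ffmc <- function(f0, temp, rh, wind, rain) {
  wmo <- 147.2 * (101 - f0) / (59.5 + f0)
  if (rain > 0.5) {
    ra <- rain - 0.5
    if (wmo > 150) {
      wmo <- wmo + 42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra)) +
        0.0015 * (wmo - 150)^2 * sqrt(ra)
    } else {
      wmo <- wmo + 42.5 * ra * exp(-100 / (251 - wmo)) * (1 - exp(-6.93 / ra))
    }
    if (wmo > 250) wmo <- 250
  }
  ed <- 0.942 * rh^0.679 + 11 * exp((rh - 100) / 10) +
    0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
  if (wmo > ed) {
    z <- 0.424 * (1 - (rh / 100)^1.7) +
      0.0694 * sqrt(wind) * (1 - (rh / 100)^8)
    x <- z * 0.581 * exp(0.0365 * temp)
    wm <- ed + (wmo - ed) * 10^(-x)
  } else {
    ew <- 0.618 * rh^0.753 + 10 * exp((rh - 100) / 10) +
      0.18 * (21.1 - temp) * (1 - exp(-0.115 * rh))
    if (wmo < ew) {
      z <- 0.424 * (1 - ((100 - rh) / 100)^1.7) +
        0.0694 * sqrt(wind) * (1 - ((100 - rh) / 100)^8)
      x <- z * 0.581 * exp(0.0365 * temp)
      wm <- ew - (ew - wmo) * 10^(-x)
    } else {
      wm <- wmo
    }
  }
  f <- 59.5 * (250 - wm) / (147.2 + wm)
  if (f > 101) f <- 101
  if (f < 0) f <- 0
  f
}

.ref_el <- c(6.5, 7.5, 9.0, 12.8, 13.9, 13.9, 12.4, 10.9, 9.4, 8.0, 7.0, 6.0)

ref_dmc <- function(p0, temp, rh, rain, month) {
  if (rain > 1.5) {
    rw <- 0.92 * rain - 1.27
    wmi <- 20 + 280 / exp(0.023 * p0)
    if (p0 <= 33) {
      b <- 100 / (0.5 + 0.3 * p0)
    } else if (p0 <= 65) {
      b <- 14 - 1.3 * log(p0)
    } else {
      b <- 6.2 * log(p0) - 17.2
    }
    wmr <- wmi + 1000 * rw / (48.77 + b * rw)
    p0 <- 43.43 * (5.6348 - log(wmr - 20))
    if (p0 < 0) p0 <- 0
  }
  tt <- temp
  if (tt < -1.1) tt <- -1.1
  rk <- 1.894 * (tt + 1.1) * (100 - rh) * .ref_el[month] * 1e-6
  p <- p0 + 100 * rk
  if (p < 0) p <- 0
  p
}

.ref_fl <- c(-1.6, -1.6, -1.6, 0.9, 3.8, 5.8, 6.4, 5.0, 2.4, 0.4, -1.6, -1.6)

ref_dc <- function(d0, temp, rain, month) {
  if (rain > 2.8) {
    rw <- 0.83 * rain - 1.27
    smi <- 800 * exp(-d0 / 400)
    d0 <- 400 * log(800 / (smi + 3.937 * rw))
    if (d0 < 0) d0 <- 0
  }
  tt <- temp
  if (tt < -2.8) tt <- -2.8
  v <- 0.36 * (tt + 2.8) + .ref_fl[month]
  if (v < 0) v <- 0
  d <- d0 + 0.5 * v
  if (d < 0) d <- 0
  d
}

ref_bui <- function(dmc, dc) {
  if (dmc == 0 && dc == 0) return(0)
  if (dmc <= 0.4 * dc) {
    b <- 0.8 * dc * dmc / (dmc + 0.4 * dc)
  } else {
    b <- dmc - (1 - 0.8 * dc / (dmc + 0.4 * dc)) *
      (0.92 + (0.0114 * dmc)^1.7)
  }
  if (b < 0) b <- 0
  b
}

# random admissible daily weather for oracle comparisons
random_weather <- function(n, seed) {
  set.seed(seed)
  data.frame(
    temp = runif(n, -5, 35),
    rh = runif(n, 10, 100),
    wind = runif(n, 0, 40),
    rain = ifelse(runif(n) < 0.4, rexp(n, 1 / 6), 0)
  )
}
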