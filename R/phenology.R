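# Canonical order of the seven cultivar-specific parameters (CSPs).
CSP_NAMES <- c("csdl", "ppsen", "r1ppo", "em_fl", "fl_sh", "fl_sd", "sd_pm")

STAGE_NAMES <- c("fs", "ps", "gs", "ms")

#' Calibration ranges for the seven cultivar-specific parameters
#'
#' Returns the box constraints used for calibration and prior sampling:
#' critical short day `csdl` (h), photoperiod sensitivity `ppsen` (1/h),
#' post-anthesis increase in daylength sensitivity `r1ppo` (h), and the four
#' phase durations in photothermal days: sowing/emergence to first flower
#' `em_fl`, first flower to first pod `fl_sh`, first flower to first seed
#' `fl_sd`, first seed to physiological maturity `sd_pm`.
#'
#' @return A 7 x 2 numeric matrix with rownames `csdl`, `ppsen`, `r1ppo`,
#'   `em_fl`, `fl_sh`, `fl_sd`, `sd_pm` and columns `lower`, `upper`.
#' @examples
#' csp_bounds()
#' @export
csp_bounds <- function() {
  m <- matrix(c(
    11.78, 14.6,
    0.129, 0.385,
    0.189, 0.549,
    15.5, 28.9,
    5.5, 10.0,
    12.0, 16.0,
    12.0, 16.0
  ), ncol = 2, byrow = TRUE,
  dimnames = list(CSP_NAMES, c("lower", "upper")))
  m
}

#' Construct and validate a cultivar parameter vector
#'
#' @param csdl Critical short day (hours): the daylength at or below which
#'   development proceeds at the photoperiod-unconstrained rate.
#' @param ppsen Photoperiod sensitivity (1/hour): relative development-rate
#'   reduction per hour of daylength beyond `csdl`.
#' @param r1ppo Post-anthesis increase in daylength sensitivity (hours): the
#'   effective critical short day after first flowering is `csdl - r1ppo`.
#' @param em_fl,fl_sh,fl_sd,sd_pm Phase durations in photothermal days:
#'   emergence to first flower, first flower to first pod, first flower to
#'   first seed, first seed to physiological maturity.
#' @param strict If `TRUE` (default), each value must lie inside its
#'   calibration range from [csp_bounds()]; otherwise values need only be
#'   positive.
#' @return Named numeric vector of length 7 in canonical order.
#' @examples
#' cultivar_params(csdl = 13, ppsen = 0.25, r1ppo = 0.35,
#'                 em_fl = 20, fl_sh = 7, fl_sd = 14, sd_pm = 14)
#' @export
cultivar_params <- function(csdl, ppsen, r1ppo, em_fl, fl_sh, fl_sd, sd_pm,
                            strict = TRUE) {
  p <- c(csdl = csdl, ppsen = ppsen, r1ppo = r1ppo, em_fl = em_fl,
         fl_sh = fl_sh, fl_sd = fl_sd, sd_pm = sd_pm)
  if (any(!is.finite(p)) || any(p <= 0)) {
    stop("all cultivar parameters must be finite and positive")
  }
  if (strict) {
    b <- csp_bounds()
    bad <- p < b[, "lower"] | p > b[, "upper"]
    if (any(bad)) {
      stop("cultivar parameter(s) outside calibration range: ",
           paste(CSP_NAMES[bad], collapse = ", "))
    }
  }
  p
}

#' Cardinal temperatures of the thermal response
#'
#' The daily thermal factor is a trapezoid on daily mean temperature: 0 at or
#' below `t_base` and at or above `t_ceil`, 1 on the optimal plateau
#' `[t_opt_lo, t_opt_hi]`, linear in between.  Defaults (6, 26, 30, 45 degC)
#' are configuration for a warm-season legume, not observations.
#'
#' @param t_base,t_opt_lo,t_opt_hi,t_ceil Cardinal temperatures in degC,
#'   strictly ordered `t_base < t_opt_lo <= t_opt_hi < t_ceil`.
#' @return Named numeric vector of length 4.
#' @export
cardinal_temps <- function(t_base = 6, t_opt_lo = 26, t_opt_hi = 30,
                           t_ceil = 45) {
  if (!(t_base < t_opt_lo && t_opt_lo <= t_opt_hi && t_opt_hi < t_ceil)) {
    stop("cardinal temperatures must satisfy t_base < t_opt_lo <= t_opt_hi < t_ceil")
  }
  c(t_base = t_base, t_opt_lo = t_opt_lo, t_opt_hi = t_opt_hi,
    t_ceil = t_ceil)
}

#' Site and sowing description
#'
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param sowing_date A `Date` (or string coercible to one).
#' @param sowing_depth Sowing depth in cm, in `(0, 15]`.
#' @return List with elements `latitude`, `sowing_date`, `sowing_depth`.
#' @export
site_sowing <- function(latitude, sowing_date, sowing_depth = 3) {
  if (!is.finite(latitude) || abs(latitude) > 90) {
    stop("latitude must lie in [-90, 90]")
  }
  sowing_date <- as.Date(sowing_date)
  if (is.na(sowing_date)) stop("sowing_date is not a valid date")
  if (!is.finite(sowing_depth) || sowing_depth <= 0 || sowing_depth > 15) {
    stop("sowing_depth must lie in (0, 15] cm")
  }
  list(latitude = latitude, sowing_date = sowing_date,
       sowing_depth = sowing_depth)
}

#' Validate a daily weather series
#'
#' @param weather Data frame with columns `date` (Date), `tmax`, `tmin`
#'   (degC).  Dates must be strictly consecutive calendar days.
#' @return The validated data frame (invisibly unchanged).
#' @export
validate_weather <- function(weather) {
  need <- c("date", "tmax", "tmin")
  miss <- setdiff(need, names(weather))
  if (length(miss) > 0) {
    stop("weather table is missing column(s): ", paste(miss, collapse = ", "))
  }
  if (nrow(weather) == 0) stop("weather series is empty")
  weather$date <- as.Date(weather$date)
  if (anyNA(weather$date)) stop("weather contains unparseable dates")
  d <- diff(as.integer(weather$date))
  if (any(d == 0)) {
    stop("weather contains duplicated date(s): ",
         paste(weather$date[which(d == 0)], collapse = ", "))
  }
  if (any(d != 1)) {
    i <- which(d != 1)[1]
    stop("weather dates are not consecutive: gap after ", weather$date[i])
  }
  if (anyNA(weather$tmax) || anyNA(weather$tmin) ||
      any(!is.finite(weather$tmax)) || any(!is.finite(weather$tmin))) {
    stop("weather temperatures must be finite")
  }
  if (any(weather$tmax < weather$tmin)) {
    stop("tmax < tmin on ", weather$date[which(weather$tmax < weather$tmin)[1]])
  }
  if (any(abs(weather$tmax) > 60) || any(abs(weather$tmin) > 60)) {
    stop("weather temperatures outside plausible range (|T| <= 60 degC)")
  }
  weather
}

#' Astronomical daylength with optional twilight extension
#'
#' Standard hour-angle daylength: solar declination from the day of year,
#' sunrise/sunset defined by the sun reaching `twilight_angle` degrees of
#' elevation.  `twilight_angle = 0` is geometric sunrise; the default -6
#' (civil twilight) extends the photoperiod as crop models conventionally do.
#'
#' @param latitude Degrees north, in `[-90, 90]`.
#' @param doy Day of year, 1..366 (vectorised).
#' @param twilight_angle Solar elevation angle (degrees) defining day/night;
#'   negative values extend the day.
#' @return Daylength in hours, in `[0, 24]`.
#' @examples
#' daylength(0, 80, twilight_angle = 0)    # ~12 h at the equator
#' daylength(32.06, 172)                   # midsummer at ~32 N
#' @export
daylength <- function(latitude, doy, twilight_angle = -6) {
  if (any(!is.finite(latitude)) || any(abs(latitude) > 90)) {
    stop("latitude must lie in [-90, 90]")
  }
  if (any(doy < 1) || any(doy > 366)) stop("doy must lie in 1..366")
  rad <- pi / 180
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * rad
  lat <- latitude * rad
  a <- twilight_angle * rad
  cosw <- (sin(a) - sin(lat) * sin(decl)) / (cos(lat) * cos(decl))
  cosw <- pmin(pmax(cosw, -1), 1)  # polar day / night
  2 * acos(cosw) / rad / 15
}

#' Thermal development factor from daily temperature extremes
#'
#' Trapezoidal response on the daily mean `(tmax + tmin) / 2` with the given
#' cardinal temperatures.
#'
#' @param tmin,tmax Daily extremes in degC (vectorised), `tmax >= tmin`.
#' @param cardinals From [cardinal_temps()].
#' @return Value(s) in `[0, 1]`.
#' @export
thermal_factor <- function(tmin, tmax, cardinals = cardinal_temps()) {
  if (any(tmax < tmin)) stop("tmax must be >= tmin")
  tm <- (tmax + tmin) / 2
  tb <- cardinals[["t_base"]]
  to1 <- cardinals[["t_opt_lo"]]
  to2 <- cardinals[["t_opt_hi"]]
  tc <- cardinals[["t_ceil"]]
  f <- numeric(length(tm))
  rising <- tm > tb & tm < to1
  f[rising] <- (tm[rising] - tb) / (to1 - tb)
  f[tm >= to1 & tm <= to2] <- 1
  falling <- tm > to2 & tm < tc
  f[falling] <- (tc - tm[falling]) / (tc - to2)
  f
}

#' Photoperiod development factor for a short-day crop
#'
#' `1` at daylengths at or below the critical short day; above it the factor
#' declines linearly at `ppsen` per hour, floored at 0.
#'
#' @param dl Daylength in hours (vectorised).
#' @param csdl Critical short day (hours).
#' @param ppsen Photoperiod sensitivity (1/hour), positive.
#' @return Value(s) in `[0, 1]`, non-increasing in `dl`.
#' @export
photoperiod_factor <- function(dl, csdl, ppsen) {
  if (ppsen <= 0) stop("ppsen must be positive")
  pmin(pmax(1 - ppsen * (dl - csdl), 0), 1)
}

#' Daily photothermal increment
#'
#' One day at optimal temperature under non-limiting photoperiod contributes
#' one photothermal day; otherwise the product of the two factors.
#'
#' @param tf Thermal factor in `[0, 1]`.
#' @param pf Photoperiod factor in `[0, 1]`.
#' @return `tf * pf`, in `[0, 1]`.
#' @export
photothermal_increment <- function(tf, pf) {
  if (any(tf < 0 | tf > 1) || any(pf < 0 | pf > 1)) {
    stop("factors must lie in [0, 1]")
  }
  tf * pf
}

#' Precompute parameter-independent forcing for a site and season
#'
#' Computes, once per (weather, site) pair, the daily thermal factor and
#' daylength over the simulation window and the emergence date (emergence is
#' driven by temperature only, with threshold `e_base + e_slope * depth`
#' photothermal days accumulated from the day after sowing).  The result can
#' be reused across thousands of candidate parameter vectors during
#' calibration.
#'
#' @param weather Daily weather data frame (see [validate_weather()]).
#' @param site From [site_sowing()].
#' @param cardinals From [cardinal_temps()].
#' @param twilight_angle Degrees; see [daylength()].
#' @param horizon Days after sowing within which all stages must occur.
#' @param e_base,e_slope Emergence threshold intercept (photothermal days)
#'   and slope per cm of sowing depth.
#' @return A `soycal_forcing` list: `dates`, `doy`, `dl`, `tf`, `sow_idx`,
#'   `emerge_idx` (NA if emergence not reached), `horizon`, `site`.
#' @export
make_forcing <- function(weather, site, cardinals = cardinal_temps(),
                         twilight_angle = -6, horizon = 200,
                         e_base = 3.0, e_slope = 0.1) {
  weather <- validate_weather(weather)
  sow <- site$sowing_date
  idx <- match(sow, weather$date)
  if (is.na(idx)) stop("sowing_date not covered by the weather series")
  last_needed <- sow + horizon
  if (weather$date[nrow(weather)] < last_needed) {
    stop("weather series must cover sowing_date + horizon (through ",
         last_needed, ")")
  }
  keep <- idx:match(last_needed, weather$date)
  w <- weather[keep, , drop = FALSE]
  doy <- as.integer(format(w$date, "%j"))
  dl <- daylength(site$latitude, doy, twilight_angle)
  tf <- thermal_factor(w$tmin, w$tmax, cardinals)
  e_thresh <- e_base + e_slope * site$sowing_depth
  n <- nrow(w)
  emerge_idx <- NA_integer_
  if (n >= 2) {
    acc <- cumsum(tf[2:n])
    hit <- which(acc >= e_thresh)
    if (length(hit) > 0) emerge_idx <- 1L + hit[1]
  }
  structure(list(dates = w$date, doy = doy, dl = dl, tf = tf,
                 sow_idx = 1L, emerge_idx = emerge_idx, horizon = horizon,
                 site = site),
            class = "soycal_forcing")
}

# Stage indices within a forcing window for one candidate parameter vector.
# Returns integer vector (fs, ps, gs, ms); NA from the first unreached stage
# onward (emergence failure gives all NA).  Accumulation for each phase
# starts the day after the phase-opening event; a stage is the first day on
# which the accumulator meets or exceeds the phase duration.
stage_indices <- function(forcing, params) {
  out <- rep(NA_integer_, 4L)
  e <- forcing$emerge_idx
  if (is.na(e)) return(out)
  n <- length(forcing$tf)
  if (e >= n) return(out)
  dl <- forcing$dl
  tf <- forcing$tf
  pf_pre <- pmin(pmax(1 - params[["ppsen"]] * (dl - params[["csdl"]]), 0), 1)
  cs1 <- cumsum(tf * pf_pre)
  hit <- which(cs1[(e + 1L):n] - cs1[e] >= params[["em_fl"]])
  if (length(hit) == 0) return(out)
  fs <- e + hit[1]
  out[1] <- fs
  if (fs >= n) return(out)
  csdl_post <- params[["csdl"]] - params[["r1ppo"]]
  pf_post <- pmin(pmax(1 - params[["ppsen"]] * (dl - csdl_post), 0), 1)
  cs2 <- cumsum(tf * pf_post)
  post <- cs2[(fs + 1L):n] - cs2[fs]
  hit <- which(post >= params[["fl_sh"]])
  if (length(hit) == 0) return(out)
  out[2] <- fs + hit[1]
  hit <- which(post >= params[["fl_sd"]])
  if (length(hit) == 0) return(out)
  gs <- fs + hit[1]
  out[3] <- gs
  if (gs >= n) return(out)
  hit <- which(cs2[(gs + 1L):n] - cs2[gs] >= params[["sd_pm"]])
  if (length(hit) == 0) return(out)
  out[4] <- gs + hit[1]
  names(out) <- STAGE_NAMES
  out
}

# Stage day-of-year vector (named fs/ps/gs/ms), NA where unreached.
# Day-of-year is counted past Dec 31 (367, 368, ...) when the season crosses
# the year boundary, so stage values stay monotone within a season.
stage_doy <- function(forcing, params) {
  idx <- stage_indices(forcing, params)
  first_doy <- as.integer(format(forcing$dates[1], "%j"))
  doy <- first_doy + (idx - 1L)
  names(doy) <- STAGE_NAMES
  doy
}

#' Simulate the four phenological stages
#'
#' Predicts first flowering (FS), first pod (PS), first grain (GS) and first
#' maturity (MS) by photothermal-day accumulation.  Daily development rate is
#' `thermal_factor * photoperiod_factor`; a phase completes on the first day
#' its accumulated rate reaches the phase duration.  Before first flowering
#' the photoperiod factor uses `csdl`; from the day after FS the effective
#' critical short day tightens to `csdl - r1ppo`.  Emergence is thermal-only
#' (see [make_forcing()]).
#'
#' @param weather Daily weather data frame, or a precomputed
#'   `soycal_forcing` object (then `site`, `cardinals`, `twilight_angle`,
#'   `horizon` are ignored).
#' @param site From [site_sowing()].
#' @param params From [cultivar_params()] (or a named vector in canonical
#'   order).
#' @param cardinals,twilight_angle,horizon See [make_forcing()].
#' @return A list with `dates` (Date, named fs/ps/gs/ms), `doy` (day of
#'   year, counted past 366 when the season crosses Dec 31), and
#'   `days_after_sowing`.
#' @examples
#' w <- data.frame(date = seq(as.Date("2019-06-01"), by = 1, length.out = 250),
#'                 tmax = 30, tmin = 22)
#' s <- site_sowing(32.06, "2019-06-21")
#' p <- cultivar_params(12.5, 0.3, 0.3, 20, 7, 14, 13)
#' simulate_stages(w, s, p)
#' @export
simulate_stages <- function(weather, site = NULL, params,
                            cardinals = cardinal_temps(),
                            twilight_angle = -6, horizon = 200) {
  forcing <- if (inherits(weather, "soycal_forcing")) weather else
    make_forcing(weather, site, cardinals, twilight_angle, horizon)
  idx <- stage_indices(forcing, params)
  if (anyNA(idx)) {
    stage <- c("FS", "PS", "GS", "MS")[which(is.na(idx))[1]]
    cond <- structure(
      class = c("soycal_stage_not_reached", "error", "condition"),
      list(message = paste0("stage ", stage, " not reached within ",
                            forcing$horizon, " days of sowing"),
           call = sys.call(-1), stage = stage))
    stop(cond)
  }
  dates <- forcing$dates[idx]
  names(dates) <- STAGE_NAMES
  first_doy <- as.integer(format(forcing$dates[1], "%j"))
  doy <- first_doy + (idx - 1L)
  names(doy) <- STAGE_NAMES
  das <- idx - forcing$sow_idx
  names(das) <- STAGE_NAMES
  list(dates = dates, doy = doy, days_after_sowing = das)
}
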