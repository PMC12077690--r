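#' Generate a synthetic daily weather series
#'
#' A minimal temperate-climate emulator: daily mean temperature follows a
#' sinusoidal annual cycle peaking in midsummer for the site's hemisphere;
#' daily extremes are the mean plus/minus half the diurnal range plus
#' independent Gaussian noise, re-ordered so `tmax >= tmin`.  Two calendar
#' years are produced (the sowing year and the next) so late-sown seasons
#' that cross the year boundary stay covered.
#'
#' @param latitude Degrees north (sets the phase of the annual cycle).
#' @param year First calendar year of the series.
#' @param mean_annual_t Annual mean temperature (degC).
#' @param seasonal_amplitude Half peak-to-trough amplitude of the annual
#'   cycle (degC).
#' @param diurnal_range Mean `tmax - tmin` (degC, > 0).
#' @param noise_sd Standard deviation of daily Gaussian noise (degC).
#' @param seed Optional seed; `NULL` uses the current RNG state.
#' @return A weather data frame (`date`, `tmax`, `tmin`).
#' @export
gen_weather <- function(latitude, year, mean_annual_t = 16,
                        seasonal_amplitude = 11, diurnal_range = 8,
                        noise_sd = 1.5, seed = NULL) {
  if (diurnal_range <= 0) stop("diurnal_range must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  if (!is.null(seed)) set.seed(seed)
  dates <- seq(as.Date(sprintf("%d-01-01", year)),
               as.Date(sprintf("%d-12-31", year + 1)), by = 1)
  doy <- as.integer(format(dates, "%j"))
  peak <- if (latitude >= 0) 197 else 15  # mid-July vs mid-January
  tmean <- mean_annual_t +
    seasonal_amplitude * cos(2 * pi * (doy - peak) / 365.25)
  n <- length(dates)
  hi <- tmean + diurnal_range / 2 + stats::rnorm(n, 0, noise_sd)
  lo <- tmean - diurnal_range / 2 + stats::rnorm(n, 0, noise_sd)
  data.frame(date = dates, tmax = pmax(hi, lo), tmin = pmin(hi, lo))
}

#' Sample "true" cultivar parameter vectors
#'
#' Uniform draws over the calibration ranges, one row per cultivar, labelled
#' C1, C2, ...
#'
#' @param n_cultivars Number of cultivars.
#' @param bounds Bounds matrix.
#' @return An `n x 7` matrix with rownames `C1..Cn`.
#' @export
sample_true_csps <- function(n_cultivars, bounds = csp_bounds()) {
  m <- initialize_population(n_cultivars, bounds)
  rownames(m) <- paste0("C", seq_len(n_cultivars))
  m
}

#' Generate noisy stage observations from a true parameter vector
#'
#' Runs the forward model and adds integer-rounded Gaussian noise to each
#' stage date (field phenology is scored on whole days).  The noisy set is
#' re-drawn until it respects the stage ordering `fs <= ps <= gs < ms`.
#' With `noise_days = 0` the observations equal the forward predictions.
#'
#' @param forcing From [make_forcing()].
#' @param truth True cultivar parameter vector.
#' @param noise_days Standard deviation of the observation noise (days).
#' @param max_tries Re-draw budget before giving up on the ordering repair.
#' @return Named numeric stage vector (day of year, counted past Dec 31
#'   for cross-year seasons).
#' @export
gen_observations <- function(forcing, truth, noise_days = 0,
                             max_tries = 1000) {
  sim <- stage_doy(forcing, truth)
  if (anyNA(sim)) {
    stage <- c("FS", "PS", "GS", "MS")[which(is.na(sim))[1]]
    stop("stage ", stage, " not reached for the true parameters")
  }
  if (noise_days == 0) return(sim)
  for (try in seq_len(max_tries)) {
    obs <- sim + round(stats::rnorm(4, 0, noise_days))
    if (obs[1] <= obs[2] && obs[2] <= obs[3] && obs[3] < obs[4]) return(obs)
  }
  stop("could not generate ordered observations in ", max_tries, " tries")
}

#' Build the three-experiment synthetic calibration suite
#'
#' Emulates the field-trial structure used throughout the package: two sites
#' on the lower Yangtze (about 31.57 N and 32.06 N), three experiments
#' (site A sown 5 July of year 1; site B sown 21 June of year 2; site A sown
#' 24 June of year 2), nine cultivars shared across experiments, and the
#' four stages FS/PS/GS/MS observed in each.  True cultivar parameters are
#' drawn uniformly from the calibration ranges and re-drawn (rejection
#' sampling) until the forward model reaches maturity within the horizon in
#' all three experiments.  The calibration/evaluation pairing is: experiment
#' 1 cultivars C1-C3 evaluated on experiment 2; experiment 2 C4-C6 on
#' experiment 3; experiment 3 C7-C9 on experiment 1.
#'
#' @param seed Top-level seed; the whole suite is reproducible from it.
#' @param noise_days Observation noise (days); 0 gives noise-free truth.
#' @param n_cultivars Number of cultivars (default 9; the pairing table
#'   requires a multiple of 3).
#' @param year First experiment year.
#' @param horizon Simulation horizon (days after sowing).
#' @param cardinals,twilight_angle Forward-model constants.
#' @param sowing_depth Sowing depth in cm (row planting at 3 cm).
#' @return A `soycal_suite` list: `experiments` (each with `site`,
#'   `weather`, `forcing`), `truth` (cultivar x parameter matrix),
#'   `observations` (data frame `experiment`, `cultivar`, `stage`, `doy`,
#'   `date`), `pairing` (data frame `id`, `calib_exp`, `eval_exp` plus a
#'   `cultivars` list-column), `noise_days`, `seed`.
#' @export
build_experiment_suite <- function(seed, noise_days = 2, n_cultivars = 9,
                                   year = 2018, horizon = 200,
                                   cardinals = cardinal_temps(),
                                   twilight_angle = -6, sowing_depth = 3) {
  if (n_cultivars %% 3 != 0) stop("n_cultivars must be a multiple of 3")
  set.seed(seed)
  lat_a <- 31.571   # site A, Dangtu-like
  lat_b <- 32.059   # site B, Nanjing-like
  site_defs <- list(
    list(lat = lat_a, sowing = as.Date(sprintf("%d-07-05", year))),
    list(lat = lat_b, sowing = as.Date(sprintf("%d-06-21", year + 1))),
    list(lat = lat_a, sowing = as.Date(sprintf("%d-06-24", year + 1))))
  weather_a1 <- gen_weather(lat_a, year)
  weather_b2 <- gen_weather(lat_b, year + 1)
  weather_a2 <- gen_weather(lat_a, year + 1)
  weathers <- list(weather_a1, weather_b2, weather_a2)
  experiments <- vector("list", 3)
  for (e in 1:3) {
    site <- site_sowing(site_defs[[e]]$lat, site_defs[[e]]$sowing,
                        sowing_depth)
    experiments[[e]] <- list(
      name = paste0("Exp", e), site = site, weather = weathers[[e]],
      forcing = make_forcing(weathers[[e]], site, cardinals,
                             twilight_angle, horizon))
  }
  # rejection-sample cultivars viable in all three experiments
  truth <- matrix(0, n_cultivars, length(CSP_NAMES),
                  dimnames = list(paste0("C", seq_len(n_cultivars)),
                                  CSP_NAMES))
  got <- 0L
  tries <- 0L
  while (got < n_cultivars) {
    tries <- tries + 1L
    if (tries > 1000L * n_cultivars) {
      stop("could not sample viable cultivars for this suite")
    }
    cand <- initialize_population(1, csp_bounds())[1, ]
    ok <- all(vapply(experiments,
                     function(ex) !anyNA(stage_indices(ex$forcing, cand)),
                     logical(1)))
    if (ok) {
      got <- got + 1L
      truth[got, ] <- cand
    }
  }
  obs_rows <- list()
  for (e in 1:3) {
    for (ci in seq_len(n_cultivars)) {
      o <- gen_observations(experiments[[e]]$forcing, truth[ci, ],
                            noise_days)
      first_date <- experiments[[e]]$forcing$dates[1]
      first_doy <- as.integer(format(first_date, "%j"))
      obs_rows[[length(obs_rows) + 1]] <- data.frame(
        experiment = e, cultivar = rownames(truth)[ci],
        stage = c("FS", "PS", "GS", "MS"), doy = as.numeric(o),
        date = first_date + (o - first_doy))
    }
  }
  observations <- do.call(rbind, obs_rows)
  groups <- split(seq_len(n_cultivars),
                  rep(1:3, each = n_cultivars / 3))
  pairing <- data.frame(id = 1:3, calib_exp = c(1, 2, 3),
                        eval_exp = c(2, 3, 1))
  pairing$cultivars <- lapply(1:3, function(i) {
    paste0("C", groups[[i]])
  })
  structure(list(experiments = experiments, truth = truth,
                 observations = observations, pairing = pairing,
                 noise_days = noise_days, seed = seed,
                 horizon = horizon),
            class = "soycal_suite")
}

#' Extract one cultivar's observed stage vector from a suite
#'
#' @param suite From [build_experiment_suite()].
#' @param experiment Experiment index (1..3).
#' @param cultivar Cultivar label, e.g. `"C1"`.
#' @return Named stage vector (`fs`, `ps`, `gs`, `ms`), day of year.
#' @export
suite_observed <- function(suite, experiment, cultivar) {
  rows <- suite$observations[suite$observations$experiment == experiment &
                             suite$observations$cultivar == cultivar, ]
  if (nrow(rows) != 4) stop("no complete observation set for ", cultivar,
                            " in experiment ", experiment)
  o <- rows$doy[match(c("FS", "PS", "GS", "MS"), rows$stage)]
  names(o) <- STAGE_NAMES
  o
}
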