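# Shared fixtures and independent oracles for the test suite.

# Weather at constant optimal temperature (thermal factor 1 by default).
const_weather <- function(start = "2019-06-01", n = 260, tmax = 30,
                          tmin = 22) {
  data.frame(date = seq(as.Date(start), by = 1, length.out = n),
             tmax = tmax, tmin = tmin)
}

# A mid-latitude forcing used across calibration tests.
test_forcing <- function(lat = 32.06, sowing = "2019-06-21", ...) {
  make_forcing(const_weather(), site_sowing(lat, sowing), ...)
}

# Independent daylength oracle: brute-force scan of the solar elevation
# over the day; daylength = fraction of time the sun is above the
# twilight elevation.  Shares only the declination formula with the
# implementation; the hour-angle solution is replaced by numerical search.
oracle_daylength <- function(latitude, doy, twilight_angle = -6,
                             n_steps = 200000) {
  rad <- pi / 180
  decl <- 23.45 * sin(2 * pi * (284 + doy) / 365) * rad
  h <- seq(-pi, pi, length.out = n_steps)  # hour angle through the day
  sin_elev <- sin(latitude * rad) * sin(decl) +
    cos(latitude * rad) * cos(decl) * cos(h)
  up <- sin_elev > sin(twilight_angle * rad)
  24 * mean(up)
}

# Independent forward-model oracle: naive day-by-day loop applying the
# documented accumulation rules one day at a time, no cumsum machinery.
oracle_stage_indices <- function(forcing, params) {
  n <- length(forcing$tf)
  pf <- function(dl, csdl) min(max(1 - params[["ppsen"]] * (dl - csdl), 0), 1)
  out <- rep(NA_integer_, 4)
  e <- forcing$emerge_idx
  if (is.na(e)) return(out)
  acc <- 0; fs <- NA
  for (j in seq(e + 1, n)) {
    acc <- acc + forcing$tf[j] * pf(forcing$dl[j], params[["csdl"]])
    if (acc >= params[["em_fl"]]) { fs <- j; break }
  }
  if (is.na(fs)) return(out)
  out[1] <- fs
  csdl2 <- params[["csdl"]] - params[["r1ppo"]]
  acc <- 0; ps <- NA; gs <- NA
  if (fs < n) {
    for (j in seq(fs + 1, n)) {
      acc <- acc + forcing$tf[j] * pf(forcing$dl[j], csdl2)
      if (is.na(ps) && acc >= params[["fl_sh"]]) ps <- j
      if (acc >= params[["fl_sd"]]) { gs <- j; break }
    }
  }
  if (is.na(ps)) return(out)
  out[2] <- ps
  if (is.na(gs)) return(out)
  out[3] <- gs
  acc <- 0
  if (gs < n) {
    for (j in seq(gs + 1, n)) {
      acc <- acc + forcing$tf[j] * pf(forcing$dl[j], csdl2)
      if (acc >= params[["sd_pm"]]) { out[4] <- j; break }
    }
  }
  out
}

# Brute-force non-dominated ranking: repeatedly peel the set of
# individuals not dominated by any remaining individual.
oracle_pareto_ranks <- function(objectives) {
  n <- nrow(objectives)
  rank <- integer(n)
  remaining <- seq_len(n)
  r <- 1L
  dominates_pair <- function(a, b) all(a <= b) && any(a < b)
  while (length(remaining) > 0) {
    nd <- vapply(remaining, function(i) {
      !any(vapply(remaining, function(j) {
        j != i && dominates_pair(objectives[j, ], objectives[i, ])
      }, logical(1)))
    }, logical(1))
    rank[remaining[nd]] <- r
    remaining <- remaining[!nd]
    r <- r + 1L
  }
  rank
}

# Random cultivar parameter vector inside the calibration box.
random_params <- function() {
  b <- csp_bounds()
  stats::setNames(stats::runif(7, b[, 1], b[, 2]), rownames(b))
}

# Run one algorithm with the blocks of a run-config list and a given seed.
run_algorithm_acc <- function(alg, forcing, obs, cfg, seed) {
  soycal:::run_algorithm(alg, forcing, obs,
                         soycal:::algo_config(alg, cfg[[alg]], seed))
}
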