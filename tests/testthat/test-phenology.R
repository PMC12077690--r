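test_that("daylength matches solar geometry", {
  # equatorial symmetry: 12 h at zero twilight angle on any day
  for (doy in c(1, 80, 172, 355)) {
    expect_equal(daylength(0, doy, twilight_angle = 0), 12, tolerance = 1e-9)
  }
  # northern-hemisphere summer day is longer than winter day
  expect_gt(daylength(45, 172), daylength(45, 355))
  # against the brute-force solar-elevation oracle
  for (case in list(c(32.06, 172, -6), c(32.06, 300, -6), c(45, 80, 0),
                    c(-35, 172, -6))) {
    expect_equal(daylength(case[1], case[2], case[3]),
                 oracle_daylength(case[1], case[2], case[3]),
                 tolerance = 1e-3)
  }
  # bounded and defined at the poles (polar day/night clamp)
  expect_equal(daylength(90, 172, 0), 24)
  expect_equal(daylength(90, 355, 0), 0)
  expect_error(daylength(91, 100), "latitude")
})

test_that("thermal factor is the documented trapezoid", {
  card <- cardinal_temps(6, 26, 30, 45)
  # plateau, base, ceiling
  expect_equal(thermal_factor(26, 26, card), 1)
  expect_equal(thermal_factor(2, 10, card), 0)       # mean = t_base
  expect_equal(thermal_factor(45, 45, card), 0)
  # halfway up the rising limb: mean (6+26)/2 = 16 -> 0.5
  expect_equal(thermal_factor(16, 16, card), 0.5)
  # halfway down the falling limb: mean 37.5 -> 0.5
  expect_equal(thermal_factor(35, 40, card), 0.5)
  expect_error(thermal_factor(20, 10), "tmax")
  expect_error(cardinal_temps(30, 26, 28, 45), "cardinal")
})

test_that("photoperiod factor is clamped, linear and non-increasing", {
  expect_equal(photoperiod_factor(12.0, csdl = 12.5, ppsen = 0.2), 1)
  expect_equal(photoperiod_factor(13.5, csdl = 12.5, ppsen = 0.2), 0.8)
  # zero crossing at csdl + 1/ppsen
  expect_equal(photoperiod_factor(12.5 + 1 / 0.2, csdl = 12.5, ppsen = 0.2), 0)
  dl <- seq(10, 20, by = 0.1)
  f <- photoperiod_factor(dl, 12.5, 0.2)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(photoperiod_factor(12, 12.5, -0.1), "ppsen")
})

test_that("photothermal increment is the product of the two factors", {
  expect_equal(photothermal_increment(0, 1), 0)
  expect_equal(photothermal_increment(1, 1), 1)
  expect_equal(photothermal_increment(0.5, 0.8), 0.4)
  expect_error(photothermal_increment(1.2, 0.5), "0, 1")
})

test_that("unit daily rate gives stage dates equal to phase durations", {
  # constant optimal temperature and short days -> tf = pf = 1 every day
  w <- const_weather(tmax = 30, tmin = 22)
  site <- site_sowing(0, "2019-06-21", sowing_depth = 3)  # equator: 12 h days
  p <- cultivar_params(14.6, 0.129, 0.2, 20, 7, 14, 13, strict = FALSE)
  f <- make_forcing(w, site, twilight_angle = 0)
  # emergence threshold 3 + 0.1*3 = 3.3 -> day 4 after sowing
  expect_equal(f$emerge_idx, 1 + 4)
  res <- simulate_stages(f, params = p)
  das <- res$days_after_sowing
  expect_equal(unname(das["fs"]), 4 + 20)
  expect_equal(unname(das["ps"] - das["fs"]), 7)
  expect_equal(unname(das["gs"] - das["fs"]), 14)
  expect_equal(unname(das["ms"] - das["gs"]), 13)
})

test_that("a hand-traced short series reproduces the day-by-day accumulation", {
  # 3 optimal days then cooler days: tf = 1, 1, 1, 0.5, 0.5, ...
  w <- const_weather(n = 120)
  w$tmax[4:120] <- 16; w$tmin[4:120] <- 16  # mean 16 -> tf 0.5
  site <- site_sowing(0, w$date[1], sowing_depth = 2)  # threshold 3.2
  f <- make_forcing(w, site, twilight_angle = 0, horizon = 110)
  # emergence: tf from day 2: 1+1+0.5 = 2.5 (day 4), +0.5 = 3.0 (day 5),
  # +0.5 = 3.5 >= 3.2 on day 6
  expect_equal(f$emerge_idx, 6)
  p <- cultivar_params(14.6, 0.129, 0.2, em_fl = 2.2, fl_sh = 1.0,
                       fl_sd = 1.4, sd_pm = 1.0, strict = FALSE)
  idx <- soycal:::stage_indices(f, p)
  # after emergence every day adds 0.5: fs at +5 days (2.5 >= 2.2),
  # ps at +2 (1.0 >= 1.0), gs at +3 (1.5 >= 1.4), ms at +2
  expect_equal(unname(idx), c(11, 13, 14, 16))
})

test_that("forward model agrees exactly with the naive day-loop oracle", {
  suite <- build_experiment_suite(seed = 5, noise_days = 0)
  forcings <- lapply(suite$experiments, `[[`, "forcing")
  set.seed(99)
  for (i in 1:100) {
    p <- random_params()
    f <- forcings[[sample.int(3, 1)]]
    expect_identical(unname(soycal:::stage_indices(f, p)),
                     unname(oracle_stage_indices(f, p)))
  }
})

test_that("stage ordering and parameter monotonicity hold", {
  f <- test_forcing()
  set.seed(7)
  for (i in 1:50) {
    p <- random_params()
    idx <- soycal:::stage_indices(f, p)
    if (anyNA(idx)) next
    expect_true(idx[1] <= idx[2] && idx[2] <= idx[3] && idx[3] < idx[4])
    # longer phase durations never advance the corresponding stage
    p2 <- p; p2[["em_fl"]] <- min(p[["em_fl"]] + 2, 28.9)
    idx2 <- soycal:::stage_indices(f, p2)
    if (!is.na(idx2[1])) expect_gte(idx2[1], idx[1])
    p3 <- p; p3[["sd_pm"]] <- min(p[["sd_pm"]] + 2, 16)
    idx3 <- soycal:::stage_indices(f, p3)
    if (!is.na(idx3[4])) expect_gte(idx3[4], idx[4])
  }
})

test_that("stronger photoperiod sensitivity never advances flowering", {
  # all daylengths above csdl in midsummer at 45 N
  f <- make_forcing(const_weather(), site_sowing(45, "2019-06-21"))
  p <- cultivar_params(11.78, 0.2, 0.3, 20, 7, 14, 13)
  fs1 <- soycal:::stage_indices(f, p)[1]
  p[["ppsen"]] <- 0.35
  fs2 <- soycal:::stage_indices(f, p)[1]
  expect_true(is.na(fs2) || fs2 >= fs1)
})

test_that("stage-not-reached is a typed error naming the stage", {
  w <- const_weather(n = 120)
  site <- site_sowing(32, "2019-06-21")
  p <- cultivar_params(12.5, 0.3, 0.3, 28.9, 10, 16, 16)
  err <- tryCatch(
    simulate_stages(w, site, p, horizon = 60),
    soycal_stage_not_reached = function(e) e)
  expect_s3_class(err, "soycal_stage_not_reached")
  expect_match(conditionMessage(err), "FS|PS|GS|MS")
})

test_that("weather validation rejects malformed series", {
  w <- const_weather(n = 10)
  expect_silent(validate_weather(w))
  expect_error(validate_weather(w[-3, ]), "consecutive")
  expect_error(validate_weather(rbind(w, w[10, ])), "duplicated")
  w2 <- w; w2$tmax[2] <- w2$tmin[2] - 1
  expect_error(validate_weather(w2), "tmax < tmin")
  w3 <- w; w3$tmin[5] <- -100
  expect_error(validate_weather(w3), "plausible")
  expect_error(validate_weather(w[, c("date", "tmax")]), "tmin")
})

test_that("cultivar parameter validation enforces the calibration box", {
  expect_error(cultivar_params(11.0, 0.2, 0.3, 20, 7, 14, 13), "csdl")
  expect_error(cultivar_params(12, 0.2, 0.3, 20, 7, 14, -1), "positive")
  p <- cultivar_params(11.0, 0.2, 0.3, 20, 7, 14, 13, strict = FALSE)
  expect_equal(unname(p["csdl"]), 11.0)
})
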