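test_that("population initialisation is uniform within bounds and seeded", {
  b <- csp_bounds()
  # point bounds collapse to the single vector
  bp <- cbind(lower = b[, 1], upper = b[, 1])
  expect_equal(unname(initialize_population(1, bp)[1, ]), unname(b[, 1]))
  expect_error(initialize_population(3, b[, 2:1]), "degenerate")
  set.seed(4); p1 <- initialize_population(50)
  set.seed(4); p2 <- initialize_population(50)
  expect_identical(p1, p2)
  set.seed(8)
  big <- initialize_population(10000)
  expect_true(all(sweep(big, 2, b[, 1], ">=")) &&
                all(sweep(big, 2, b[, 2], "<=")))
  # per-coordinate uniformity: chi-squared on 10 equal-probability bins
  for (k in 1:7) {
    u <- (big[, k] - b[k, 1]) / (b[k, 2] - b[k, 1])
    ct <- table(cut(u, seq(0, 1, 0.1)))
    expect_gt(stats::chisq.test(ct)$p.value, 1e-4)
  }
})

test_that("stage error objectives are absolute day errors with penalty", {
  o <- c(fs = 200, ps = 210, gs = 215, ms = 240)
  expect_equal(stage_error_objectives(o, o), c(0, 0, 0, 0))
  expect_equal(stage_error_objectives(o, c(198, 210, 216, 244)),
               c(2, 0, 1, 4))
  expect_equal(stage_error_objectives(o, c(198, NA, 216, 244), horizon = 150),
               rep(150, 4))
  expect_error(stage_error_objectives(o[1:3], o[1:3]), "four")
})

test_that("dominance is componentwise with one strict inequality", {
  expect_true(dominates(c(1, 1, 1, 1), c(2, 2, 2, 2)))
  expect_false(dominates(c(1, 2), c(2, 1)))
  expect_false(dominates(c(1, 2), c(1, 2)))
  expect_true(dominates(c(1, 2), c(1, 3)))
  expect_error(dominates(c(1, 2), c(1, 2, 3)), "length")
})

test_that("fast non-dominated sort matches the worked partition", {
  obj <- rbind(c(1, 5), c(2, 3), c(4, 1), c(3, 4), c(5, 5))
  srt <- fast_nondominated_sort(obj)
  expect_equal(sort(srt$fronts[[1]]), c(1, 2, 3))
  expect_equal(srt$fronts[[2]], 4)
  expect_equal(srt$fronts[[3]], 5)
  expect_equal(srt$rank, c(1, 1, 1, 2, 3))
  # degenerate cases
  expect_equal(fast_nondominated_sort(rbind(c(1, 1)))$rank, 1L)
  srt2 <- fast_nondominated_sort(rbind(c(2, 2), c(1, 1)))
  expect_equal(srt2$rank, c(2L, 1L))
  expect_error(fast_nondominated_sort(rbind(c(1, NA))), "evaluated")
})

test_that("fast non-dominated sort matches the brute-force classifier", {
  set.seed(21)
  for (rep in 1:10) {
    obj <- matrix(sample.int(12, 60 * 4, replace = TRUE), 60, 4)
    srt <- fast_nondominated_sort(obj)
    expect_identical(srt$rank, oracle_pareto_ranks(obj))
    # partition is exhaustive and disjoint
    expect_setequal(unlist(srt$fronts), 1:60)
    # front members are mutually non-dominated
    f1 <- srt$fronts[[1]]
    for (i in f1) for (j in f1) {
      if (i != j) expect_false(dominates(obj[i, ], obj[j, ]))
    }
  }
})

test_that("crowding distance follows the boundary and gap rules", {
  expect_equal(crowding_distance(rbind(c(1, 2))), Inf)
  expect_equal(crowding_distance(rbind(c(1, 2), c(2, 1))), c(Inf, Inf))
  # one varying objective (values 1, 2, 4): middle distance = 3/3 = 1
  obj <- cbind(c(1, 2, 4), c(5, 5, 5))
  expect_equal(crowding_distance(obj), c(Inf, 1, Inf))
  # duplicated objective vectors: finite zero interior distance, no NaN
  dup <- rbind(c(1, 1), c(1, 1), c(1, 1))
  expect_equal(crowding_distance(dup), c(Inf, 0, Inf))
})

test_that("tournament selection prefers rank then crowding", {
  rank <- c(1, 2, 1, 1)
  crowd <- c(Inf, 1, 0.5, 0.5)
  expect_equal(soycal:::tournament_pick(1, 2, rank, crowd), 1)
  expect_equal(soycal:::tournament_pick(1, 3, rank, crowd), 1)
  set.seed(1)
  picks <- replicate(200, soycal:::tournament_pick(3, 4, rank, crowd))
  expect_setequal(unique(picks), c(3, 4))  # full tie: both reachable
})

test_that("SBX respects pc, bounds, and concentrates with eta_c", {
  b <- csp_bounds()
  set.seed(3)
  p1 <- random_params(); p2 <- random_params()
  kids <- sbx_crossover(p1, p2, pc = 0)
  expect_identical(kids[[1]], p1)
  expect_identical(kids[[2]], p2)
  set.seed(5)
  spread <- sapply(c(2, 20, 200), function(eta) {
    d <- replicate(400, {
      k <- sbx_crossover(p1, p2, eta_c = eta, pc = 1)
      mean(abs(k[[1]] - p1))
    })
    mean(d)
  })
  expect_true(all(diff(spread) < 0))  # larger eta -> children nearer parents
  set.seed(6)
  for (i in 1:500) {
    k <- sbx_crossover(random_params(), random_params(), pc = 1)
    for (child in k) {
      expect_true(all(child >= b[, 1] & child <= b[, 2]))
    }
  }
})

test_that("polynomial mutation respects pm and bounds", {
  b <- csp_bounds()
  p <- random_params()
  expect_identical(polynomial_mutation(p, pm = 0), p)
  set.seed(9)
  n_changed <- replicate(3000, sum(polynomial_mutation(p, pm = 1 / 7) != p))
  expect_equal(mean(n_changed) / 7, 1 / 7, tolerance = 0.15)
  set.seed(10)
  for (i in 1:500) {
    y <- polynomial_mutation(random_params(), pm = 1)
    expect_true(all(y >= b[, 1] & y <= b[, 2]))
  }
})

test_that("environmental selection fills by front and truncates by crowding", {
  # front 1 = {A}, front 2 = {B, C, D}; B has the larger crowding gap
  obj <- rbind(A = c(0, 0), B = c(1, 5), C = c(3, 3), D = c(5, 1))
  keep <- environmental_selection(obj, 2)
  expect_equal(as.integer(keep[1]), 1L)
  expect_true(keep[2] %in% c(2, 4))  # boundary members (Inf crowding) win
  expect_length(environmental_selection(obj, 3), 3)
  # never discards an individual that dominates a retained one
  set.seed(12)
  for (rep in 1:20) {
    o <- matrix(stats::runif(40), 20, 2)
    keep <- environmental_selection(o, 10)
    drop <- setdiff(1:20, keep)
    for (d in drop) for (k in keep) {
      expect_false(dominates(o[d, ], o[k, ]))
    }
  }
})

test_that("PEST objective is the weighted sum of squared residuals", {
  expect_equal(pest_phi(c(1, 2), c(1, 2)), 0)
  expect_equal(pest_phi(c(1, 2), c(0, 0)), 5)
  expect_equal(pest_phi(c(1, 2), c(0, 0), weights = c(2, 1)), 8)
  expect_error(pest_phi(1:3, 1:2), "length")
})

test_that("total relative error matches the worked examples", {
  expect_equal(err_tol(c(100, 110, 120, 130), c(100, 110, 120, 130)), 0)
  expect_equal(err_tol(c(100, 110, 120, 130), c(90, 110, 120, 130)), 0.1)
  expect_equal(err_tol(c(50, 100, 150, 200), c(55, 90, 150, 200)), 0.2)
  expect_error(err_tol(c(0, 1, 2, 3), c(1, 1, 2, 3)), "non-zero")
})

test_that("optimal selection minimises err_tol with phi tie-break", {
  obs <- c(fs = 100, ps = 110, gs = 120, ms = 130)
  params <- rbind(a = rep(1, 7), b = rep(2, 7), c = rep(3, 7))
  sims <- rbind(c(90, 110, 120, 130),    # err_tol 0.10
                c(95, 110, 120, 130),    # err_tol 0.05 <- best
                c(100, 104.5, 120, 130)) # err_tol 0.05 but larger phi?
  # row 2: phi = 25; row 3: err_tol 5.5/110 = 0.05, phi = 30.25
  expect_equal(err_tol(obs, sims[2, ]), err_tol(obs, sims[3, ]))
  sel <- select_optimal(params, sims, obs)
  expect_equal(sel$index, 2)
  expect_equal(sel$err_tol, 0.05)
  expect_error(select_optimal(params[0, , drop = FALSE],
                              sims[0, , drop = FALSE], obs), "non-empty")
})

test_that("MNSGA-II recovers a noise-free synthetic target", {
  f <- test_forcing()
  set.seed(31)
  truth <- random_params()
  obs <- soycal:::stage_doy(f, truth)
  cfg <- mnsga2_config(n_init = 100, n_gen = 15, seed = 17)
  res <- run_mnsga2(f, obs, cfg)
  sim <- soycal:::stage_doy(f, res$params)
  expect_lte(rmse(obs, sim), 1)
  # seed reproducibility
  res2 <- run_mnsga2(f, obs, cfg)
  expect_identical(res$params, res2$params)
  expect_identical(res$diagnostics$trace, res2$diagnostics$trace)
  # best-so-far err_tol trace is non-increasing
  expect_true(all(diff(res$diagnostics$trace) <= 0))
  # selected solution is optimal within the final front
  front1 <- res$diagnostics$front1
  ets <- apply(front1, 1, function(p)
    err_tol(obs, soycal:::stage_doy(f, p)))
  expect_lte(res$diagnostics$err_tol, min(ets) + 1e-12)
  # evaluation budget
  expect_lte(res$diagnostics$n_evaluations, 100 * (15 + 1))
})

test_that("with no variation the objective set never worsens", {
  f <- test_forcing()
  set.seed(41)
  obs <- soycal:::stage_doy(f, random_params())
  cfg <- mnsga2_config(n_init = 40, n_gen = 5, pc = 0, pm = 0, seed = 3)
  res <- run_mnsga2(f, obs, cfg)
  expect_true(all(diff(res$diagnostics$trace) <= 0))
})
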