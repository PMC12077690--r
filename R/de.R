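#' Configuration for Differential Evolution calibration
#'
#' Defaults follow the study conditions: population 500, 40 generations,
#' crossover rate 0.5 and differential weight `2.38 / sqrt(2 * 7)` (about
#' 0.636, from the standard scaling with the number of parameters).
#'
#' @param n_init Population size (>= 4).
#' @param n_gen Number of generations.
#' @param cr Binomial crossover rate in `[0, 1]`.
#' @param f_scale Differential weight F (> 0).
#' @param seed RNG seed.
#' @return A list of class `de_config`.
#' @export
de_config <- function(n_init = 500, n_gen = 40, cr = 0.5,
                      f_scale = 2.38 / sqrt(2 * 7), seed = 1) {
  if (n_init < 4) stop("n_init must be >= 4")
  if (cr < 0 || cr > 1) stop("cr must lie in [0, 1]")
  if (f_scale <= 0) stop("f_scale must be positive")
  structure(list(n_init = n_init, n_gen = n_gen, cr = cr,
                 f_scale = f_scale, seed = seed),
            class = "de_config")
}

#' Mean squared error fitness over the four stages
#'
#' `FitFunc = (1 / n) * sum (O_i - S_i)^2` in days^2; the quantity minimised
#' by the DE calibrator.  A failed simulation is penalised with the squared
#' horizon.
#'
#' @param observed,simulated Stage vectors of length 4; `simulated` may be
#'   `NA`.
#' @param horizon Penalty basis (days) for failed simulations.
#' @return Non-negative scalar (days^2).
#' @examples
#' de_fitness(c(10, 20, 30, 40), c(12, 20, 30, 40))  # 1
#' @export
de_fitness <- function(observed, simulated, horizon = 200) {
  if (length(observed) != 4 || length(simulated) != 4) {
    stop("observed and simulated must contain the four stages")
  }
  if (anyNA(observed)) stop("observed must contain all four stages")
  if (anyNA(simulated)) return(as.numeric(horizon)^2)
  mean((as.numeric(observed) - as.numeric(simulated))^2)
}

#' DE/rand/1 donor vector
#'
#' `donor = x_r1 + F * (x_r2 - x_r3)` with three distinct random indices
#' different from the target, clipped to the bounds.
#'
#' @param pop Population matrix (rows, >= 4).
#' @param target_index Row index of the target vector.
#' @param f_scale Differential weight.
#' @param bounds `p x 2` bounds matrix.
#' @return Donor vector within bounds.
#' @export
mutate_rand1 <- function(pop, target_index, f_scale,
                         bounds = csp_bounds()) {
  n <- nrow(pop)
  if (n < 4) stop("population must have at least 4 individuals")
  r <- sample(setdiff(seq_len(n), target_index), 3)
  donor <- pop[r[1], ] + f_scale * (pop[r[2], ] - pop[r[3], ])
  pmin(pmax(donor, bounds[, 1]), bounds[, 2])
}

#' Binomial crossover with a forced coordinate
#'
#' Each coordinate comes from the donor with probability `cr`; one random
#' coordinate `j_rand` always comes from the donor so the trial differs from
#' the target.
#'
#' @param target,donor Vectors of equal length.
#' @param cr Crossover rate.
#' @return Trial vector.
#' @export
crossover_binomial <- function(target, donor, cr) {
  p <- length(target)
  if (length(donor) != p) stop("target and donor must have equal length")
  from_donor <- stats::runif(p) < cr
  from_donor[sample.int(p, 1)] <- TRUE
  trial <- target
  trial[from_donor] <- donor[from_donor]
  trial
}

#' Calibrate cultivar parameters with Differential Evolution
#'
#' DE/rand/1/bin: for each target vector a donor is built from three other
#' population members, recombined by binomial crossover, and the trial
#' replaces the target when its fitness (mean squared stage error) is no
#' worse.  The best individual of the last generation is returned.
#'
#' @inheritParams run_mnsga2
#' @param config From [de_config()].
#' @return A `soycal_calibration` with diagnostics: `fitness`, `trace`
#'   (best fitness per generation), `n_evaluations`.
#' @export
run_de <- function(forcing, observed, config = de_config(),
                   bounds = csp_bounds()) {
  set.seed(config$seed)
  horizon <- forcing$horizon
  n <- config$n_init
  pop <- initialize_population(n, bounds)
  fit <- numeric(n)
  for (i in seq_len(n)) {
    fit[i] <- de_fitness(observed, stage_doy(forcing, pop[i, ]), horizon)
  }
  n_eval <- n
  trace <- numeric(config$n_gen)
  for (gen in seq_len(config$n_gen)) {
    for (i in seq_len(n)) {
      donor <- mutate_rand1(pop, i, config$f_scale, bounds)
      trial <- crossover_binomial(pop[i, ], donor, config$cr)
      tf <- de_fitness(observed, stage_doy(forcing, trial), horizon)
      n_eval <- n_eval + 1L
      if (tf <= fit[i]) {  # greedy selection, ties go to the trial
        pop[i, ] <- trial
        fit[i] <- tf
      }
    }
    trace[gen] <- min(fit)
  }
  best <- which.min(fit)
  calibration_result(
    "de", pop[best, ],
    diagnostics = list(fitness = fit[best], trace = trace,
                       n_evaluations = n_eval),
    seed = config$seed)
}
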