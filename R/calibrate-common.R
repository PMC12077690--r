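#' Initialize a uniform random population of parameter vectors
#'
#' Each coordinate is drawn independently from a uniform distribution over
#' its calibration range.  Used both as NSGA-II / DE initialisation and as
#' the GLUE prior sampler.
#'
#' @param n Number of individuals (rows).
#' @param bounds A `p x 2` matrix with columns `lower`, `upper` (default
#'   [csp_bounds()]).
#' @return An `n x p` numeric matrix with the bounds' rownames as colnames.
#' @export
initialize_population <- function(n, bounds = csp_bounds()) {
  if (n < 1) stop("n must be >= 1")
  lo <- bounds[, 1]
  hi <- bounds[, 2]
  if (any(lo > hi)) stop("degenerate bounds: lower > upper")
  p <- nrow(bounds)
  u <- matrix(stats::runif(n * p), nrow = n)
  pop <- sweep(sweep(u, 2, hi - lo, "*"), 2, lo, "+")
  colnames(pop) <- rownames(bounds)
  pop
}

#' Per-stage absolute error objectives
#'
#' The four objectives minimised by the multi-objective calibrator: the
#' absolute difference in days between observed and simulated date of each
#' stage.  A failed simulation (any `NA` stage) is penalised with the
#' horizon length on every stage, so infeasible candidates stay comparable
#' without aborting a run.
#'
#' @param observed,simulated Named numeric vectors (`fs`, `ps`, `gs`, `ms`)
#'   of day-of-year values; `simulated` may contain `NA`.
#' @param horizon Penalty value (days) for failed simulations.
#' @return Numeric vector of 4 non-negative objective values.
#' @export
stage_error_objectives <- function(observed, simulated, horizon = 200) {
  if (length(observed) != 4 || anyNA(observed)) {
    stop("observed must contain all four stages")
  }
  if (length(simulated) != 4) stop("simulated must have four stages")
  if (anyNA(simulated)) return(rep(as.numeric(horizon), 4))
  abs(as.numeric(observed) - as.numeric(simulated))
}

# Simulate every row of a population against one forcing.
# Returns list(sims = n x 4 matrix of stage DOY (NA where unreached),
#              objectives = n x 4 matrix of penalised absolute errors).
evaluate_population <- function(forcing, pop, observed, horizon = 200) {
  n <- nrow(pop)
  sims <- matrix(NA_real_, n, 4, dimnames = list(NULL, STAGE_NAMES))
  for (i in seq_len(n)) {
    sims[i, ] <- stage_doy(forcing, pop[i, ])
  }
  obj <- matrix(0, n, 4, dimnames = list(NULL, STAGE_NAMES))
  for (i in seq_len(n)) {
    obj[i, ] <- stage_error_objectives(observed, sims[i, ], horizon)
  }
  list(sims = sims, objectives = obj)
}

#' PEST-style weighted least-squares objective
#'
#' The quadratic form `(c - Xb)' M (c - Xb)` with diagonal cofactor matrix
#' `M = diag(weights^2)`: the sum of squared weighted residuals between an
#' observation vector and its model-generated counterpart.
#'
#' @param c_obs Observation vector.
#' @param xb Model-generated counterpart, same length.
#' @param weights Positive observation weights (recycled), default 1.
#' @return Non-negative scalar.
#' @examples
#' pest_phi(c(1, 2), c(0, 0))              # 5
#' pest_phi(c(1, 2), c(0, 0), c(2, 1))     # 8
#' @export
pest_phi <- function(c_obs, xb, weights = 1) {
  if (length(c_obs) != length(xb)) stop("c_obs and xb must have equal length")
  w <- rep_len(weights, length(c_obs))
  if (any(w <= 0)) stop("weights must be positive")
  sum(w^2 * (c_obs - xb)^2)
}

#' Weighted total relative error over the four stages
#'
#' `Err_tol = sum_i w_i * |(O_i - S_i) / O_i|` over the four phenological
#' stages; the criterion used to pick the single optimal solution from the
#' rank-1 front.
#'
#' @param observed Observed stage values (non-zero).
#' @param simulated Simulated stage values; `NA` entries contribute the
#'   relative error of a `horizon`-day miss.
#' @param weights Stage weights, default 1.
#' @param horizon Penalty (days) substituted for `NA` simulated values.
#' @return Non-negative scalar.
#' @examples
#' err_tol(c(100, 110, 120, 130), c(90, 110, 120, 130))  # 0.1
#' @export
err_tol <- function(observed, simulated, weights = 1, horizon = 200) {
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length")
  }
  if (any(observed == 0)) stop("observed stage values must be non-zero")
  w <- rep_len(weights, length(observed))
  s <- as.numeric(simulated)
  miss <- is.na(s)
  s[miss] <- observed[miss] + horizon
  sum(w * abs((observed - s) / observed))
}

# Container for one calibration run's outcome; shared by all 3 algorithms.
calibration_result <- function(algorithm, params, diagnostics, seed) {
  structure(list(algorithm = algorithm, params = params,
                 diagnostics = diagnostics, seed = seed),
            class = "soycal_calibration")
}

#' @export
print.soycal_calibration <- function(x, ...) {
  cat("<soycal calibration:", x$algorithm, ">\n")
  cat("  params:", paste(sprintf("%s=%.4g", names(x$params), x$params),
                         collapse = " "), "\n")
  if (!is.null(x$diagnostics$err_tol)) {
    cat("  err_tol:", format(x$diagnostics$err_tol), "\n")
  }
  if (!is.null(x$diagnostics$fitness)) {
    cat("  fitness:", format(x$diagnostics$fitness), "\n")
  }
  if (!is.null(x$diagnostics$n_behavioral)) {
    cat("  behavioral set size:", x$diagnostics$n_behavioral, "\n")
  }
  cat("  model evaluations:", x$diagnostics$n_evaluations,
      " seed:", x$seed, "\n")
  invisible(x)
}
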