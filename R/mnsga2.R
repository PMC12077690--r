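#' Configuration for the modified NSGA-II calibrator
#'
#' Defaults follow the study conditions: population 1000, 20 generations,
#' crossover probability 0.8, per-coordinate mutation probability `1/7`
#' (one over the number of parameters), simulated-binary-crossover and
#' polynomial-mutation distribution indices both 20.
#'
#' @param n_init Population size (even, >= 4).
#' @param n_gen Number of generations.
#' @param pc Crossover probability per parent pair.
#' @param pm Per-coordinate mutation probability.
#' @param eta_c,eta_m SBX / polynomial mutation distribution indices.
#' @param seed RNG seed for the run.
#' @return A list of class `mnsga2_config`.
#' @export
mnsga2_config <- function(n_init = 1000, n_gen = 20, pc = 0.8, pm = 1 / 7,
                          eta_c = 20, eta_m = 20, seed = 1) {
  if (n_init < 4 || n_init %% 2 != 0) stop("n_init must be even and >= 4")
  if (pc < 0 || pc > 1 || pm < 0 || pm > 1) stop("pc and pm must lie in [0, 1]")
  structure(list(n_init = n_init, n_gen = n_gen, pc = pc, pm = pm,
                 eta_c = eta_c, eta_m = eta_m, seed = seed),
            class = "mnsga2_config")
}

#' Pareto dominance (minimisation)
#'
#' @param a,b Objective vectors of equal length.
#' @return `TRUE` iff `a` is no worse than `b` in every objective and
#'   strictly better in at least one.
#' @export
dominates <- function(a, b) {
  if (length(a) != length(b)) stop("objective vectors must have equal length")
  all(a <= b) && any(a < b)
}

#' Fast non-dominated sorting
#'
#' Partitions a population into Pareto fronts under minimisation.
#'
#' @param objectives An `n x m` matrix, one row of objective values per
#'   individual.
#' @return List with `rank` (integer vector, 1 = non-dominated) and
#'   `fronts` (list of index vectors in ascending rank order).
#' @export
fast_nondominated_sort <- function(objectives) {
  if (anyNA(objectives)) stop("all individuals must be evaluated before sorting")
  n <- nrow(objectives)
  m <- ncol(objectives)
  # dominance matrix: dom[i, j] TRUE iff i dominates j
  le <- matrix(TRUE, n, n)
  lt <- matrix(FALSE, n, n)
  for (k in seq_len(m)) {
    ok <- objectives[, k]
    le <- le & outer(ok, ok, "<=")
    lt <- lt | outer(ok, ok, "<")
  }
  dom <- le & lt
  n_dominators <- colSums(dom)
  rank <- integer(n)
  fronts <- list()
  current <- which(n_dominators == 0)
  r <- 1L
  remaining <- n_dominators
  while (length(current) > 0) {
    rank[current] <- r
    fronts[[r]] <- current
    remaining[current] <- NA_integer_
    if (length(current) == 1) {
      dec <- dom[current, ]
    } else {
      dec <- colSums(dom[current, , drop = FALSE])
    }
    remaining <- remaining - dec
    current <- which(!is.na(remaining) & remaining == 0)
    r <- r + 1L
  }
  list(rank = rank, fronts = fronts)
}

#' Crowding distance within one front
#'
#' Per-objective, boundary individuals receive infinite distance; interior
#' individuals accumulate the normalised gap between their neighbours.
#' Objectives with zero range contribute nothing.
#'
#' @param objectives An `n x m` matrix for the members of one front.
#' @return Numeric vector of length `n` (may contain `Inf`).
#' @export
crowding_distance <- function(objectives) {
  n <- nrow(objectives)
  if (n == 0) stop("front must be non-empty")
  if (n <= 2) return(rep(Inf, n))
  d <- numeric(n)
  for (k in seq_len(ncol(objectives))) {
    o <- objectives[, k]
    ord <- order(o)
    rng <- o[ord[n]] - o[ord[1]]
    d[ord[1]] <- Inf
    d[ord[n]] <- Inf
    if (rng > 0) {
      inner <- ord[2:(n - 1)]
      d[inner] <- d[inner] + (o[ord[3:n]] - o[ord[1:(n - 2)]]) / rng
    }
  }
  d
}

# Binary tournament on (rank, crowding): lower rank wins; ties by larger
# crowding; full ties decided by a fair coin.
tournament_pick <- function(i, j, rank, crowd) {
  if (rank[i] != rank[j]) return(if (rank[i] < rank[j]) i else j)
  if (crowd[i] != crowd[j]) return(if (crowd[i] > crowd[j]) i else j)
  if (stats::runif(1) < 0.5) i else j
}

#' Simulated binary crossover (SBX) for bounded real vectors
#'
#' With probability `1 - pc` the children are copies of the parents.
#' Otherwise each coordinate is recombined with the SBX spread distribution
#' of index `eta_c` (larger index concentrates children near the parents);
#' children are clipped to the bounds.
#'
#' @param p1,p2 Parent vectors within bounds.
#' @param eta_c Distribution index (> 0).
#' @param pc Crossover probability.
#' @param bounds `p x 2` bounds matrix.
#' @return A list of two child vectors.
#' @export
sbx_crossover <- function(p1, p2, eta_c = 20, pc = 0.8,
                          bounds = csp_bounds()) {
  p <- length(p1)
  if (stats::runif(1) > pc) return(list(p1, p2))
  u <- stats::runif(p)
  beta <- ifelse(u <= 0.5,
                 (2 * u)^(1 / (eta_c + 1)),
                 (1 / (2 * (1 - u)))^(1 / (eta_c + 1)))
  c1 <- 0.5 * ((1 + beta) * p1 + (1 - beta) * p2)
  c2 <- 0.5 * ((1 - beta) * p1 + (1 + beta) * p2)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  list(pmin(pmax(c1, lo), hi), pmin(pmax(c2, lo), hi))
}

#' Polynomial mutation for bounded real vectors
#'
#' Each coordinate is perturbed independently with probability `pm` using
#' the polynomial mutation distribution of index `eta_m`, then clipped to
#' the bounds.
#'
#' @param x Vector within bounds.
#' @param eta_m Distribution index (> 0).
#' @param pm Per-coordinate mutation probability.
#' @param bounds `p x 2` bounds matrix.
#' @return Mutated vector within bounds.
#' @export
polynomial_mutation <- function(x, eta_m = 20, pm = 1 / 7,
                                bounds = csp_bounds()) {
  p <- length(x)
  lo <- bounds[, 1]; hi <- bounds[, 2]
  mut <- stats::runif(p) < pm
  if (!any(mut)) return(x)
  u <- stats::runif(p)
  span <- hi - lo
  delta <- ifelse(u < 0.5,
                  (2 * u)^(1 / (eta_m + 1)) - 1,
                  1 - (2 * (1 - u))^(1 / (eta_m + 1)))
  y <- x
  y[mut] <- x[mut] + delta[mut] * span[mut]
  pmin(pmax(y, lo), hi)
}

#' Environmental selection of the fittest N from a merged population
#'
#' Fills the next generation front by front; the front that overflows is
#' truncated by descending crowding distance.
#'
#' @param objectives `2N x m` objective matrix of the merged population.
#' @param n_keep Number of survivors N.
#' @return Integer vector of `n_keep` selected row indices.
#' @export
environmental_selection <- function(objectives, n_keep) {
  srt <- fast_nondominated_sort(objectives)
  chosen <- integer(0)
  for (front in srt$fronts) {
    if (length(chosen) + length(front) <= n_keep) {
      chosen <- c(chosen, front)
      if (length(chosen) == n_keep) break
    } else {
      cd <- crowding_distance(objectives[front, , drop = FALSE])
      take <- front[order(cd, decreasing = TRUE)][seq_len(n_keep - length(chosen))]
      chosen <- c(chosen, take)
      break
    }
  }
  chosen
}

#' Select the optimal individual from the rank-1 front
#'
#' Among non-dominated candidates, picks the one minimising the weighted
#' total relative error ([err_tol()]); ties are broken by the smaller
#' weighted least-squares objective ([pest_phi()]), then by first-seen
#' order.
#'
#' @param params Matrix of rank-1 parameter vectors (rows).
#' @param sims Matrix of their simulated stage values (rows, NA allowed).
#' @param observed Observed stage vector.
#' @param weights Stage weights for both criteria.
#' @param horizon Penalty for failed simulations.
#' @return List with `index`, `params`, `err_tol`, `phi`.
#' @export
select_optimal <- function(params, sims, observed, weights = 1,
                           horizon = 200) {
  n <- nrow(params)
  if (is.null(n) || n == 0) stop("rank-1 front must be non-empty")
  et <- numeric(n)
  phi <- numeric(n)
  for (i in seq_len(n)) {
    et[i] <- err_tol(observed, sims[i, ], weights, horizon)
    s <- sims[i, ]
    s[is.na(s)] <- observed[is.na(s)] + horizon
    phi[i] <- pest_phi(observed, s, weights)
  }
  best <- order(et, phi)[1]
  list(index = best, params = params[best, ], err_tol = et[best],
       phi = phi[best])
}

#' Calibrate cultivar parameters with the modified NSGA-II
#'
#' Evolves a population of parameter vectors against the four per-stage
#' absolute-error objectives using non-dominated sorting, crowding-distance
#' tournament selection, SBX crossover and polynomial mutation with an
#' elitist merge.  After the final generation the single optimal solution is
#' selected from the rank-1 front by minimum weighted total relative error
#' (ties by the weighted least-squares objective).
#'
#' @param forcing From [make_forcing()] for the calibration site/season.
#' @param observed Named stage vector (`fs`, `ps`, `gs`, `ms`), day of year.
#' @param config From [mnsga2_config()].
#' @param bounds Parameter bounds matrix.
#' @return A `soycal_calibration` with diagnostics: `err_tol`, `phi`,
#'   `trace` (best-so-far err_tol per generation), `front1` (final rank-1
#'   parameter matrix), `n_evaluations`.
#' @export
run_mnsga2 <- function(forcing, observed, config = mnsga2_config(),
                       bounds = csp_bounds()) {
  set.seed(config$seed)
  horizon <- forcing$horizon
  n <- config$n_init
  pop <- initialize_population(n, bounds)
  ev <- evaluate_population(forcing, pop, observed, horizon)
  sims <- ev$sims
  obj <- ev$objectives
  n_eval <- n
  best_trace <- numeric(config$n_gen)
  rank1_et <- function(obj, sims) {
    r1 <- fast_nondominated_sort(obj)$fronts[[1]]
    min(vapply(r1, function(i) err_tol(observed, sims[i, ], 1, horizon),
               numeric(1)))
  }
  best_so_far <- rank1_et(obj, sims)
  for (gen in seq_len(config$n_gen)) {
    srt <- fast_nondominated_sort(obj)
    crowd <- numeric(n)
    for (front in srt$fronts) {
      crowd[front] <- crowding_distance(obj[front, , drop = FALSE])
    }
    # variation: tournament parents -> SBX -> polynomial mutation
    children <- matrix(0, n, ncol(pop), dimnames = dimnames(pop))
    i <- 1L
    while (i <= n) {
      cand <- sample.int(n, 4, replace = TRUE)
      a <- tournament_pick(cand[1], cand[2], srt$rank, crowd)
      b <- tournament_pick(cand[3], cand[4], srt$rank, crowd)
      kids <- sbx_crossover(pop[a, ], pop[b, ], config$eta_c, config$pc, bounds)
      children[i, ] <- polynomial_mutation(kids[[1]], config$eta_m,
                                           config$pm, bounds)
      if (i + 1L <= n) {
        children[i + 1L, ] <- polynomial_mutation(kids[[2]], config$eta_m,
                                                  config$pm, bounds)
      }
      i <- i + 2L
    }
    evc <- evaluate_population(forcing, children, observed, horizon)
    n_eval <- n_eval + n
    merged_pop <- rbind(pop, children)
    merged_obj <- rbind(obj, evc$objectives)
    merged_sims <- rbind(sims, evc$sims)
    keep <- environmental_selection(merged_obj, n)
    pop <- merged_pop[keep, , drop = FALSE]
    obj <- merged_obj[keep, , drop = FALSE]
    sims <- merged_sims[keep, , drop = FALSE]
    best_so_far <- min(best_so_far, rank1_et(obj, sims))
    best_trace[gen] <- best_so_far
  }
  front1 <- fast_nondominated_sort(obj)$fronts[[1]]
  sel <- select_optimal(pop[front1, , drop = FALSE],
                        sims[front1, , drop = FALSE], observed,
                        weights = 1, horizon = horizon)
  calibration_result(
    "mnsga2", sel$params,
    diagnostics = list(err_tol = sel$err_tol, phi = sel$phi,
                       trace = best_trace,
                       front1 = pop[front1, , drop = FALSE],
                       n_evaluations = n_eval),
    seed = config$seed)
}
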