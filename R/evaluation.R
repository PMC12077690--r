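#' Root mean square error
#'
#' @param observed,simulated Numeric vectors of equal length (days).
#' @return `sqrt(mean((observed - simulated)^2))`.
#' @examples
#' rmse(c(10, 20, 30), c(13, 16, 30))  # sqrt(25/3)
#' @export
rmse <- function(observed, simulated) {
  check_pairs(observed, simulated)
  sqrt(mean((observed - simulated)^2))
}

#' Mean absolute error
#'
#' @inheritParams rmse
#' @return `mean(abs(observed - simulated))`.
#' @export
mae <- function(observed, simulated) {
  check_pairs(observed, simulated)
  mean(abs(observed - simulated))
}

#' Coefficient of determination about the 1:1 line
#'
#' `R^2 = 1 - RSS/TSS` with `RSS = sum((O - S)^2)` and
#' `TSS = sum((O - mean(O))^2)`.  Can be negative when the simulation is
#' worse than predicting the observed mean.
#'
#' @inheritParams rmse
#' @return Scalar `<= 1`.
#' @export
r2 <- function(observed, simulated) {
  check_pairs(observed, simulated)
  if (length(observed) < 2) stop("r2 requires at least 2 pairs")
  tss <- sum((observed - mean(observed))^2)
  if (tss == 0) stop("r2 undefined: observed values are constant (TSS = 0)")
  1 - sum((observed - simulated)^2) / tss
}

check_pairs <- function(observed, simulated) {
  if (length(observed) == 0) stop("empty observation vector")
  if (length(observed) != length(simulated)) {
    stop("observed and simulated must have equal length")
  }
  if (anyNA(observed) || anyNA(simulated)) stop("pairs must not contain NA")
  invisible(NULL)
}

#' Paired one-tailed t-test
#'
#' Tests whether `mean(a - b) > 0` with the paired t statistic.  Degenerate
#' inputs are defined explicitly: zero-variance differences with zero mean
#' are declared not significant (`t = 0, p = 1`); zero-variance differences
#' with non-zero mean are declared significant (`p = 0`, `t` signed
#' infinite).
#'
#' @param a,b Paired numeric vectors, length >= 2.
#' @param alpha Significance level for the `significant` flag.
#' @return List with `t`, `df`, `p`, `significant`.
#' @export
paired_one_tailed_ttest <- function(a, b, alpha = 0.05) {
  if (length(a) != length(b)) stop("a and b must have equal length")
  n <- length(a)
  if (n < 2) stop("paired t-test requires at least 2 pairs")
  d <- a - b
  if (stats::sd(d) == 0) {
    if (mean(d) == 0) {
      return(list(t = 0, df = n - 1, p = 1, significant = FALSE))
    }
    return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0,
                significant = TRUE))
  }
  ht <- stats::t.test(a, b, paired = TRUE, alternative = "greater")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, significant = ht$p.value < alpha)
}

#' Aggregate repeated calibrations into one parameter set
#'
#' The calibration of one cultivar is repeated several times; the
#' coordinate-wise mean of the optimised parameter vectors is taken as the
#' final estimate, and every ordered pair of repeats is compared with a
#' paired one-tailed t-test across the parameters as a stability check.
#' Aggregation proceeds regardless of significance; the flags are reported.
#'
#' @param results A list of `soycal_calibration` objects (or plain named
#'   parameter vectors), length >= 2 for the stability tests (a single
#'   result is returned as-is with an empty test table).
#' @return List with `params` (mean vector), `tests` (data frame of
#'   pairwise t-tests), `repeats` (parameter matrix, one row per repeat),
#'   and `any_significant`.
#' @export
aggregate_repeats <- function(results) {
  vecs <- lapply(results, function(r) {
    if (inherits(r, "soycal_calibration")) r$params else r
  })
  k <- length(vecs)
  if (k < 1) stop("no results to aggregate")
  mat <- do.call(rbind, vecs)
  mean_params <- colMeans(mat)
  tests <- NULL
  if (k >= 2) {
    rows <- list()
    for (i in seq_len(k - 1)) {
      for (j in (i + 1):k) {
        tt <- paired_one_tailed_ttest(mat[i, ], mat[j, ])
        rows[[length(rows) + 1]] <- data.frame(
          repeat_a = i, repeat_b = j, t = tt$t, p = tt$p,
          significant = tt$significant)
      }
    }
    tests <- do.call(rbind, rows)
  } else {
    tests <- data.frame(repeat_a = integer(0), repeat_b = integer(0),
                        t = numeric(0), p = numeric(0),
                        significant = logical(0))
  }
  list(params = mean_params, tests = tests, repeats = mat,
       any_significant = any(tests$significant))
}

#' Goodness-of-fit metrics for a set of observed/simulated pairs
#'
#' @inheritParams rmse
#' @return Data frame with one row: `n_tol`, `rmse`, `mae`, `r2`.
#' @export
fit_metrics <- function(observed, simulated) {
  data.frame(n_tol = length(observed),
             rmse = rmse(observed, simulated),
             mae = mae(observed, simulated),
             r2 = r2(observed, simulated))
}
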