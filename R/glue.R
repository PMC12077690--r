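#' Configuration for GLUE calibration
#'
#' Defaults follow the study conditions: 20000 prior samples drawn in a
#' single batch and a behavioral threshold of 0.90 applied to the
#' max-normalised likelihood.
#'
#' @param n_samples Number of prior samples.
#' @param threshold Behavioral threshold in `(0, 1)`, applied to the
#'   likelihood normalised by the sample maximum.
#' @param sigma2 Error variance (days^2) of the Gaussian likelihood.  This
#'   is the expected observation error of a stage date, not the spread of
#'   the dates themselves; the default 4 (a 2-day scoring granularity) keeps
#'   the behavioral set concentrated around candidates that fit to within a
#'   few days.
#' @param seed RNG seed.
#' @return A list of class `glue_config`.
#' @export
glue_config <- function(n_samples = 20000, threshold = 0.90, sigma2 = 4,
                        seed = 1) {
  if (n_samples < 1) stop("n_samples must be >= 1")
  if (threshold <= 0 || threshold > 1) stop("threshold must lie in (0, 1]")
  if (!is.null(sigma2) && sigma2 <= 0) stop("sigma2 must be positive")
  structure(list(n_samples = n_samples, threshold = threshold,
                 sigma2 = sigma2, seed = seed),
            class = "glue_config")
}

#' Sample cultivar parameters from the uniform prior
#'
#' @inheritParams initialize_population
#' @return An `n x p` matrix of prior draws.
#' @export
sample_priors <- function(n, bounds = csp_bounds()) {
  initialize_population(n, bounds)
}

#' Gaussian likelihood of a candidate given observed stage dates
#'
#' `L = exp(-SSE / (2 * sigma2 * n_stages))` where SSE is the sum of squared
#' day errors over the stages.  Strictly decreasing in SSE; intended to be
#' normalised by the maximum over a sample batch before thresholding.
#'
#' @param observed,simulated Stage vectors; `NA` simulated entries are
#'   penalised with a `horizon`-day miss.
#' @param sigma2 Error variance in days^2 (> 0).
#' @param horizon Penalty (days) for unreached stages.
#' @return Likelihood value in `(0, 1]` (un-normalised).
#' @export
glue_likelihood <- function(observed, simulated, sigma2, horizon = 200) {
  if (sigma2 <= 0) stop("sigma2 must be positive")
  s <- as.numeric(simulated)
  miss <- is.na(s)
  s[miss] <- observed[miss] + horizon
  sse <- sum((as.numeric(observed) - s)^2)
  exp(-sse / (2 * sigma2 * length(observed)))
}

#' Filter the behavioral set at a likelihood threshold
#'
#' Keeps the samples whose max-normalised likelihood is at least
#' `threshold`.  The best sample always survives, so the behavioral set is
#' never empty.
#'
#' @param likelihood Raw likelihood values (one per sample).
#' @param threshold Threshold on the normalised likelihood.
#' @return List with `keep` (indices), `n_behavioral`, and
#'   `normalized` (full normalised likelihood vector).
#' @export
filter_behavioral <- function(likelihood, threshold) {
  mx <- max(likelihood)
  if (!is.finite(mx) || mx <= 0) stop("all likelihoods are zero; no behavioral set")
  norm <- likelihood / mx
  keep <- which(norm >= threshold)
  list(keep = keep, n_behavioral = length(keep), normalized = norm)
}

#' Likelihood-weighted posterior point estimate and intervals
#'
#' The point estimate is the likelihood-weighted mean of the behavioral
#' samples; uncertainty intervals are likelihood-weighted 2.5/97.5
#' percentiles per coordinate.
#'
#' @param params Matrix of behavioral parameter vectors (rows).
#' @param weights Their (normalised) likelihoods.
#' @param probs Interval probabilities.
#' @return List with `estimate` (named vector) and `intervals`
#'   (`p x 2` matrix).
#' @export
posterior_estimate <- function(params, weights,
                               probs = c(0.025, 0.975)) {
  n <- nrow(params)
  if (is.null(n) || n == 0) stop("behavioral set is empty")
  if (length(weights) != n || any(weights <= 0)) {
    stop("weights must be positive, one per behavioral sample")
  }
  w <- weights / sum(weights)
  est <- as.numeric(t(params) %*% w)
  names(est) <- colnames(params)
  ints <- t(apply(params, 2, weighted_quantile, w = w, probs = probs))
  colnames(ints) <- paste0("q", probs * 100)
  list(estimate = est, intervals = ints)
}

# Weighted quantile by inversion of the weighted empirical CDF.
weighted_quantile <- function(x, w, probs) {
  ord <- order(x)
  x <- x[ord]
  cw <- cumsum(w[ord])
  vapply(probs, function(p) x[which(cw >= p * cw[length(cw)])[1]], numeric(1))
}

#' Calibrate cultivar parameters with GLUE
#'
#' Draws `n_samples` parameter vectors from the uniform prior, evaluates the
#' Gaussian likelihood of each against the observed stage dates, retains the
#' behavioral set at the configured threshold (on the max-normalised
#' likelihood), and returns the likelihood-weighted posterior mean with
#' percentile intervals.
#'
#' @inheritParams run_mnsga2
#' @param config From [glue_config()].
#' @return A `soycal_calibration` with diagnostics: `n_behavioral`,
#'   `intervals`, `behavioral` (parameter matrix), `likelihood`
#'   (normalised, behavioral set), `n_evaluations`.
#' @export
run_glue <- function(forcing, observed, config = glue_config(),
                     bounds = csp_bounds()) {
  set.seed(config$seed)
  horizon <- forcing$horizon
  pop <- sample_priors(config$n_samples, bounds)
  sigma2 <- config$sigma2
  if (is.null(sigma2)) sigma2 <- 4
  lik <- numeric(config$n_samples)
  for (i in seq_len(config$n_samples)) {
    s <- stage_doy(forcing, pop[i, ])
    lik[i] <- glue_likelihood(observed, s, sigma2, horizon)
  }
  beh <- filter_behavioral(lik, config$threshold)
  post <- posterior_estimate(pop[beh$keep, , drop = FALSE],
                             beh$normalized[beh$keep])
  calibration_result(
    "glue", post$estimate,
    diagnostics = list(n_behavioral = beh$n_behavioral,
                       intervals = post$intervals,
                       behavioral = pop[beh$keep, , drop = FALSE],
                       likelihood = beh$normalized[beh$keep],
                       sigma2 = sigma2,
                       n_evaluations = config$n_samples),
    seed = config$seed)
}
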