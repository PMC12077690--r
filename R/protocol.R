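# Build an algorithm config object from a run-config block plus a seed.
algo_config <- function(algorithm, block, seed) {
  switch(algorithm,
    mnsga2 = mnsga2_config(n_init = block$n_init, n_gen = block$n_gen,
                           pc = block$pc, pm = block$pm,
                           eta_c = block$eta_c, eta_m = block$eta_m,
                           seed = seed),
    glue = glue_config(n_samples = block$n_samples,
                       threshold = block$threshold,
                       sigma2 = block$sigma2, seed = seed),
    de = de_config(n_init = block$n_init, n_gen = block$n_gen,
                   cr = block$cr, f_scale = block$f_scale, seed = seed),
    stop("unknown algorithm: ", algorithm))
}

run_algorithm <- function(algorithm, forcing, observed, config) {
  switch(algorithm,
    mnsga2 = run_mnsga2(forcing, observed, config),
    glue = run_glue(forcing, observed, config),
    de = run_de(forcing, observed, config))
}

#' Repeat a calibration and aggregate the results
#'
#' Runs the chosen algorithm `repeats` times with distinct sub-seeds derived
#' deterministically from the top-level seed, compares the repeated
#' parameter sets pairwise with paired one-tailed t-tests, and returns the
#' coordinate-wise mean as the final parameter estimate.  Aggregation
#' proceeds regardless of significance; the flags are recorded.
#'
#' @param forcing From [make_forcing()] for the calibration data.
#' @param observed Named stage vector (`fs`, `ps`, `gs`, `ms`).
#' @param algorithm One of `"mnsga2"`, `"glue"`, `"de"`.
#' @param config Run configuration (see [default_run_config()]); only the
#'   matching algorithm block is used.
#' @param repeats Number of repeats (default from config).
#' @param seed Top-level seed (default from config).
#' @return List with `algorithm`, `params` (mean vector), `tests`,
#'   `results` (per-repeat `soycal_calibration`s), `sub_seeds`, `seed`.
#' @export
run_calibration_protocol <- function(forcing, observed, algorithm,
                                     config = default_run_config(),
                                     repeats = config$repeats,
                                     seed = config$seed) {
  if (repeats < 1) stop("repeats must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, repeats)
  results <- vector("list", repeats)
  for (r in seq_len(repeats)) {
    cfg <- algo_config(algorithm, config[[algorithm]], sub_seeds[r])
    results[[r]] <- run_algorithm(algorithm, forcing, observed, cfg)
  }
  agg <- aggregate_repeats(results)
  list(algorithm = algorithm, params = agg$params, tests = agg$tests,
       results = results, sub_seeds = sub_seeds, seed = seed)
}

#' Calibrate every cultivar of a synthetic suite
#'
#' For each pairing row, calibrates the row's cultivars on its calibration
#' experiment with [run_calibration_protocol()].
#'
#' @param suite From [build_experiment_suite()].
#' @param algorithm One of `"mnsga2"`, `"glue"`, `"de"`.
#' @param config Run configuration.
#' @param repeats,seed Protocol settings (default from config).  Each
#'   cultivar gets a distinct derived seed so repeats never share streams.
#' @return Named list (by cultivar) of protocol results.
#' @export
calibrate_suite <- function(suite, algorithm,
                            config = default_run_config(),
                            repeats = config$repeats, seed = config$seed) {
  set.seed(seed)
  n_cult <- nrow(suite$truth)
  cult_seeds <- sample.int(.Machine$integer.max - 1L, n_cult)
  out <- list()
  for (k in seq_len(nrow(suite$pairing))) {
    calib_exp <- suite$pairing$calib_exp[k]
    forcing <- suite$experiments[[calib_exp]]$forcing
    for (cultivar in suite$pairing$cultivars[[k]]) {
      ci <- match(cultivar, rownames(suite$truth))
      observed <- suite_observed(suite, calib_exp, cultivar)
      out[[cultivar]] <- run_calibration_protocol(
        forcing, observed, algorithm, config, repeats,
        seed = cult_seeds[ci])
      out[[cultivar]]$calib_exp <- calib_exp
    }
  }
  out
}

#' Cross-evaluate calibrated parameters on independent experiments
#'
#' Simulates each cultivar with its calibrated parameters under the forcing
#' of its evaluation experiment (the pairing partner of the calibration
#' experiment) and compares against that experiment's observations.
#' Failed simulations are dropped from the pair table with a warning.
#'
#' @param suite From [build_experiment_suite()].
#' @param calibrations Named list (by cultivar) with `$params`, as returned
#'   by [calibrate_suite()], or a cultivar x 7 parameter matrix.
#' @return List with `pairs` (data frame `pairing`, `experiment`,
#'   `cultivar`, `stage`, `observed`, `simulated`) and `metrics` (one row
#'   per pairing plus a pooled row: `scope`, `n_tol`, `rmse`, `mae`, `r2`).
#' @export
run_cross_evaluation <- function(suite, calibrations) {
  get_params <- function(cultivar) {
    if (is.matrix(calibrations)) return(calibrations[cultivar, ])
    res <- calibrations[[cultivar]]
    if (is.null(res)) stop("missing calibration for cultivar ", cultivar)
    if (is.list(res) && !is.null(res$params)) res$params else res
  }
  rows <- list()
  for (k in seq_len(nrow(suite$pairing))) {
    eval_exp <- suite$pairing$eval_exp[k]
    forcing <- suite$experiments[[eval_exp]]$forcing
    for (cultivar in suite$pairing$cultivars[[k]]) {
      observed <- suite_observed(suite, eval_exp, cultivar)
      sim <- stage_doy(forcing, get_params(cultivar))
      if (anyNA(sim)) {
        warning("evaluation simulation failed for ", cultivar,
                " in experiment ", eval_exp, "; pairs dropped")
        next
      }
      rows[[length(rows) + 1]] <- data.frame(
        pairing = k, experiment = eval_exp, cultivar = cultivar,
        stage = c("FS", "PS", "GS", "MS"),
        observed = as.numeric(observed), simulated = as.numeric(sim))
    }
  }
  pairs <- do.call(rbind, rows)
  if (is.null(pairs) || nrow(pairs) == 0) stop("no evaluable pairs")
  metric_rows <- lapply(split(pairs, pairs$pairing), function(g) {
    cbind(scope = paste0("pairing", g$pairing[1]),
          fit_metrics(g$observed, g$simulated))
  })
  metric_rows$pooled <- cbind(scope = "pooled",
                              fit_metrics(pairs$observed, pairs$simulated))
  metrics <- do.call(rbind, metric_rows)
  rownames(metrics) <- NULL
  list(pairs = pairs, metrics = metrics)
}

#' Write a full calibration report to a directory
#'
#' Emits: `csps.csv` (optimized parameters per cultivar and repeat),
#' `metrics.csv`, `pairs.csv` (observed-vs-simulated dump from which every
#' metric can be recomputed), and `config.yaml` (the configuration echo
#' including all seeds).
#'
#' @param dir Output directory (created if needed).
#' @param calibrations From [calibrate_suite()].
#' @param evaluation From [run_cross_evaluation()].
#' @param config Run configuration used.
#' @param algorithm Algorithm label recorded in the tables.
#' @return Invisibly, the vector of written file paths.
#' @export
write_calibration_report <- function(dir, calibrations, evaluation, config,
                                     algorithm) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csp_rows <- list()
  for (cultivar in names(calibrations)) {
    res <- calibrations[[cultivar]]
    csp_rows[[length(csp_rows) + 1]] <- data.frame(
      cultivar = cultivar, algorithm = algorithm, repeat_id = 0,
      seed = res$seed, t(res$params), check.names = FALSE)
    for (r in seq_along(res$results)) {
      csp_rows[[length(csp_rows) + 1]] <- data.frame(
        cultivar = cultivar, algorithm = algorithm, repeat_id = r,
        seed = res$sub_seeds[r], t(res$results[[r]]$params),
        check.names = FALSE)
    }
  }
  csps <- do.call(rbind, csp_rows)
  paths <- file.path(dir, c("csps.csv", "metrics.csv", "pairs.csv",
                            "config.yaml"))
  utils::write.csv(csps, paths[1], row.names = FALSE)
  metrics <- cbind(algorithm = algorithm, evaluation$metrics)
  utils::write.csv(metrics, paths[2], row.names = FALSE)
  utils::write.csv(cbind(algorithm = algorithm, evaluation$pairs),
                   paths[3], row.names = FALSE)
  echo <- config
  echo$algorithm <- algorithm
  echo$sub_seeds <- lapply(calibrations, function(r) r$sub_seeds)
  yaml::write_yaml(echo, paths[4])
  invisible(paths)
}

#' Run all three calibration algorithms on one suite
#'
#' Convenience wrapper: calibrates and cross-evaluates the suite with
#' MNSGA-II, GLUE and DE under a shared configuration and seed.
#'
#' @param suite From [build_experiment_suite()].
#' @param config Run configuration.
#' @param repeats,seed Protocol settings.
#' @return Named list (by algorithm) of lists with `calibrations` and
#'   `evaluation`.
#' @export
compare_algorithms <- function(suite, config = default_run_config(),
                               repeats = config$repeats,
                               seed = config$seed) {
  out <- list()
  for (alg in c("mnsga2", "glue", "de")) {
    cal <- calibrate_suite(suite, alg, config, repeats, seed)
    out[[alg]] <- list(calibrations = cal,
                       evaluation = run_cross_evaluation(suite, cal))
  }
  out
}
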