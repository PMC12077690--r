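#' Read a daily weather table
#'
#' Two dialects: plain CSV with header `date,tmax,tmin` (ISO dates), and a
#' DSSAT-style `.WTH` whitespace-column table whose header line starts with
#' `@DATE` and contains `TMAX` and `TMIN` columns (dates as `YYDDD`).
#'
#' @param path Path to the file.
#' @param dialect `"csv"` or `"dssat_wth"`.
#' @return A validated weather data frame (see [validate_weather()]).
#' @export
read_weather_table <- function(path, dialect = c("csv", "dssat_wth")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("weather file not found: ", path)
  if (dialect == "csv") {
    w <- utils::read.csv(path, stringsAsFactors = FALSE)
    miss <- setdiff(c("date", "tmax", "tmin"), names(w))
    if (length(miss) > 0) {
      stop("weather CSV is missing column(s): ", paste(miss, collapse = ", "))
    }
    w$date <- as.Date(w$date)
    return(validate_weather(w[, c("date", "tmax", "tmin")]))
  }
  lines <- readLines(path)
  hdr_i <- grep("^@DATE", lines)
  if (length(hdr_i) == 0) stop("no @DATE header line in WTH file: ", path)
  hdr_i <- hdr_i[1]
  cols <- strsplit(sub("^@", "", lines[hdr_i]), "\\s+")[[1]]
  need <- c("DATE", "TMAX", "TMIN")
  miss <- setdiff(need, cols)
  if (length(miss) > 0) {
    stop("WTH header is missing column(s): ", paste(miss, collapse = ", "))
  }
  body <- lines[(hdr_i + 1):length(lines)]
  body <- body[nzchar(trimws(body))]
  tab <- utils::read.table(text = body, col.names = cols,
                           colClasses = "character")
  yyddd <- tab$DATE
  yy <- as.integer(substr(yyddd, 1, 2))
  ddd <- as.integer(substr(yyddd, 3, 5))
  year <- ifelse(yy < 50, 2000 + yy, 1900 + yy)
  date <- as.Date(ddd - 1, origin = as.Date(sprintf("%d-01-01", year)))
  w <- data.frame(date = date, tmax = as.numeric(tab$TMAX),
                  tmin = as.numeric(tab$TMIN))
  validate_weather(w)
}

#' Write a weather series as CSV
#'
#' @param weather Weather data frame.
#' @param path Output path.
#' @export
write_weather_csv <- function(weather, path) {
  weather <- validate_weather(weather)
  utils::write.csv(weather[, c("date", "tmax", "tmin")], path,
                   row.names = FALSE)
}

STAGE_LABELS <- c("FS", "PS", "GS", "MS")

#' Read a phenology observations table
#'
#' CSV with columns `experiment,cultivar,stage,date`; stages must be among
#' FS, PS, GS, MS and each (experiment, cultivar, stage) may appear once.
#'
#' @param path Path to the CSV file.
#' @return Validated data frame with `date` parsed as `Date`.
#' @export
read_observations_table <- function(path) {
  if (!file.exists(path)) stop("observations file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  miss <- setdiff(c("experiment", "cultivar", "stage", "date"), names(d))
  if (length(miss) > 0) {
    stop("observations CSV is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  bad <- setdiff(unique(d$stage), STAGE_LABELS)
  if (length(bad) > 0) {
    stop("unknown stage label(s): ", paste(bad, collapse = ", "),
         " (expected FS, PS, GS, MS)")
  }
  key <- paste(d$experiment, d$cultivar, d$stage)
  if (anyDuplicated(key)) {
    stop("duplicate stage record(s): ", key[duplicated(key)][1])
  }
  d$date <- as.Date(d$date)
  if (anyNA(d$date)) stop("observations contain unparseable dates")
  d
}

#' Write a phenology observations table as CSV
#'
#' @param observations Data frame with `experiment,cultivar,stage,date`.
#' @param path Output path.
#' @export
write_observations_table <- function(observations, path) {
  utils::write.csv(
    observations[, c("experiment", "cultivar", "stage", "date")], path,
    row.names = FALSE)
}

CSP_FILE_NAMES <- c("CSDL", "PPSEN", "R1PPO", "EM-FL", "FL-SH", "FL-SD",
                    "SD-PM")

#' Write a cultivar-parameter table as CSV
#'
#' Columns: `cultivar,CSDL,PPSEN,R1PPO,EM-FL,FL-SH,FL-SD,SD-PM`.
#'
#' @param csps Matrix (cultivars x 7, rownames = cultivar labels) or a
#'   single named parameter vector.
#' @param path Output path.
#' @export
write_csp_table <- function(csps, path) {
  if (is.null(dim(csps))) csps <- matrix(csps, 1, dimnames = list("C1", names(csps)))
  d <- data.frame(cultivar = rownames(csps), csps, check.names = FALSE)
  names(d) <- c("cultivar", CSP_FILE_NAMES)
  utils::write.csv(d, path, row.names = FALSE, quote = FALSE)
}

#' Read a cultivar-parameter table
#'
#' @param path Path to a CSV written by [write_csp_table()].
#' @return Matrix with rownames = cultivar labels and canonical
#'   lower-case parameter colnames.
#' @export
read_csp_table <- function(path) {
  if (!file.exists(path)) stop("CSP file not found: ", path)
  d <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  miss <- setdiff(c("cultivar", CSP_FILE_NAMES), names(d))
  if (length(miss) > 0) {
    stop("CSP table is missing column(s): ", paste(miss, collapse = ", "))
  }
  m <- as.matrix(d[, CSP_FILE_NAMES])
  dimnames(m) <- list(d$cultivar, CSP_NAMES)
  m
}

#' Ingest an observed-vs-simulated pair workbook or CSV
#'
#' Reads a table of observed and simulated stage dates (day of year) per
#' algorithm — e.g. supplementary figure data — and recomputes the pooled
#' goodness-of-fit metrics with the evaluation module.  Column names are
#' mapping-configurable because external workbooks vary in layout.
#'
#' @param path CSV or XLSX file (XLSX requires the `readxl` package).
#' @param mapping Named list giving the column names for `algorithm`,
#'   `observed` and `simulated` in the source table.
#' @param sheet Sheet name or index for XLSX sources.
#' @return List with `pairs` (normalised data frame) and `metrics` (one
#'   row per algorithm: `algorithm`, `n_tol`, `rmse`, `mae`, `r2`).
#' @export
ingest_s1 <- function(path,
                      mapping = list(algorithm = "algorithm",
                                     observed = "observed",
                                     simulated = "simulated"),
                      sheet = 1) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.xlsx?$", path, ignore.case = TRUE)) {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading XLSX requires the readxl package")
    }
    d <- as.data.frame(readxl::read_excel(path, sheet = sheet))
  } else {
    d <- utils::read.csv(path, stringsAsFactors = FALSE)
  }
  need <- unlist(mapping)
  miss <- setdiff(need, names(d))
  if (length(miss) > 0) {
    stop("source table is missing column(s): ", paste(miss, collapse = ", "))
  }
  pairs <- data.frame(algorithm = d[[mapping$algorithm]],
                      observed = as.numeric(d[[mapping$observed]]),
                      simulated = as.numeric(d[[mapping$simulated]]))
  metrics <- do.call(rbind, lapply(split(pairs, pairs$algorithm), function(g) {
    cbind(algorithm = g$algorithm[1], fit_metrics(g$observed, g$simulated))
  }))
  rownames(metrics) <- NULL
  list(pairs = pairs, metrics = metrics)
}

#' Default run configuration
#'
#' All algorithm blocks carry the study-condition defaults; every value can
#' be overridden from a YAML file ([read_run_config()]) or in code.
#'
#' @return Nested list: `algorithm`, `repeats`, `seed`, `model` (cardinal
#'   temperatures, twilight angle, horizon, emergence constants), and one
#'   block per algorithm.
#' @export
default_run_config <- function() {
  list(
    algorithm = "mnsga2",
    repeats = 3,
    seed = 1,
    model = list(t_base = 6, t_opt_lo = 26, t_opt_hi = 30, t_ceil = 45,
                 twilight_angle = -6, horizon = 200,
                 e_base = 3.0, e_slope = 0.1),
    mnsga2 = list(n_init = 1000, n_gen = 20, pc = 0.8, pm = 1 / 7,
                  eta_c = 20, eta_m = 20),
    glue = list(n_samples = 20000, threshold = 0.90, sigma2 = 4),
    de = list(n_init = 500, n_gen = 40, cr = 0.5,
              f_scale = 2.38 / sqrt(2 * 7))
  )
}

#' Read a run configuration from YAML
#'
#' Values present in the file override the defaults from
#' [default_run_config()]; everything else keeps its default.
#'
#' @param path Path to a YAML file (may be absent or partial).
#' @return Merged configuration list.
#' @export
read_run_config <- function(path) {
  cfg <- default_run_config()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    user <- yaml::read_yaml(path)
    cfg <- modify_list_deep(cfg, user)
  }
  cfg
}

modify_list_deep <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- modify_list_deep(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

#' Write a run configuration as YAML
#'
#' @param config Configuration list.
#' @param path Output path.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(config, path)
}
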