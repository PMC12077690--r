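Package: soycal
Title: Calibration of a Soybean Phenological Model by MNSGA-II, GLUE and
    Differential Evolution
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A photothermal model of soybean phenology (first flowering,
    first pod, first grain, first maturity) driven by daily temperature and
    daylength, together with three algorithms for estimating the seven
    cultivar-specific parameters that control it: a modified NSGA-II that
    selects the optimal rank-1 solution by a weighted relative total error,
    Generalized Likelihood Uncertainty Estimation (GLUE) with behavioral-set
    filtering, and Differential Evolution (rand/1/bin).  Includes RMSE, MAE
    and R-squared evaluation metrics, a repeat-calibration protocol with
    paired one-tailed t-tests, a synthetic multi-site multi-cultivar
    experiment generator for parameter-recovery studies, readers and writers
    for weather, observation and parameter tables, and a command-line
    interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    readxl,
    optparse,
    jsonlite
Config/testthat/edition: 3
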