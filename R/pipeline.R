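# End-to-end orchestration: simulate -> preprocess -> fit -> cut-points ->
# evaluate, under one configuration, with a run log and no silent data loss.

#' Pipeline configuration
#'
#' Defaults follow the calibration study's stated analysis choices: 34 male
#' and 22 female participants, the five-condition treadmill protocol,
#' 3-SD/4-neighbour breath cleaning, central-four-minute steady-state
#' windows, 95% confidence level.
#'
#' @param n_male,n_female Cohort sizes (defaults 34 and 22).
#' @param seed Integer seed for every source of randomness.
#' @param truth A [truth_parameters()] object.
#' @param fidelity "observation" (default: draw steady-state observations
#'   directly from the truth model) or "signal" (full raw-signal, count
#'   emulation and breath simulation path through file I/O).
#' @param sd_multiplier Breath-cleaning threshold in local SDs (default 3).
#' @param ci_level Confidence level (default 0.95).
#' @param ci_multiplier "z" or "t" (see [fit_calibration()]).
#' @param stratify_by "none", "sex" or "stratum" for the classification
#'   reports.
#' @param out_dir Output directory, or `NULL` for no file output.
#' @return List of class `pipeline_config`.
#' @export
pipeline_config <- function(n_male = 34, n_female = 22, seed = 1,
                            truth = truth_parameters(),
                            fidelity = c("observation", "signal"),
                            sd_multiplier = 3, ci_level = 0.95,
                            ci_multiplier = "z",
                            stratify_by = "none", out_dir = NULL) {
  structure(
    list(n_male = n_male, n_female = n_female, seed = seed, truth = truth,
         fidelity = match.arg(fidelity), sd_multiplier = sd_multiplier,
         ci_level = ci_level, ci_multiplier = ci_multiplier,
         stratify_by = stratify_by, out_dir = out_dir),
    class = "pipeline_config"
  )
}

config_hash <- function(config) {
  rlang::hash(lapply(unclass(config), function(x)
    if (is.list(x)) lapply(unclass(x), unclass) else x))
}

#' Run the full calibration pipeline
#'
#' Simulates a cohort, builds the steady-state observation table, fits the
#' square-root-scale calibration, derives the cut-point table, scores
#' intensity classification and computes the diagnostic analyses. With an
#' `out_dir` every stage product is written as CSV; re-running with the
#' same configuration reproduces identical outputs.
#'
#' @param config A [pipeline_config()].
#' @return List of class `pipeline_result`: `observations`, `fit`,
#'   `equations`, `equation_table`, `cutpoints`, `reports`, `correlations`,
#'   `anova`, `bland_altman`, `diagnostics`, `log`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  log <- list(config_hash = config_hash(config),
              started = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ"),
              version = as.character(utils::packageVersion("actimet")),
              exclusions = 0L, breaths_removed = 0L)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  cohort <- stage("cohort",
                  generate_cohort(config$n_male, config$n_female,
                                  seed = config$seed))
  if (config$fidelity == "observation") {
    obs <- stage("simulate",
                 simulate_observations(cohort, config$truth,
                                       seed = config$seed + 1))
  } else {
    dir <- config$out_dir %||% tempfile("actimet_dataset")
    data_dir <- file.path(dir, "dataset")
    stage("simulate",
          write_cohort_dataset(cohort, config$truth, data_dir,
                               seed = config$seed + 1))
    ds <- stage("read", read_cohort_dataset(data_dir))
    obs <- stage("preprocess",
                 build_observation_table(ds$breaths, ds$epochs,
                                         cohort = ds$cohort))
    log$exclusions <- nrow(attr(obs, "exclusions"))
    log$breaths_removed <- attr(obs, "n_breaths_removed")
  }
  fit <- stage("fit", fit_calibration(obs,
                                      ci_multiplier = config$ci_multiplier))
  eqs <- stage("equations", stratum_equations(fit))
  cp <- stage("cutpoints",
              build_cutpoint_table(fit, level = config$ci_level))
  reports <- stage("evaluate",
                   stratified_reports(obs, cp, eqs,
                                      by = config$stratify_by))
  correlations <- stage("correlations", pearson_speed_correlations(obs))
  anova <- stage("anova", anova_counts(obs))
  ba <- stage("bland_altman", bland_altman(eqs, obs))
  diagnostics <- stage("diagnostics", residual_diagnostics(fit))
  log$finished <- format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ")
  result <- structure(
    list(observations = obs, fit = fit, equations = eqs,
         equation_table = equation_table(fit), cutpoints = cp,
         reports = reports, correlations = correlations, anova = anova,
         bland_altman = ba, diagnostics = diagnostics, log = log),
    class = "pipeline_result"
  )
  if (!is.null(config$out_dir)) write_pipeline_result(result, config)
  result
}

`%||%` <- function(a, b) if (is.null(a)) b else a

write_pipeline_result <- function(result, config) {
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  wr <- function(x, name) {
    write.csv(x, file.path(config$out_dir, name), row.names = FALSE)
  }
  wr(result$observations, "observations.csv")
  wr(result$equation_table, "equations.csv")
  wr(result$cutpoints, "cutpoints.csv")
  metrics <- dplyr::bind_rows(lapply(result$reports, function(r) {
    m <- tidyr::pivot_longer(r$metrics, -"class", names_to = "metric",
                             values_to = "value")
    m$group <- r$group
    m
  }))
  wr(metrics, "classification_metrics.csv")
  conf <- dplyr::bind_rows(lapply(result$reports, function(r) {
    d <- as.data.frame(r$confusion)
    d$group <- r$group
    d
  }))
  wr(conf, "confusion_matrices.csv")
  wr(result$correlations, "correlations.csv")
  wr(result$bland_altman, "bland_altman.csv")
  beta_tab <- tibble::tibble(term = names(result$fit$beta),
                             estimate = unname(result$fit$beta))
  wr(beta_tab, "coefficients.csv")
  anova_tab <- tibble::tibble(
    F = result$anova$F, df_between = result$anova$df_between,
    df_within = result$anova$df_within, p = result$anova$p,
    eta_squared = result$anova$eta_squared
  )
  wr(anova_tab, "anova.csv")
  wr(result$anova$tukey, "tukey_hsd.csv")
  log_tab <- tibble::tibble(field = names(result$log),
                            value = vapply(result$log, as.character, ""))
  wr(log_tab, "run_log.csv")
  invisible(NULL)
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat("Calibration pipeline result (config ", x$log$config_hash, ")\n\n",
      sep = "")
  print(x$fit)
  cat("\nCut-points (counts/min):\n")
  print(as.data.frame(x$cutpoints), digits = 4)
  invisible(x)
}

#' Check a coefficient table against its own printed cut-points
#'
#' Reads a coefficient file in the fit-report dialect (columns `stratum`,
#' `b0`, `b1` and printed cut-points `cp3`, `cp6`, `cp9`), recomputes the
#' cut-points by inverting each equation at 3, 6 and 9 METs, and reports the
#' relative deviation from the printed values. With no argument, the shipped
#' published reference table is checked.
#'
#' @param coefficients Path to a CSV, or a data frame, in the dialect of
#'   [reference_calibration()]. Default: the shipped reference.
#' @return Tibble: `stratum`, `threshold_met`, `printed`, `recomputed`,
#'   `rel_dev`.
#' @export
validate_reference <- function(coefficients = reference_calibration()) {
  if (is.character(coefficients)) {
    coefficients <- tryCatch(
      read.csv(coefficients, stringsAsFactors = FALSE),
      error = function(e) stop("cannot parse coefficient file: ",
                               conditionMessage(e)))
  }
  need <- c("stratum", "b0", "b1", "cp3", "cp6", "cp9")
  miss <- setdiff(need, names(coefficients))
  if (length(miss) > 0)
    stop("coefficient table lacks columns: ", paste(miss, collapse = ", "))
  rows <- list()
  for (i in seq_len(nrow(coefficients))) {
    r <- coefficients[i, ]
    parts <- strsplit(as.character(r$stratum), "_", fixed = TRUE)[[1]]
    eq <- make_stratum_equation(r$b0, r$b1, parts[1], parts[2])
    for (m in c(3, 6, 9)) {
      printed <- r[[paste0("cp", m)]]
      recomputed <- invert_cutpoint(eq, m)
      rows[[length(rows) + 1]] <- tibble::tibble(
        stratum = as.character(r$stratum), threshold_met = m,
        printed = printed, recomputed = recomputed,
        rel_dev = (recomputed - printed) / printed
      )
    }
  }
  dplyr::bind_rows(rows)
}
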