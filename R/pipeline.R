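#' Read and write trial tables
#'
#' Trial tables are plain UTF-8 CSV with a header and `.` decimal separator,
#' columns `subject_id, group, phase, condition, trial, temperature_c, vas`
#' (`group`/`temperature_c` optional). [read_trials()] validates phases,
#' conditions and the VAS range on read and reports the offending file.
#'
#' @param path File path.
#' @param trials Trial table data frame.
#' @return [read_trials()]: the validated data frame. [write_trials()]:
#'   `path`, invisibly.
#' @export
read_trials <- function(path) {
  if (!file.exists(path))
    stop("trial file not found: ", path, call. = FALSE)
  df <- tryCatch(utils::read.csv(path, stringsAsFactors = FALSE),
                 error = function(e)
                   stop("failed to parse '", path, "': ", conditionMessage(e),
                        call. = FALSE))
  tryCatch(check_trials(df),
           error = function(e)
             stop("invalid trial table '", path, "': ", conditionMessage(e),
                  call. = FALSE))
}

#' @rdname read_trials
#' @export
write_trials <- function(trials, path) {
  utils::write.csv(check_trials(trials), path, row.names = FALSE)
  invisible(path)
}

#' Export per-subject covariates for second-level analyses
#'
#' Builds the covariate table consumed by downstream (e.g. neuroimaging
#' second-level) analyses: one row per subject with the attraction weight
#' `w_prior`, the prior mean `mu_prior`, the natural log of the prior spread
#' `log_sigma_prior`, and the posterior model probability `p_bayes`.
#'
#' @param fit A [placebo_bayes()] fit.
#' @param center Mean-center the covariate columns (default `FALSE`).
#' @param path Optional path; when given, the table is written as
#'   tab-separated text with a header.
#' @return The covariate data frame (invisibly when `path` is given).
#' @export
export_covariates <- function(fit, center = FALSE, path = NULL) {
  stopifnot(inherits(fit, "placebo_bayes"))
  m <- fit$models[fit$models$model == "bayes", , drop = FALSE]
  ev <- fit$evidence
  if (!setequal(m$subject_id, ev$subject_id))
    stop("subjects missing from the evidence table: ",
         paste(setdiff(m$subject_id, ev$subject_id), collapse = ", "),
         call. = FALSE)
  out <- merge(data.frame(subject_id = m$subject_id, w_prior = m$w_prior,
                          mu_prior = m$mu_prior,
                          log_sigma_prior = log(m$sigma_prior),
                          stringsAsFactors = FALSE),
               ev[, c("subject_id", "p_bayes")], by = "subject_id")
  if (center)
    for (col in c("w_prior", "mu_prior", "log_sigma_prior", "p_bayes"))
      out[[col]] <- out[[col]] - mean(out[[col]])
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
    return(invisible(out))
  }
  out
}

#' Run the full pipeline and write every result to disk
#'
#' End-to-end driver: simulates a cohort (or loads an existing trial CSV),
#' fits [placebo_bayes()], and writes all intermediate and final tables plus
#' a JSON manifest with the configuration, seeds and MD5 hashes of every
#' output file, so a run is fully re-derivable from the manifest alone.
#'
#' Files written to `output_dir`: `trials.csv`, `ground_truth.csv` (simulated
#' runs), `subject_models.csv`, `evidence.csv`, `summaries.csv`,
#' `rfx.json`, `regression.json`, `covariates.tsv`, `long_format.csv`
#' (tidy export for external mixed-model tools), `report.txt`,
#' `manifest.json`.
#'
#' @param cohort A [cohort_config()] to simulate, or a path to a trial CSV.
#' @param output_dir Directory (created if needed).
#' @param ... Passed to [placebo_bayes()] (sigma floor, conventions,
#'   thresholds, RFX settings).
#' @return The manifest, invisibly (list; also written as JSON).
#' @export
run_pipeline <- function(cohort = cohort_config(), output_dir, ...) {
  stopifnot(is.character(output_dir), length(output_dir) == 1L)
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(output_dir, f)

  if (inherits(cohort, "cohort_config")) {
    sim <- simulate_cohort(cohort)
    trials <- sim$trials
    write_trials(trials, p("trials.csv"))
    utils::write.csv(sim$ground_truth, p("ground_truth.csv"), row.names = FALSE)
    cohort_desc <- unclass(cohort)
  } else {
    trials <- read_trials(cohort)
    write_trials(trials, p("trials.csv"))
    cohort_desc <- list(source = cohort)
  }

  fit <- placebo_bayes(trials, ...)
  utils::write.csv(fit$models, p("subject_models.csv"), row.names = FALSE)
  ev <- fit$evidence
  for (col in c("p_bayes", "p_null")) ev[[col]] <- round(ev[[col]], 6L)
  utils::write.csv(ev, p("evidence.csv"), row.names = FALSE)
  utils::write.csv(fit$summaries, p("summaries.csv"), row.names = FALSE)
  jsonlite::write_json(list(alpha = fit$rfx$alpha,
                            expected_prob = fit$rfx$expected_prob,
                            exceedance_prob = fit$rfx$exceedance_prob,
                            converged = fit$rfx$converged,
                            iterations = fit$rfx$iterations,
                            seed = fit$rfx$seed),
                       p("rfx.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(fit$regression))
    jsonlite::write_json(fit$regression[c("coefficients", "std_coefficients",
                                          "se", "t", "p_value", "r_squared",
                                          "adj_r_squared", "f_statistic",
                                          "df", "n")],
                         p("regression.json"), auto_unbox = TRUE, digits = NA)
  export_covariates(fit, path = p("covariates.tsv"))
  long <- trials[, intersect(c("subject_id", "group", "phase", "condition",
                               "trial", "vas"), names(trials))]
  utils::write.csv(long, p("long_format.csv"), row.names = FALSE)

  sm <- summary(fit)
  writeLines(utils::capture.output(print(sm)), p("report.txt"))

  files <- setdiff(list.files(output_dir), "manifest.json")
  manifest <- list(
    package_version = as.character(utils::packageVersion("bayesplacebo")),
    r_version = as.character(getRversion()),
    cohort = cohort_desc,
    settings = fit$settings,
    files = as.list(tools::md5sum(file.path(output_dir, sort(files)))))
  names(manifest$files) <- sort(files)
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
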