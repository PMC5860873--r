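#' Per-subject behavioural summaries
#'
#' Computes, for every subject in a trial table, the cell means and
#' descriptive standard deviations (n-1 denominator, the reporting
#' convention) of all four phase-condition cells, and the observed placebo
#' effect: mean test-phase control rating minus mean test-phase placebo
#' rating, so positive values mean pain relief under identical stimulation.
#' Individual treatment variability is the SD of the conditioning-phase
#' placebo ratings (`sd_cond_placebo`).
#'
#' @param trials Trial table (see [fit_subject()] for the required columns);
#'   a `group` column, if present, is carried through.
#' @return Data frame, one row per subject: `subject_id`, `group`,
#'   `mean_*`/`sd_*` for the four cells, `placebo_effect_observed`.
#' @export
summarize_subjects <- function(trials) {
  trials <- check_trials(trials)
  ids <- unique(trials$subject_id)
  rows <- lapply(ids, function(id) {
    sub <- trials[trials$subject_id == id, , drop = FALSE]
    cell <- function(phase, condition) {
      v <- sub$vas[sub$phase == phase & sub$condition == condition]
      if (length(v) < 2L)
        stop(sprintf("subject '%s' is missing ratings in the %s %s cell",
                     id, phase, condition), call. = FALSE)
      v
    }
    cp <- cell("conditioning", "placebo"); cc <- cell("conditioning", "control")
    tp <- cell("test", "placebo");        tc <- cell("test", "control")
    data.frame(subject_id = id,
               group = if ("group" %in% names(sub)) sub$group[1L] else NA_character_,
               mean_cond_placebo = mean(cp), sd_cond_placebo = stats::sd(cp),
               mean_cond_control = mean(cc), sd_cond_control = stats::sd(cc),
               mean_test_placebo = mean(tp), sd_test_placebo = stats::sd(tp),
               mean_test_control = mean(tc), sd_test_control = stats::sd(tc),
               placebo_effect_observed = mean(tc) - mean(tp),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Precision-manipulation sub-sample selection
#'
#' Flags the subjects in whom the conditioning manipulation demonstrably
#' induced the intended treatment-precision level, using variance cut-offs
#' derived from an independent behavioural sample: HTP subjects are kept when
#' their conditioning-placebo rating variance is strictly below 384.08
#' (SD 19.60) -- i.e. they are more precise than that sample's average LTP
#' group -- and LTP subjects are kept when it is strictly above 194.90
#' (SD 13.96). No ratings are altered; rows are only flagged.
#'
#' @param summaries Output of [summarize_subjects()]; `group` must be
#'   `"HTP"` or `"LTP"`.
#' @param htp_var_max,ltp_var_min Variance cut-offs (defaults 384.08 and
#'   194.90).
#' @return `summaries` with a logical `in_subsample` column added.
#' @export
apply_subsample_cutoffs <- function(summaries, htp_var_max = 384.08,
                                    ltp_var_min = 194.90) {
  stopifnot(is.data.frame(summaries),
            all(c("group", "sd_cond_placebo") %in% names(summaries)))
  if (!all(summaries$group %in% c("HTP", "LTP")))
    stop("'group' must be 'HTP' or 'LTP' for sub-sample selection",
         call. = FALSE)
  v <- summaries$sd_cond_placebo^2
  summaries$in_subsample <- ifelse(summaries$group == "HTP",
                                   v < htp_var_max, v > ltp_var_min)
  summaries
}

#' Pearson correlation with a two-sided test
#'
#' Thin wrapper over the standard product-moment correlation test, returning
#' the coefficient and the t-based two-sided p value.
#'
#' @param x,y Numeric vectors of equal length (at least 3), each with
#'   non-zero variance.
#' @return List with `r`, `p_value`, `n`, `df`, `t`.
#' @export
pearson_correlation <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("'x' and 'y' must have equal length >= 3", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("correlation undefined: an input has zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x),
       df = unname(ct$parameter), t = unname(ct$statistic))
}

#' Regression of the placebo effect on prior and likelihood spread
#'
#' Ordinary least squares of the observed placebo effect on the fitted prior
#' and likelihood standard deviations (Bayesian-integration model), with an
#' intercept:
#' \deqn{effect_i = b_0 + b_1\,\sigma_{prior,i} + b_2\,\sigma_{like,i} +
#'   \varepsilon_i.}
#' A negative \eqn{b_1} means subjects with a less precise (more variable)
#' treatment expectation show smaller placebo effects, controlling for
#' sensory precision. Unstandardised coefficients are reported (the scale on
#' which a prediction equation is written) together with standardised ones.
#'
#' @param summaries Output of [summarize_subjects()].
#' @param models Data frame with columns `subject_id`, `sigma_prior`,
#'   `sigma_like` (e.g. the bayes-model rows of a [placebo_bayes()] fit's
#'   `$models` table).
#' @return List of class `"placebo_regression"`: `coefficients` (named
#'   vector), `std_coefficients`, `se`, `t`, `p_value`, `r_squared`,
#'   `adj_r_squared`, `f_statistic`, `df`, `n`, and the underlying `lm` fit.
#' @export
regress_placebo_on_sigmas <- function(summaries, models) {
  stopifnot(is.data.frame(summaries), is.data.frame(models),
            all(c("subject_id", "placebo_effect_observed") %in% names(summaries)),
            all(c("subject_id", "sigma_prior", "sigma_like") %in% names(models)))
  dat <- merge(summaries[, c("subject_id", "placebo_effect_observed")],
               models[, c("subject_id", "sigma_prior", "sigma_like")],
               by = "subject_id")
  if (nrow(dat) < 4L)
    stop("need at least 4 subjects for the regression", call. = FALSE)
  if (stats::sd(dat$sigma_prior) == 0 || stats::sd(dat$sigma_like) == 0 ||
      abs(stats::cor(dat$sigma_prior, dat$sigma_like)) > 1 - 1e-12)
    stop("rank-deficient design: predictors are (nearly) collinear",
         call. = FALSE)
  fit <- stats::lm(placebo_effect_observed ~ sigma_prior + sigma_like,
                   data = dat)
  sm <- summary(fit)
  coefs <- stats::coef(fit)
  sds <- vapply(dat[c("sigma_prior", "sigma_like")], stats::sd, numeric(1L))
  std <- coefs[-1L] * sds / stats::sd(dat$placebo_effect_observed)
  fstat <- sm$fstatistic
  structure(list(coefficients = coefs,
                 std_coefficients = std,
                 se = sm$coefficients[, "Std. Error"],
                 t = sm$coefficients[, "t value"],
                 p_value = sm$coefficients[, "Pr(>|t|)"],
                 r_squared = sm$r.squared, adj_r_squared = sm$adj.r.squared,
                 f_statistic = unname(fstat[1L]),
                 df = unname(fstat[2:3]), n = nrow(dat), lm_fit = fit),
            class = "placebo_regression")
}

#' @export
print.placebo_regression <- function(x, ...) {
  cat("Placebo effect ~ sigma_prior + sigma_like (OLS)\n")
  cat(sprintf("  effect = %.3f %+.3f*sigma_prior %+.3f*sigma_like\n",
              x$coefficients[1L], x$coefficients[2L], x$coefficients[3L]))
  cat(sprintf("  R^2 = %.3f (adj. %.3f), F(%d, %d) = %.2f, n = %d\n",
              x$r_squared, x$adj_r_squared, x$df[1L], x$df[2L],
              x$f_statistic, x$n))
  invisible(x)
}
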