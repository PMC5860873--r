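#' Fit the Bayesian-integration analysis of placebo hypoalgesia
#'
#' The package's central fitting function. Given trial-level pain ratings
#' from a two-phase conditioning/test experiment it runs, per subject:
#' \enumerate{
#'   \item maximum-likelihood Gaussian fits of the treatment-expectation
#'     prior (conditioning placebo ratings) and the sensory likelihood
#'     (test control ratings), plus the Null model's prior (conditioning
#'     control ratings);
#'   \item precision-weighted integration into each model's predicted
#'     posterior percept and attraction weight;
#'   \item model comparison on the test-phase placebo ratings through the
#'     conjugate Gaussian marginal likelihood, giving Bayes factors and
#'     posterior model probabilities;
#' }
#' and, across subjects: the positive evidence ratio, random-effects
#' Bayesian model selection, behavioural summaries with the
#' precision-manipulation sub-sample flags, the predicted-versus-observed
#' placebo-effect correlation, the attraction-weight correlation, and the
#' regression of the placebo effect on prior and likelihood spread.
#'
#' @param data Trial table: a data frame with columns `subject_id`, `phase`
#'   (`"conditioning"`/`"test"`), `condition` (`"placebo"`/`"control"`),
#'   `trial`, `vas` (0-100), optionally `group` (`"HTP"`/`"LTP"`) and
#'   `temperature_c`. See [simulate_cohort()] and [read_trials()].
#' @param sigma_floor Smallest admissible fitted or observation sigma, VAS
#'   units (default 0.5).
#' @param sigma_obs_convention `"n_minus_1"` (default) or `"n"`: denominator
#'   for the observation-noise SD in the evidence stage.
#' @param evidence_model_input `"posterior"` (default) or `"prior"`: which of
#'   a model's distributions enters the marginal likelihood as
#'   \eqn{(\mu_M, \sigma_M)}.
#' @param per_threshold Bayes-factor cut-off for the positive evidence ratio
#'   (default 3, strict).
#' @param rfx_prior_alpha Dirichlet prior concentration for the RFX stage
#'   (default 1).
#' @param rfx_seed Seed for the RFX Monte-Carlo sampler (only used for
#'   three or more models; recorded regardless).
#' @return An object of class `"placebo_bayes"` with components
#' \describe{
#'   \item{models}{data frame, two rows (bayes/null) per subject: fitted
#'     `mu_prior`, `sigma_prior`, `mu_like`, `sigma_like`, posterior
#'     `mu_post`, `sigma_post`, `w_prior`, `w_like`,
#'     `predicted_placebo_effect`, degeneracy flags.}
#'   \item{evidence}{data frame, one row per subject: log evidences,
#'     `bf_10`, `bf_01`, `p_bayes`, `p_null`, `sigma_obs`, `n_obs`.}
#'   \item{per}{positive evidence ratio (list; see
#'     [positive_evidence_ratio()]).}
#'   \item{rfx}{[rfx_model_selection()] result over (bayes, null).}
#'   \item{summaries}{behavioural summary table with `in_subsample`,
#'     `placebo_effect_predicted` and `w_prior` merged in.}
#'   \item{correlations}{predicted-vs-observed effect and
#'     attraction-weight-vs-observed effect Pearson tests.}
#'   \item{regression}{[regress_placebo_on_sigmas()] result.}
#'   \item{trials, settings, call}{inputs for reproducibility.}
#' }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_htp = 6, n_ltp = 6, seed = 11))
#' fit <- placebo_bayes(cohort$trials)
#' print(fit)
#' summary(fit)
#' @seealso [summary.placebo_bayes()], [export_covariates()],
#'   [write_placebo_results()]
#' @export
placebo_bayes <- function(data, sigma_floor = 0.5,
                          sigma_obs_convention = c("n_minus_1", "n"),
                          evidence_model_input = c("posterior", "prior"),
                          per_threshold = 3, rfx_prior_alpha = 1,
                          rfx_seed = 1L) {
  cl <- match.call()
  sigma_obs_convention <- match.arg(sigma_obs_convention)
  evidence_model_input <- match.arg(evidence_model_input)
  trials <- check_trials(data)
  ids <- unique(trials$subject_id)
  if (length(ids) < 1L) stop("no subjects in 'data'", call. = FALSE)

  model_rows <- vector("list", length(ids))
  ev_rows <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    id <- ids[i]
    sm <- build_subject_models(trials, id, sigma_floor)
    model_rows[[i]] <- do.call(rbind, lapply(sm, subject_model_row))

    tp <- trials$vas[trials$subject_id == id & trials$phase == "test" &
                       trials$condition == "placebo"]
    pick <- function(m) if (evidence_model_input == "posterior") m$posterior
                        else m$prior
    ev <- compare_models(tp, pick(sm$bayes), pick(sm$null),
                         sigma_obs_convention, sigma_floor)
    ev_rows[[i]] <- data.frame(subject_id = id,
                               log_evidence_bayes = ev$log_evidence_bayes,
                               log_evidence_null = ev$log_evidence_null,
                               bf_10 = ev$bf_10, bf_01 = ev$bf_01,
                               p_bayes = ev$p_bayes, p_null = ev$p_null,
                               sigma_obs = ev$sigma_obs, n_obs = ev$n_obs,
                               sigma_obs_degenerate = ev$sigma_obs_degenerate,
                               stringsAsFactors = FALSE)
  }
  models <- do.call(rbind, model_rows)
  rownames(models) <- NULL
  evidence <- do.call(rbind, ev_rows)

  le <- cbind(bayes = evidence$log_evidence_bayes,
              null = evidence$log_evidence_null)
  rfx <- rfx_model_selection(le, prior_alpha = rfx_prior_alpha, seed = rfx_seed)
  per <- positive_evidence_ratio(evidence, threshold = per_threshold)

  summaries <- summarize_subjects(trials)
  if (all(summaries$group %in% c("HTP", "LTP")))
    summaries <- apply_subsample_cutoffs(summaries)
  bayes_models <- models[models$model == "bayes", , drop = FALSE]
  summaries <- merge(summaries,
                     bayes_models[, c("subject_id", "w_prior",
                                      "predicted_placebo_effect")],
                     by = "subject_id", sort = FALSE)
  names(summaries)[names(summaries) == "predicted_placebo_effect"] <-
    "placebo_effect_predicted"

  correlations <- list(predicted_vs_observed = NULL, w_prior_vs_observed = NULL)
  if (nrow(summaries) >= 3L &&
      stats::sd(summaries$placebo_effect_predicted) > 0 &&
      stats::sd(summaries$placebo_effect_observed) > 0) {
    correlations$predicted_vs_observed <-
      pearson_correlation(summaries$placebo_effect_predicted,
                          summaries$placebo_effect_observed)
    if (stats::sd(summaries$w_prior) > 0)
      correlations$w_prior_vs_observed <-
        pearson_correlation(summaries$w_prior,
                            summaries$placebo_effect_observed)
  }
  regression <- if (nrow(summaries) >= 4L)
    tryCatch(regress_placebo_on_sigmas(summaries, bayes_models),
             error = function(e) NULL)

  structure(list(models = models, evidence = evidence, per = per, rfx = rfx,
                 summaries = summaries, correlations = correlations,
                 regression = regression, trials = trials,
                 settings = list(sigma_floor = sigma_floor,
                                 sigma_obs_convention = sigma_obs_convention,
                                 evidence_model_input = evidence_model_input,
                                 per_threshold = per_threshold,
                                 rfx_prior_alpha = rfx_prior_alpha,
                                 rfx_seed = rfx_seed),
                 call = cl),
            class = "placebo_bayes")
}

subject_model_row <- function(m) {
  data.frame(subject_id = m$subject_id, model = m$model,
             mu_prior = m$prior$mu, sigma_prior = m$prior$sigma,
             mu_like = m$likelihood$mu, sigma_like = m$likelihood$sigma,
             mu_post = m$posterior$mu, sigma_post = m$posterior$sigma,
             w_prior = m$w_prior, w_like = m$w_like,
             predicted_placebo_effect = m$predicted_placebo_effect,
             prior_degenerate = m$prior$degenerate,
             like_degenerate = m$likelihood$degenerate,
             stringsAsFactors = FALSE)
}

#' @export
print.placebo_bayes <- function(x, ...) {
  n <- nrow(x$evidence)
  cat("Bayesian-integration analysis of placebo hypoalgesia\n")
  cat(sprintf("  %d subjects; evidence input: model %s; sigma_obs: %s SD\n",
              n, x$settings$evidence_model_input,
              sub("_", "-", x$settings$sigma_obs_convention)))
  cat(sprintf("  RFX expected p(bayes) = %.3f (exceedance %.3f)\n",
              x$rfx$expected_prob[["bayes"]], x$rfx$exceedance_prob[["bayes"]]))
  cat(sprintf("  PER: %d vs %d subjects with BF > %g -> %s\n",
              x$per$n_favoring_bayes, x$per$n_favoring_null, x$per$threshold,
              if (is.na(x$per$per)) "undefined" else sprintf("%.2f", x$per$per)))
  invisible(x)
}

#' Summarise a fitted placebo-integration analysis
#'
#' @param object A [placebo_bayes()] fit.
#' @param ... Unused.
#' @return An object of class `"summary.placebo_bayes"` collecting group-level
#'   placebo effects and treatment variability, model-selection results and
#'   the behavioural correlations/regression, with a print method.
#' @export
summary.placebo_bayes <- function(object, ...) {
  s <- object$summaries
  by_group <- NULL
  if (all(s$group %in% c("HTP", "LTP"))) {
    by_group <- do.call(rbind, lapply(split(s, s$group), function(g)
      data.frame(group = g$group[1L], n = nrow(g),
                 mean_effect = mean(g$placebo_effect_observed),
                 sd_effect = stats::sd(g$placebo_effect_observed),
                 mean_sd_cond_placebo = mean(g$sd_cond_placebo),
                 n_in_subsample = if ("in_subsample" %in% names(g))
                   sum(g$in_subsample) else NA_integer_,
                 stringsAsFactors = FALSE)))
    rownames(by_group) <- NULL
  }
  structure(list(n_subjects = nrow(object$evidence), by_group = by_group,
                 overall_effect = mean(s$placebo_effect_observed),
                 per = object$per, rfx = object$rfx,
                 correlations = object$correlations,
                 regression = object$regression,
                 settings = object$settings),
            class = "summary.placebo_bayes")
}

#' @export
print.summary.placebo_bayes <- function(x, ...) {
  cat("Bayesian-integration analysis of placebo hypoalgesia\n")
  cat(sprintf("Subjects: %d; mean observed placebo effect %.2f VAS\n",
              x$n_subjects, x$overall_effect))
  if (!is.null(x$by_group)) {
    cat("\nGroup summaries (placebo effect = test control - test placebo):\n")
    print(x$by_group, row.names = FALSE, digits = 4)
  }
  cat("\nModel selection:\n")
  cat(sprintf("  RFX expected model probabilities: bayes %.3f, null %.3f\n",
              x$rfx$expected_prob[["bayes"]], x$rfx$expected_prob[["null"]]))
  cat(sprintf("  exceedance probabilities:         bayes %.4f, null %.4f\n",
              x$rfx$exceedance_prob[["bayes"]], x$rfx$exceedance_prob[["null"]]))
  cat(sprintf("  PER (threshold %g): %d / %d = %s\n", x$per$threshold,
              x$per$n_favoring_bayes, x$per$n_favoring_null,
              if (is.na(x$per$per)) "undefined" else sprintf("%.2f", x$per$per)))
  co <- x$correlations
  if (!is.null(co$predicted_vs_observed))
    cat(sprintf("\nPredicted vs observed placebo effect: r = %.3f, p = %.3g\n",
                co$predicted_vs_observed$r, co$predicted_vs_observed$p_value))
  if (!is.null(co$w_prior_vs_observed))
    cat(sprintf("Attraction weight vs observed effect: r = %.3f, p = %.3g\n",
                co$w_prior_vs_observed$r, co$w_prior_vs_observed$p_value))
  if (!is.null(x$regression)) { cat("\n"); print(x$regression) }
  invisible(x)
}

#' Extract fitted per-subject parameters
#'
#' @param object A [placebo_bayes()] fit.
#' @param model `"bayes"` (default) or `"null"`.
#' @param ... Unused.
#' @return Numeric matrix, one row per subject, columns `mu_prior`,
#'   `sigma_prior`, `mu_like`, `sigma_like`, `mu_post`, `sigma_post`,
#'   `w_prior`.
#' @export
coef.placebo_bayes <- function(object, model = c("bayes", "null"), ...) {
  model <- match.arg(model)
  m <- object$models[object$models$model == model, , drop = FALSE]
  out <- as.matrix(m[, c("mu_prior", "sigma_prior", "mu_like", "sigma_like",
                         "mu_post", "sigma_post", "w_prior")])
  rownames(out) <- m$subject_id
  out
}

#' Model predictions per subject
#'
#' @param object A [placebo_bayes()] fit.
#' @param type `"placebo_effect"` (default; predicted
#'   \eqn{\mu_{like} - \mu_{post}}) or `"posterior_mean"` (predicted treated
#'   percept \eqn{\mu_{post}}).
#' @param model `"bayes"` (default) or `"null"`.
#' @param ... Unused.
#' @return Named numeric vector, one element per subject.
#' @export
predict.placebo_bayes <- function(object, type = c("placebo_effect",
                                                   "posterior_mean"),
                                  model = c("bayes", "null"), ...) {
  type <- match.arg(type)
  model <- match.arg(model)
  m <- object$models[object$models$model == model, , drop = FALSE]
  out <- if (type == "placebo_effect") m$predicted_placebo_effect else m$mu_post
  stats::setNames(out, m$subject_id)
}

#' Residual placebo effects
#'
#' Observed minus predicted placebo effect per subject, under the
#' Bayesian-integration model.
#'
#' @param object A [placebo_bayes()] fit.
#' @param ... Unused.
#' @return Named numeric vector.
#' @export
residuals.placebo_bayes <- function(object, ...) {
  s <- object$summaries
  stats::setNames(s$placebo_effect_observed - s$placebo_effect_predicted,
                  s$subject_id)
}

#' Simulate test-placebo ratings from the fitted posteriors
#'
#' Draws new test-phase placebo ratings for every subject from that
#' subject's fitted Bayesian-integration posterior (a posterior predictive
#' check at the rating-mean level; observation noise is not added on top, as
#' the posterior already carries the integrated spread).
#'
#' @param object A [placebo_bayes()] fit.
#' @param nsim Number of replicate rating sets (default 1).
#' @param seed Seed; the caller's RNG state is preserved.
#' @param n_trials Ratings per subject per replicate (default: the observed
#'   test-placebo trial count).
#' @param ... Unused.
#' @return Data frame: `sim`, `subject_id`, `trial`, `vas`.
#' @export
simulate.placebo_bayes <- function(object, nsim = 1, seed = 1L,
                                   n_trials = NULL, ...) {
  m <- object$models[object$models$model == "bayes", , drop = FALSE]
  if (is.null(n_trials)) n_trials <- object$evidence$n_obs[1L]
  with_preserved_rng(seed, {
    reps <- lapply(seq_len(nsim), function(s) {
      do.call(rbind, lapply(seq_len(nrow(m)), function(i)
        data.frame(sim = s, subject_id = m$subject_id[i],
                   trial = seq_len(n_trials),
                   vas = pmin(pmax(stats::rnorm(n_trials, m$mu_post[i],
                                                m$sigma_post[i]), 0), 100),
                   stringsAsFactors = FALSE)))
    })
    do.call(rbind, reps)
  })
}

#' Diagnostic plots for a placebo-integration fit
#'
#' Two base-graphics panels: predicted versus observed placebo effect with
#' the identity line and the OLS trend, and one subject's prior, likelihood
#' and posterior densities.
#'
#' @param x A [placebo_bayes()] fit.
#' @param subject Subject id for the density panel (default: the subject
#'   with the largest Bayes factor).
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.placebo_bayes <- function(x, subject = NULL, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op), add = TRUE)

  s <- x$summaries
  plot(s$placebo_effect_predicted, s$placebo_effect_observed,
       xlab = "predicted placebo effect (VAS)",
       ylab = "observed placebo effect (VAS)",
       main = "Predicted vs observed", pch = 19,
       col = ifelse(s$group == "HTP", "#2166AC", "#B2182B"), ...)
  graphics::abline(0, 1, lty = 2)
  if (nrow(s) >= 3L)
    graphics::abline(stats::lm(placebo_effect_observed ~
                                 placebo_effect_predicted, data = s))

  if (is.null(subject))
    subject <- x$evidence$subject_id[which.max(x$evidence$bf_10)]
  m <- x$models[x$models$subject_id == subject & x$models$model == "bayes", ]
  grid <- seq(0, 100, length.out = 512L)
  dens <- cbind(prior = stats::dnorm(grid, m$mu_prior, m$sigma_prior),
                likelihood = stats::dnorm(grid, m$mu_like, m$sigma_like),
                posterior = stats::dnorm(grid, m$mu_post, m$sigma_post))
  graphics::matplot(grid, dens, type = "l", lty = c(2, 3, 1), lwd = 2,
                    col = c("#2166AC", "#B2182B", "black"),
                    xlab = "VAS", ylab = "density",
                    main = paste("Subject", subject))
  graphics::legend("topright", c("prior", "likelihood", "posterior"),
                   lty = c(2, 3, 1), lwd = 2,
                   col = c("#2166AC", "#B2182B", "black"), bty = "n")
  invisible(x)
}
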