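#' Attraction weight: relative precision of the prior
#'
#' The weight the prior receives in the precision-weighted combination,
#' \deqn{w_{prior} = \frac{1/\sigma_{prior}^2}
#'   {1/\sigma_{prior}^2 + 1/\sigma_{like}^2}, \qquad
#'   w_{like} = 1 - w_{prior},}
#' i.e. the prior precision divided by the total precision. It is computed on
#' the variance ratio, \eqn{w_{prior} = \sigma_{like}^2 /
#' (\sigma_{like}^2 + \sigma_{prior}^2)}, which cannot overflow when a
#' floored (very small) sigma produces a huge precision.
#'
#' @param prior,likelihood [gaussian_params()] objects (or lists with `mu`
#'   and positive `sigma`).
#' @return Named numeric vector `c(w_prior = , w_like = )`, each in
#'   \eqn{[0, 1]}, summing to 1.
#' @examples
#' attraction_weight(gaussian_params(30, 10), gaussian_params(50, 20))
#' @export
attraction_weight <- function(prior, likelihood) {
  sp <- check_sigma(prior, "prior")
  sl <- check_sigma(likelihood, "likelihood")
  w_prior <- sl^2 / (sl^2 + sp^2)
  c(w_prior = w_prior, w_like = 1 - w_prior)
}

#' Precision-weighted integration of prior and likelihood
#'
#' Combines two Gaussians by Bayes' rule (normalised density product): the
#' posterior mean is the precision-weighted mean and the posterior precision
#' is the sum of the precisions,
#' \deqn{\mu_{post} = w_{prior}\,\mu_{prior} + w_{like}\,\mu_{like}, \qquad
#'       1/\sigma_{post}^2 = 1/\sigma_{prior}^2 + 1/\sigma_{like}^2.}
#' This is the model's predicted percept of the treated (placebo) test
#' stimulus: a treatment expectation (prior) pulls the experienced pain away
#' from the sensory evidence (likelihood) in proportion to its relative
#' precision.
#'
#' @inheritParams attraction_weight
#' @return A [gaussian_params()] posterior.
#' @examples
#' integrate_gaussians(gaussian_params(30, 10), gaussian_params(50, 20))
#' # Gaussian(mu = 34, sigma = sqrt(80))
#' @export
integrate_gaussians <- function(prior, likelihood) {
  sp <- check_sigma(prior, "prior")
  sl <- check_sigma(likelihood, "likelihood")
  w <- attraction_weight(prior, likelihood)
  mu_post <- w[["w_prior"]] * prior$mu + w[["w_like"]] * likelihood$mu
  # sigma_post = sqrt(sp^2 sl^2 / (sp^2 + sl^2)), written to avoid overflow
  sigma_post <- sp * sl / sqrt(sp^2 + sl^2)
  gaussian_params(mu_post, sigma_post)
}

#' Assemble a subject's integration model
#'
#' Bundles a fitted prior/likelihood pair into the full per-subject model:
#' posterior, attraction weights and the predicted placebo effect
#' \eqn{\mu_{like} - \mu_{post}} (how far the treatment expectation pulls the
#' predicted percept below the untreated evidence).
#'
#' @param subject_id Subject identifier carried through to the output.
#' @param model `"bayes"` or `"null"` label for the prior's provenance.
#' @param prior,likelihood [gaussian_params()] objects.
#' @return An object of class `"subject_model"`: list with `subject_id`,
#'   `model`, `prior`, `likelihood`, `posterior`, `w_prior`, `w_like`,
#'   `predicted_placebo_effect`.
#' @export
subject_model <- function(subject_id, model, prior, likelihood) {
  posterior <- integrate_gaussians(prior, likelihood)
  w <- attraction_weight(prior, likelihood)
  structure(list(subject_id = as.character(subject_id),
                 model = match.arg(model, c("bayes", "null")),
                 prior = prior, likelihood = likelihood, posterior = posterior,
                 w_prior = w[["w_prior"]], w_like = w[["w_like"]],
                 predicted_placebo_effect = likelihood$mu - posterior$mu),
            class = "subject_model")
}

#' Fit both candidate models for one subject
#'
#' Runs [fit_subject()] under the Bayesian-integration and Null priors and
#' assembles the two [subject_model()]s. Both models share the likelihood
#' (test-phase control ratings); only the prior differs.
#'
#' @inheritParams fit_subject
#' @return Named list `list(bayes = , null = )` of `subject_model` objects.
#' @export
build_subject_models <- function(trials, subject_id, sigma_floor = 0.5) {
  fb <- fit_subject(trials, subject_id, "bayes", sigma_floor)
  fn <- fit_subject(trials, subject_id, "null", sigma_floor)
  list(bayes = subject_model(subject_id, "bayes", fb$prior, fb$likelihood),
       null = subject_model(subject_id, "null", fn$prior, fn$likelihood))
}

#' @export
print.subject_model <- function(x, ...) {
  cat(sprintf("Subject %s, %s-model integration\n", x$subject_id, x$model))
  cat(sprintf("  prior:      mu %7.3f  sigma %7.3f\n", x$prior$mu, x$prior$sigma))
  cat(sprintf("  likelihood: mu %7.3f  sigma %7.3f\n",
              x$likelihood$mu, x$likelihood$sigma))
  cat(sprintf("  posterior:  mu %7.3f  sigma %7.3f\n",
              x$posterior$mu, x$posterior$sigma))
  cat(sprintf("  w_prior %.3f   predicted placebo effect %.3f VAS\n",
              x$w_prior, x$predicted_placebo_effect))
  invisible(x)
}

check_sigma <- function(g, what) {
  if (!is.list(g) || is.null(g$sigma) || is.null(g$mu))
    stop("'", what, "' must be a gaussian_params-like object", call. = FALSE)
  if (!is.finite(g$sigma) || g$sigma <= 0)
    stop("'", what, "' sigma must be positive and finite", call. = FALSE)
  g$sigma
}
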