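#' Conjugate Gaussian log marginal likelihood
#'
#' Model evidence for a set of ratings under a Gaussian observation model
#' with a Gaussian prior over the unknown rating mean:
#' \deqn{p(X \mid \mu_M, \sigma_{obs}^2, \sigma_M^2) =
#'   \int \Big[\prod_{i=1}^n N(x_i \mid \mu_{obs}, \sigma_{obs}^2)\Big]
#'   N(\mu_{obs} \mid \mu_M, \sigma_M^2)\, d\mu_{obs}.}
#' The integral is conjugate and evaluated in closed form, in log space, via
#' the numerically stable factorisation
#' \deqn{\log p = -\tfrac{n-1}{2}\log(2\pi\sigma_{obs}^2) - \tfrac12\log n
#'   - \frac{\sum_i (x_i - \bar x)^2}{2\sigma_{obs}^2}
#'   + \log N\!\big(\bar x \mid \mu_M,\ \sigma_M^2 + \sigma_{obs}^2/n\big),}
#' which is algebraically identical to expanding the product-of-Gaussians
#' integral but avoids the cancellation of large \eqn{\mu_M^2/\sigma_M^2}
#' terms when \eqn{\sigma_M} is small.
#'
#' @param data Numeric vector of observed ratings (at least 1, finite).
#' @param model_mu Model-predicted mean \eqn{\mu_M}, VAS units.
#' @param model_sigma Model-predicted spread \eqn{\sigma_M > 0}, VAS units.
#' @param sigma_obs Observation noise SD \eqn{\sigma_{obs} > 0}, VAS units.
#' @return Natural-log marginal density (scalar).
#' @examples
#' log_marginal_likelihood(c(40, 45, 42), model_mu = 43, model_sigma = 5,
#'                         sigma_obs = 3)
#' @export
log_marginal_likelihood <- function(data, model_mu, model_sigma, sigma_obs) {
  if (!is.numeric(data) || length(data) < 1L || !all(is.finite(data)))
    stop("'data' must be a non-empty finite numeric vector", call. = FALSE)
  stopifnot(length(model_mu) == 1L, is.finite(model_mu),
            length(model_sigma) == 1L, length(sigma_obs) == 1L)
  if (!is.finite(model_sigma) || model_sigma <= 0)
    stop("'model_sigma' must be positive", call. = FALSE)
  if (!is.finite(sigma_obs) || sigma_obs <= 0)
    stop("'sigma_obs' must be positive", call. = FALSE)

  n <- length(data)
  xbar <- mean(data)
  ss <- sum((data - xbar)^2)
  -(n - 1) / 2 * log(2 * pi * sigma_obs^2) - 0.5 * log(n) -
    ss / (2 * sigma_obs^2) +
    stats::dnorm(xbar, mean = model_mu,
                 sd = sqrt(model_sigma^2 + sigma_obs^2 / n), log = TRUE)
}

#' Per-subject model comparison via Bayes factors
#'
#' Scores the Bayesian-integration and Null models on a subject's test-phase
#' placebo ratings. Each model contributes its predicted posterior as the
#' evidence distribution over the unknown rating mean; the observation noise
#' \eqn{\sigma_{obs}} is estimated from the same ratings and shared by both
#' models, so the comparison isolates the prior (the only ingredient on which
#' the models differ). With equal model priors, the Bayes factor converts to
#' a posterior model probability as
#' \eqn{p(M_{Bay} \mid X) = BF_{10} / (BF_{10} + 1)}.
#'
#' @param test_placebo_ratings Numeric vector, at least 2 ratings.
#' @param bayes_posterior,null_posterior [gaussian_params()] predicted
#'   posteriors of the two models.
#' @param sigma_obs_convention `"n_minus_1"` (default; sample SD) or `"n"`
#'   (ML SD) for estimating the observation noise.
#' @param sigma_floor Floor applied to a degenerate \eqn{\sigma_{obs}}.
#' @return An object of class `"evidence_result"`: list with
#'   `log_evidence_bayes`, `log_evidence_null`, `bf_10`, `bf_01`, `p_bayes`,
#'   `p_null`, `sigma_obs`, `n_obs`, `sigma_obs_degenerate`. All evidence
#'   arithmetic stays in log space; Bayes factors are exponentiated only here
#'   for reporting.
#' @export
compare_models <- function(test_placebo_ratings, bayes_posterior, null_posterior,
                           sigma_obs_convention = c("n_minus_1", "n"),
                           sigma_floor = 0.5) {
  sigma_obs_convention <- match.arg(sigma_obs_convention)
  x <- test_placebo_ratings
  if (!is.numeric(x) || length(x) < 2L || !all(is.finite(x)))
    stop("need at least 2 finite test-placebo ratings", call. = FALSE)
  n <- length(x)
  ss <- sum((x - mean(x))^2)
  sigma_obs <- sqrt(ss / if (sigma_obs_convention == "n_minus_1") n - 1 else n)
  degenerate <- sigma_obs < sigma_floor
  if (degenerate) sigma_obs <- sigma_floor

  le1 <- log_marginal_likelihood(x, bayes_posterior$mu, bayes_posterior$sigma,
                                 sigma_obs)
  le0 <- log_marginal_likelihood(x, null_posterior$mu, null_posterior$sigma,
                                 sigma_obs)
  log_bf10 <- le1 - le0
  structure(list(log_evidence_bayes = le1, log_evidence_null = le0,
                 bf_10 = exp(log_bf10), bf_01 = exp(-log_bf10),
                 p_bayes = stats::plogis(log_bf10),
                 p_null = stats::plogis(-log_bf10),
                 sigma_obs = sigma_obs, n_obs = n,
                 sigma_obs_degenerate = degenerate),
            class = "evidence_result")
}

#' @export
print.evidence_result <- function(x, ...) {
  cat(sprintf("Model evidence on %d ratings (sigma_obs = %.3f%s)\n", x$n_obs,
              x$sigma_obs, if (x$sigma_obs_degenerate) ", floored" else ""))
  cat(sprintf("  log evidence: bayes %.4f, null %.4f\n",
              x$log_evidence_bayes, x$log_evidence_null))
  cat(sprintf("  BF10 = %.4g, p(bayes | data) = %.4f\n", x$bf_10, x$p_bayes))
  invisible(x)
}

#' Positive evidence ratio across subjects
#'
#' Group-level heuristic counting only subjects with at least moderate
#' evidence for either model: those with \eqn{BF_{10}} strictly above the
#' threshold (favouring Bayesian integration) versus those with
#' \eqn{BF_{01}} strictly above it (favouring the Null model). The ratio of
#' the two counts is the positive evidence ratio; when no subject favours the
#' Null model the ratio is undefined and reported as `NA` with the counts
#' preserved (never as infinity).
#'
#' @param evidence Either a list of [compare_models()] results or a data
#'   frame with columns `bf_10` and `bf_01`.
#' @param threshold Strict evidence cut-off, must exceed 1. Default 3
#'   (moderate evidence).
#' @return List with `n_favoring_bayes`, `n_favoring_null`, `per`
#'   (`NA_real_` when undefined) and `threshold`.
#' @examples
#' ev <- data.frame(bf_10 = c(5, 9, 0.2, 1.5), bf_01 = c(0.2, 1/9, 5, 1/1.5))
#' positive_evidence_ratio(ev)
#' @export
positive_evidence_ratio <- function(evidence, threshold = 3) {
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  if (threshold <= 1)
    stop("'threshold' must exceed 1", call. = FALSE)
  if (is.data.frame(evidence)) {
    bf10 <- evidence$bf_10
    bf01 <- evidence$bf_01
  } else {
    bf10 <- vapply(evidence, `[[`, numeric(1L), "bf_10")
    bf01 <- vapply(evidence, `[[`, numeric(1L), "bf_01")
  }
  if (is.null(bf10) || is.null(bf01))
    stop("'evidence' must provide bf_10 and bf_01", call. = FALSE)
  n1 <- sum(bf10 > threshold)
  n0 <- sum(bf01 > threshold)
  list(n_favoring_bayes = n1, n_favoring_null = n0,
       per = if (n0 > 0) n1 / n0 else NA_real_, threshold = threshold)
}
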