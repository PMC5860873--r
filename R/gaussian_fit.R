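#' Gaussian distribution parameters
#'
#' Lightweight constructor for a fitted rating distribution, holding the mean
#' `mu` and standard deviation `sigma` (both in VAS units) plus a flag marking
#' degenerate fits where `sigma` was raised to the floor.
#'
#' @param mu Mean, VAS units.
#' @param sigma Standard deviation, VAS units; must be positive and finite.
#' @param degenerate Logical; `TRUE` when `sigma` was clamped at the floor
#'   because the ratings had (almost) no spread.
#' @return An object of class `"gaussian_params"`.
#' @export
gaussian_params <- function(mu, sigma, degenerate = FALSE) {
  stopifnot(is.numeric(mu), length(mu) == 1L, is.finite(mu),
            is.numeric(sigma), length(sigma) == 1L)
  if (!is.finite(sigma) || sigma <= 0)
    stop("'sigma' must be positive and finite", call. = FALSE)
  structure(list(mu = mu, sigma = sigma, degenerate = isTRUE(degenerate)),
            class = "gaussian_params")
}

#' @export
print.gaussian_params <- function(x, ...) {
  cat(sprintf("Gaussian(mu = %.4f, sigma = %.4f)%s\n", x$mu, x$sigma,
              if (x$degenerate) " [sigma at floor]" else ""))
  invisible(x)
}

#' Maximum-likelihood Gaussian fit to a set of ratings
#'
#' Fits a Gaussian to trial ratings by maximising the log-likelihood with a
#' derivative-free simplex search (Nelder-Mead) initialised at the closed-form
#' estimates: the sample mean and the ML standard deviation (the \eqn{n}
#' denominator, matching the likelihood being maximised). The numeric search
#' and the closed form agree to high precision; the search is retained because
#' it mirrors the general-purpose fitting route and degrades gracefully when a
#' floor constrains sigma.
#'
#' When the unconstrained optimum falls below `sigma_floor` (e.g. a subject
#' who rated every trial identically), `sigma` is clamped at the floor, `mu`
#' is the sample mean (the ML mean for any fixed sigma), and the result is
#' flagged degenerate.
#'
#' @param ratings Numeric vector of at least 2 finite VAS ratings.
#' @param sigma_floor Smallest admissible sigma, VAS units (default 0.5).
#' @return A [gaussian_params()] object.
#' @examples
#' fit_gaussian(c(20, 30, 40))        # mu 30, sigma sqrt(200/3)
#' fit_gaussian(rep(30, 4))           # sigma clamped at the floor
#' @export
fit_gaussian <- function(ratings, sigma_floor = 0.5) {
  if (!is.numeric(ratings) || length(ratings) < 2L)
    stop("need at least 2 ratings to fit a Gaussian", call. = FALSE)
  if (!all(is.finite(ratings)))
    stop("all ratings must be finite", call. = FALSE)
  stopifnot(is.numeric(sigma_floor), length(sigma_floor) == 1L, sigma_floor > 0)

  n <- length(ratings)
  mu0 <- mean(ratings)
  sigma0 <- sqrt(sum((ratings - mu0)^2) / n)  # n-denominator ML estimate

  if (sigma0 <= sigma_floor)
    return(gaussian_params(mu0, sigma_floor, degenerate = TRUE))

  negll <- function(par) {
    -sum(stats::dnorm(ratings, mean = par[1L], sd = exp(par[2L]), log = TRUE))
  }
  opt <- stats::optim(c(mu0, log(sigma0)), negll, method = "Nelder-Mead",
                      control = list(reltol = 1e-14, maxit = 5000L))
  mu <- opt$par[1L]
  sigma <- exp(opt$par[2L])
  if (sigma < sigma_floor)
    return(gaussian_params(mean(ratings), sigma_floor, degenerate = TRUE))
  gaussian_params(mu, sigma)
}

#' Fit a subject's prior and likelihood distributions
#'
#' Extracts one subject's ratings from a trial table and fits the two
#' Gaussians entering the integration stage. Under the Bayesian-integration
#' model the prior (treatment expectation) is fitted to the conditioning-phase
#' placebo ratings; under the Null model -- which assumes the conditioning
#' treatment experience left no trace -- it is fitted to the conditioning-phase
#' control ratings. The likelihood (incoming sensory evidence) is always
#' fitted to the test-phase control ratings, so the two models differ only in
#' the prior.
#'
#' @param trials Trial table (data frame) with columns `subject_id`, `phase`
#'   (`"conditioning"`/`"test"`), `condition` (`"placebo"`/`"control"`) and
#'   `vas`, as produced by [simulate_cohort()] or [read_trials()].
#' @param subject_id Subject to fit.
#' @param model `"bayes"` or `"null"`; selects the prior's source cell.
#' @param sigma_floor Passed to [fit_gaussian()].
#' @return List with elements `prior` and `likelihood`, both
#'   [gaussian_params()].
#' @export
fit_subject <- function(trials, subject_id, model = c("bayes", "null"),
                        sigma_floor = 0.5) {
  model <- match.arg(model)
  trials <- check_trials(trials)
  sub <- trials[trials$subject_id == subject_id, , drop = FALSE]
  if (nrow(sub) == 0L)
    stop("no trials found for subject '", subject_id, "'", call. = FALSE)

  cell <- function(phase, condition) {
    v <- sub$vas[sub$phase == phase & sub$condition == condition]
    if (length(v) < 2L)
      stop(sprintf("subject '%s' is missing ratings in the %s %s cell",
                   subject_id, phase, condition), call. = FALSE)
    v
  }
  prior_ratings <- if (model == "bayes") cell("conditioning", "placebo")
                   else cell("conditioning", "control")
  list(prior = fit_gaussian(prior_ratings, sigma_floor),
       likelihood = fit_gaussian(cell("test", "control"), sigma_floor))
}

# Validate a trial table's columns and value domains; returns the table with
# character-coerced factors so downstream subsetting is predictable.
check_trials <- function(trials) {
  if (!is.data.frame(trials))
    stop("'trials' must be a data frame", call. = FALSE)
  needed <- c("subject_id", "phase", "condition", "vas")
  missing_cols <- setdiff(needed, names(trials))
  if (length(missing_cols))
    stop("trial table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  trials$subject_id <- as.character(trials$subject_id)
  trials$phase <- as.character(trials$phase)
  trials$condition <- as.character(trials$condition)
  if (!all(trials$phase %in% c("conditioning", "test")))
    stop("'phase' must be 'conditioning' or 'test'", call. = FALSE)
  if (!all(trials$condition %in% c("placebo", "control")))
    stop("'condition' must be 'placebo' or 'control'", call. = FALSE)
  if (!is.numeric(trials$vas) || any(!is.finite(trials$vas)))
    stop("'vas' must be finite numeric", call. = FALSE)
  if (any(trials$vas < 0 | trials$vas > 100))
    stop("'vas' ratings must lie in [0, 100]", call. = FALSE)
  trials
}
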