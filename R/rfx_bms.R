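#' Random-effects Bayesian model selection
#'
#' Group-level model comparison treating the model identity as a random
#' effect: subjects are allowed to use different models, and a Dirichlet
#' distribution over model frequencies is estimated from the per-subject log
#' evidences by a variational scheme. Each iteration computes subject-wise
#' model responsibilities proportional to
#' \eqn{\exp\{\log p(X_n \mid M_k) + \psi(\alpha_k) - \psi(\sum_j \alpha_j)\}}
#' (\eqn{\psi} the digamma function), then updates
#' \eqn{\alpha_k = \alpha_k^{(0)} + \sum_n r_{nk}} until the concentration
#' parameters stabilise. Expected model probabilities are
#' \eqn{\alpha / \sum \alpha}; exceedance probabilities -- the posterior
#' probability that each model is the most frequent in the population -- come
#' from [exceedance_prob()].
#'
#' @param log_evidence Numeric matrix, subjects in rows, models in columns
#'   (at least 2), finite natural-log model evidences. Column names, if
#'   present, label the output.
#' @param prior_alpha Dirichlet prior concentration per model (default 1,
#'   uniform).
#' @param tol Convergence threshold on the maximum absolute change in alpha
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 10000); hitting it returns
#'   `converged = FALSE` rather than an error.
#' @param exceedance_draws Monte-Carlo draws for K > 2 models (two-model
#'   exceedance is exact; see [exceedance_prob()]).
#' @param seed Seed for the K > 2 Monte-Carlo sampler; recorded in the result.
#' @return An object of class `"rfx_result"`: list with `alpha`,
#'   `expected_prob`, `exceedance_prob`, `responsibilities` (subjects x
#'   models), `n_subjects`, `converged`, `iterations`, `prior_alpha`, `seed`.
#' @examples
#' le <- cbind(bayes = c(-10, -12, -9), null = c(-14, -11, -15))
#' rfx_model_selection(le)
#' @export
rfx_model_selection <- function(log_evidence, prior_alpha = 1, tol = 1e-8,
                                max_iter = 10000L, exceedance_draws = 1e6,
                                seed = 1L) {
  if (!is.matrix(log_evidence)) log_evidence <- as.matrix(log_evidence)
  if (!is.numeric(log_evidence) || !all(is.finite(log_evidence)))
    stop("'log_evidence' must be a finite numeric matrix", call. = FALSE)
  n <- nrow(log_evidence)
  k <- ncol(log_evidence)
  if (n < 1L || k < 2L)
    stop("need at least 1 subject and 2 models", call. = FALSE)
  stopifnot(is.numeric(prior_alpha), all(prior_alpha > 0))
  alpha0 <- rep_len(prior_alpha, k)

  alpha <- alpha0 + n / k   # start from a uniform soft assignment
  r <- NULL
  converged <- FALSE
  iter <- 0L
  while (iter < max_iter) {
    iter <- iter + 1L
    # responsibilities: row-wise softmax of log evidence + digamma terms
    u <- sweep(log_evidence, 2L, digamma(alpha) - digamma(sum(alpha)), `+`)
    u <- u - apply(u, 1L, max)
    r <- exp(u)
    r <- r / rowSums(r)
    alpha_new <- alpha0 + colSums(r)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      converged <- TRUE
      break
    }
    alpha <- alpha_new
  }
  names(alpha) <- colnames(log_evidence)
  structure(list(alpha = alpha,
                 expected_prob = alpha / sum(alpha),
                 exceedance_prob = exceedance_prob(alpha,
                                                   draws = exceedance_draws,
                                                   seed = seed),
                 responsibilities = r,
                 n_subjects = n, converged = converged, iterations = iter,
                 prior_alpha = alpha0, seed = seed),
            class = "rfx_result")
}

#' Exceedance probabilities of a Dirichlet posterior
#'
#' Probability, under a Dirichlet(\eqn{\alpha}) posterior over model
#' frequencies, that each model's frequency is the largest. For two models
#' this is exact via the Beta distribution: the first model's frequency is
#' Beta(\eqn{\alpha_1, \alpha_2}) and its exceedance is
#' \eqn{P(r_1 > 1/2)}. For three or more models a seeded Monte-Carlo
#' estimate is used (Dirichlet draws via normalised Gamma variates).
#'
#' @param alpha Positive numeric vector of Dirichlet concentrations
#'   (length >= 2).
#' @param draws Monte-Carlo sample size for K > 2 (default 1e6).
#' @param seed Seed for the Monte-Carlo sampler; the caller's RNG state is
#'   left untouched.
#' @return Numeric vector of exceedance probabilities, one per model,
#'   summing to 1 (up to Monte-Carlo error for K > 2).
#' @examples
#' exceedance_prob(c(8.2, 1.8))   # exact, via the Beta CDF
#' @export
exceedance_prob <- function(alpha, draws = 1e6, seed = 1L) {
  if (!is.numeric(alpha) || length(alpha) < 2L || any(!is.finite(alpha)) ||
      any(alpha <= 0))
    stop("'alpha' must be a vector of >= 2 positive concentrations",
         call. = FALSE)
  k <- length(alpha)
  if (k == 2L) {
    phi1 <- stats::pbeta(0.5, alpha[1L], alpha[2L], lower.tail = FALSE)
    out <- c(phi1, 1 - phi1)
  } else {
    out <- with_preserved_rng(seed, {
      g <- matrix(stats::rgamma(draws * k, shape = rep(alpha, each = draws)),
                  nrow = draws, ncol = k)
      tabulate(max.col(g, ties.method = "first"), nbins = k) / draws
    })
  }
  names(out) <- names(alpha)
  out
}

#' @export
print.rfx_result <- function(x, ...) {
  cat(sprintf("Random-effects Bayesian model selection (%d subjects, %d models)\n",
              x$n_subjects, length(x$alpha)))
  lab <- names(x$alpha)
  if (is.null(lab)) lab <- paste0("M", seq_along(x$alpha))
  tab <- data.frame(model = lab, alpha = round(x$alpha, 3),
                    expected_prob = round(x$expected_prob, 4),
                    exceedance_prob = round(x$exceedance_prob, 4),
                    row.names = NULL)
  print(tab)
  cat(sprintf("converged: %s after %d iterations\n", x$converged, x$iterations))
  invisible(x)
}

# Run expr with a private RNG stream; restores (or removes) .Random.seed.
with_preserved_rng <- function(seed, expr) {
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  expr
}
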