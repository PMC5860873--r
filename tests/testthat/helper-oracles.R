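# Independent numeric oracles used across the suite. These deliberately take
# brute-force routes (quadrature, grids, normal equations, sampling) so they
# share no code path with the package implementation they check.

# Marginal likelihood by adaptive quadrature over the unknown rating mean,
# computed on a shifted log scale to avoid underflow.
oracle_log_marginal <- function(data, model_mu, model_sigma, sigma_obs) {
  logf <- function(mu) {
    vapply(mu, function(m)
      sum(dnorm(data, m, sigma_obs, log = TRUE)) +
        dnorm(m, model_mu, model_sigma, log = TRUE), numeric(1L))
  }
  # centre the quadrature window on the conjugate posterior mode
  n <- length(data)
  prec <- n / sigma_obs^2 + 1 / model_sigma^2
  mode <- (sum(data) / sigma_obs^2 + model_mu / model_sigma^2) / prec
  half_width <- 15 / sqrt(prec)
  shift <- logf(mode)
  val <- integrate(function(mu) exp(logf(mu) - shift),
                   lower = mode - half_width, upper = mode + half_width,
                   rel.tol = 1e-11, abs.tol = 0)$value
  shift + log(val)
}

# Posterior mean/SD from the grid-normalised pointwise product of the two
# densities (trapezoid quadrature).
oracle_density_product <- function(prior, likelihood) {
  lo <- min(prior$mu - 10 * prior$sigma, likelihood$mu - 10 * likelihood$sigma)
  hi <- max(prior$mu + 10 * prior$sigma, likelihood$mu + 10 * likelihood$sigma)
  x <- seq(lo, hi, length.out = 200001L)
  f <- dnorm(x, prior$mu, prior$sigma) * dnorm(x, likelihood$mu, likelihood$sigma)
  w <- rep(1, length(x)); w[c(1L, length(x))] <- 0.5   # trapezoid weights
  z <- sum(w * f)
  mu <- sum(w * f * x) / z
  list(mu = mu, sigma = sqrt(sum(w * f * (x - mu)^2) / z))
}

# Closed-form Gaussian ML estimates (n denominator).
oracle_gaussian_ml <- function(x) {
  list(mu = mean(x), sigma = sqrt(sum((x - mean(x))^2) / length(x)))
}

# OLS coefficients straight from the normal equations.
oracle_ols <- function(y, X) {
  X1 <- cbind(1, X)
  drop(solve(crossprod(X1), crossprod(X1, y)))
}

# Small hand-built trial table: `cells` is a named list
# conditioning_placebo / conditioning_control / test_placebo / test_control.
make_subject_trials <- function(id = "S1", group = "HTP", cells) {
  phases <- c(conditioning_placebo = "conditioning",
              conditioning_control = "conditioning",
              test_placebo = "test", test_control = "test")
  conds <- c(conditioning_placebo = "placebo",
             conditioning_control = "control",
             test_placebo = "placebo", test_control = "control")
  do.call(rbind, lapply(names(cells), function(nm)
    data.frame(subject_id = id, group = group, phase = phases[[nm]],
               condition = conds[[nm]], trial = seq_along(cells[[nm]]),
               temperature_c = NA_real_, vas = cells[[nm]],
               stringsAsFactors = FALSE)))
}

# Canonical small simulated cohort shared by several files.
small_cohort <- function(seed = 11L, n = 6L) {
  simulate_cohort(cohort_config(n_htp = n, n_ltp = n, seed = seed))
}
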