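test_that("closed-form marginal likelihood matches adaptive quadrature", {
  set.seed(601)
  for (i in 1:100) {
    n <- sample(1:12, 1)
    x <- rnorm(n, runif(1, 0, 100), runif(1, 0.5, 25))
    mu_m <- runif(1, 0, 100)
    sigma_m <- exp(runif(1, log(0.05), log(60)))   # tiny through large
    sigma_o <- exp(runif(1, log(0.5), log(30)))
    got <- log_marginal_likelihood(x, mu_m, sigma_m, sigma_o)
    want <- oracle_log_marginal(x, mu_m, sigma_m, sigma_o)
    expect_equal(got, want, tolerance = 1e-6)
  }
})

test_that("a delta prior collapses the evidence to the plain likelihood", {
  x <- 42.5
  got <- log_marginal_likelihood(x, model_mu = 40, model_sigma = 1e-9,
                                 sigma_obs = 5)
  expect_equal(got, dnorm(x, 40, 5, log = TRUE), tolerance = 1e-9)
})

test_that("evidence is translation invariant and scales with the Jacobian", {
  set.seed(602)
  x <- rnorm(10, 45, 8)
  base <- log_marginal_likelihood(x, 40, 6, 7)
  expect_equal(log_marginal_likelihood(x + 7, 47, 6, 7), base, tolerance = 1e-10)
  # scaling everything by c changes the density by -n log c
  for (cc in c(0.5, 2, 10)) {
    scaled <- log_marginal_likelihood(cc * x, cc * 40, cc * 6, cc * 7)
    expect_equal(scaled, base - length(x) * log(cc), tolerance = 1e-9)
  }
})

test_that("model comparison is symmetric and converts BF to probabilities", {
  x <- c(40, 43, 45, 41, 44)
  post <- gaussian_params(42, 5)
  ev <- compare_models(x, post, post)
  expect_equal(ev$bf_10, 1, tolerance = 1e-12)
  expect_equal(ev$p_bayes, 0.5, tolerance = 1e-12)

  ev2 <- compare_models(x, gaussian_params(42, 5), gaussian_params(60, 5))
  expect_equal(ev2$bf_01, 1 / ev2$bf_10, tolerance = 1e-12)
  expect_equal(ev2$bf_10,
               exp(ev2$log_evidence_bayes - ev2$log_evidence_null),
               tolerance = 1e-12)
  expect_equal(ev2$p_bayes, ev2$bf_10 / (ev2$bf_10 + 1), tolerance = 1e-12)
  expect_equal(ev2$p_bayes + ev2$p_null, 1, tolerance = 1e-12)
  # a Bayes factor of 3 converts to p = 0.75 under equal model priors
  expect_equal(plogis(log(3)), 0.75)
})

test_that("sigma_obs follows the configured convention and floors degenerate data", {
  x <- c(40, 43, 45, 41, 44)
  ev1 <- compare_models(x, gaussian_params(42, 5), gaussian_params(60, 5),
                        sigma_obs_convention = "n_minus_1")
  expect_equal(ev1$sigma_obs, sd(x))
  ev2 <- compare_models(x, gaussian_params(42, 5), gaussian_params(60, 5),
                        sigma_obs_convention = "n")
  expect_equal(ev2$sigma_obs, sqrt(sum((x - mean(x))^2) / length(x)))

  flat <- compare_models(rep(42, 5), gaussian_params(42, 5),
                         gaussian_params(60, 5), sigma_floor = 0.5)
  expect_true(flat$sigma_obs_degenerate)
  expect_equal(flat$sigma_obs, 0.5)
})

test_that("well-separated priors give strong evidence for the generating model", {
  cohort <- simulate_cohort(cohort_config(n_htp = 20, n_ltp = 20, seed = 66))
  fit <- placebo_bayes(cohort$trials)
  expect_gt(median(fit$evidence$bf_10), 3)

  # swapping the generating model reverses the direction
  null_cohort <- simulate_cohort(cohort_config(n_htp = 20, n_ltp = 20,
                                               seed = 66,
                                               fraction_bayes_subjects = 0))
  null_fit <- placebo_bayes(null_cohort$trials)
  expect_lt(median(null_fit$evidence$bf_10), 1)
})

test_that("positive evidence ratio counts strict threshold exceedances", {
  ev <- data.frame(bf_10 = c(5, 9, 3, 0.2, 1.5),
                   bf_01 = 1 / c(5, 9, 3, 0.2, 1.5))
  res <- positive_evidence_ratio(ev)
  expect_equal(res$n_favoring_bayes, 2L)  # bf_10 = 3 is NOT counted
  expect_equal(res$n_favoring_null, 1L)
  expect_equal(res$per, 2)

  even <- positive_evidence_ratio(data.frame(bf_10 = c(rep(4, 5), rep(0.1, 5)),
                                             bf_01 = c(rep(0.25, 5), rep(10, 5))))
  expect_equal(even$per, 1)

  none <- positive_evidence_ratio(data.frame(bf_10 = c(4, 5, 6),
                                             bf_01 = c(0.25, 0.2, 1/6)))
  expect_equal(none$n_favoring_bayes, 3L)
  expect_equal(none$n_favoring_null, 0L)
  expect_true(is.na(none$per))            # undefined, never infinite

  expect_error(positive_evidence_ratio(ev, threshold = 1), "exceed 1")
})

test_that("evidence inputs are validated", {
  expect_error(log_marginal_likelihood(numeric(0), 0, 1, 1), "non-empty")
  expect_error(log_marginal_likelihood(1:3, 0, -1, 1), "model_sigma")
  expect_error(log_marginal_likelihood(1:3, 0, 1, 0), "sigma_obs")
  expect_error(compare_models(42, gaussian_params(1, 1), gaussian_params(1, 1)),
               "at least 2")
})
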