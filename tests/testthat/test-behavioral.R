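test_that("subject summaries compute the placebo effect as control minus placebo", {
  tr <- make_subject_trials(cells = list(
    conditioning_placebo = c(28, 31, 30),
    conditioning_control = c(69, 72, 70),
    test_placebo = rep(43, 3),
    test_control = rep(50, 3)))
  s <- summarize_subjects(tr)
  expect_equal(s$placebo_effect_observed, 7)
  expect_equal(s$mean_test_control, 50)
  expect_equal(s$sd_cond_placebo, sd(c(28, 31, 30)))  # n-1 convention

  same <- make_subject_trials(cells = list(
    conditioning_placebo = c(28, 31, 30),
    conditioning_control = c(69, 72, 70),
    test_placebo = c(48, 50, 52),
    test_control = c(48, 50, 52)))
  expect_equal(summarize_subjects(same)$placebo_effect_observed, 0)
})

test_that("sub-sample cut-offs keep the printed group summaries and are strict", {
  mk <- function(group, sd_cp) data.frame(group = group, sd_cond_placebo = sd_cp)
  s <- rbind(mk("HTP", 13.63),   # printed HTP mean variability: kept
             mk("HTP", 19.60),   # exactly at the cut-off: excluded
             mk("HTP", 19.59),
             mk("LTP", 22.46),   # printed LTP mean variability: kept
             mk("LTP", 13.96),   # exactly at the cut-off: excluded
             mk("LTP", 13.97))
  out <- apply_subsample_cutoffs(s)
  expect_identical(out$in_subsample, c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE))
  # flags only; no other column is touched
  expect_identical(out$sd_cond_placebo, s$sd_cond_placebo)
  expect_error(apply_subsample_cutoffs(mk("whatever", 10)), "group")
})

test_that("the simulated groups differ in the printed directions", {
  cohort <- simulate_cohort(cohort_config(seed = 19))
  fit <- placebo_bayes(cohort$trials)
  s <- fit$summaries
  htp <- s[s$group == "HTP", ]; ltp <- s[s$group == "LTP", ]
  expect_gt(mean(htp$placebo_effect_observed),
            mean(ltp$placebo_effect_observed))
  expect_gt(mean(ltp$sd_cond_placebo), mean(htp$sd_cond_placebo))
  expect_gt(mean(s$in_subsample), 0.5)   # most subjects pass their cut-off
})

test_that("pearson correlation matches its closed-form cases and the t test", {
  x <- c(1, 3, 4, 7, 9, 12)
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1, tolerance = 1e-12)

  set.seed(801)
  n <- 1000
  rho <- 1 / sqrt(2)             # y = x + noise with equal variances
  xs <- rnorm(n); ys <- xs + rnorm(n)
  res <- pearson_correlation(xs, ys)
  se <- (1 - rho^2) / sqrt(n)
  expect_lt(abs(res$r - rho), 3 * se)
  expect_lt(res$p_value, 1e-10)
  expect_error(pearson_correlation(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson_correlation(1:2, 1:2), "length")
})

test_that("regression recovers an exact linear construction", {
  set.seed(802)
  n <- 40
  models <- data.frame(subject_id = sprintf("S%02d", 1:n),
                       sigma_prior = runif(n, 5, 25),
                       sigma_like = runif(n, 5, 25))
  summaries <- data.frame(
    subject_id = models$subject_id,
    placebo_effect_observed = 15.005 - 0.883 * models$sigma_prior +
      0.562 * models$sigma_like)
  # suppressWarnings: summary.lm warns on a deliberately noise-free fit
  fit <- suppressWarnings(regress_placebo_on_sigmas(summaries, models))
  expect_equal(unname(fit$coefficients), c(15.005, -0.883, 0.562),
               tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-9)
})

test_that("regression equals the normal-equations oracle on noisy data", {
  set.seed(803)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    models <- data.frame(subject_id = sprintf("S%02d", 1:n),
                         sigma_prior = runif(n, 2, 30),
                         sigma_like = runif(n, 2, 30))
    y <- 5 + rnorm(n, 0, 4) - 0.5 * models$sigma_prior + 0.2 * models$sigma_like
    summaries <- data.frame(subject_id = models$subject_id,
                            placebo_effect_observed = y)
    fit <- regress_placebo_on_sigmas(summaries, models)
    want <- oracle_ols(y, as.matrix(models[, c("sigma_prior", "sigma_like")]))
    expect_equal(unname(fit$coefficients), unname(want), tolerance = 1e-9)
    expect_gte(fit$r_squared, 0); expect_lte(fit$r_squared, 1)
    expect_lte(fit$adj_r_squared, fit$r_squared)
  }
})

test_that("collinear predictors raise a rank-deficiency error", {
  models <- data.frame(subject_id = sprintf("S%02d", 1:10),
                       sigma_prior = 1:10, sigma_like = 2 * (1:10))
  summaries <- data.frame(subject_id = models$subject_id,
                          placebo_effect_observed = rnorm(10))
  expect_error(regress_placebo_on_sigmas(summaries, models), "collinear")
})

test_that("model-based correlations strengthen with more trials per condition", {
  r_at <- function(ntr, seed = 33) {
    cohort <- simulate_cohort(cohort_config(n_htp = 25, n_ltp = 25,
                                            seed = seed,
                                            trials_per_condition = ntr))
    fit <- placebo_bayes(cohort$trials)
    fit$correlations$predicted_vs_observed$r
  }
  r12 <- r_at(12); r48 <- r_at(48)
  expect_gt(r12, 0)
  expect_gt(r48, r12)
})
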