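test_that("offset schedule hits the target SD with zero mean and bounded range", {
  sched <- ltp_offset_schedule(12, 0.55, 0.8)
  expect_length(sched, 12L)
  expect_identical(mean(sched), 0)            # exact, by +/- pairing
  expect_equal(sd(sched), 0.55, tolerance = 1e-6)
  expect_lte(max(abs(sched)), 0.8 + 1e-12)
  expect_equal(sort(sched), sort(-sched))     # symmetric
})

test_that("offset schedule handles degenerate and anchored regimes", {
  expect_identical(ltp_offset_schedule(12, 0, 0.8), numeric(12))
  # target SD at the cap forces the top magnitude onto the cap
  hard <- ltp_offset_schedule(12, 0.8, 0.8)
  expect_equal(sd(hard), 0.8, tolerance = 1e-6)
  expect_equal(max(abs(hard)), 0.8, tolerance = 1e-9)
  # two-trial case
  expect_equal(sd(ltp_offset_schedule(2, 0.3, 0.8)), 0.3, tolerance = 1e-9)
  # a grid of feasible targets all solve to the requested SD
  for (s in seq(0.1, 0.78, by = 0.08))
    expect_equal(sd(ltp_offset_schedule(12, s, 0.8)), s, tolerance = 1e-6)
})

test_that("offset schedule rejects infeasible or odd designs", {
  expect_error(ltp_offset_schedule(12, 0.9, 0.8), "infeasible")
  expect_error(ltp_offset_schedule(11, 0.55, 0.8), "even")
})

test_that("equal seeds give bit-identical cohorts and valid ratings", {
  a <- simulate_cohort(cohort_config(n_htp = 5, n_ltp = 5, seed = 7))
  b <- simulate_cohort(cohort_config(n_htp = 5, n_ltp = 5, seed = 7))
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth, b$ground_truth)
  c <- simulate_cohort(cohort_config(n_htp = 5, n_ltp = 5, seed = 8))
  expect_false(identical(a$trials$vas, c$trials$vas))

  expect_true(all(a$trials$vas >= 0 & a$trials$vas <= 100))
  # 4 cells x 12 trials per subject, trial index unique within cells
  counts <- table(a$trials$subject_id, a$trials$phase, a$trials$condition)
  expect_true(all(counts == 12L))
})

test_that("clip truncation policy also keeps ratings in range", {
  cfg <- cohort_config(n_htp = 4, n_ltp = 4, seed = 3,
                       truncation_policy = "clip")
  tr <- simulate_cohort(cfg)$trials
  expect_true(all(tr$vas >= 0 & tr$vas <= 100))
})

test_that("conditioning anchors and the precision manipulation are honoured", {
  cohort <- simulate_cohort(cohort_config(n_htp = 200, n_ltp = 200, seed = 21))
  tr <- cohort$trials
  cp <- tr[tr$phase == "conditioning" & tr$condition == "placebo", ]
  # law of large numbers: conditioning-placebo ratings centred at VAS 30
  expect_lt(abs(mean(cp$vas) - 30), 1)

  # HTP conditioning-placebo temperature constant; LTP jittered with the
  # schedule's spread
  by_subj_temp <- tapply(cp$temperature_c, cp$subject_id, sd)
  grp <- tapply(cp$group, cp$subject_id, `[`, 1L)
  expect_true(all(by_subj_temp[grp == "HTP"] == 0))
  expect_true(all(abs(by_subj_temp[grp == "LTP"] - 0.55) < 1e-9))

  # within-subject rating SD strictly larger in LTP on average
  by_subj_sd <- tapply(cp$vas, cp$subject_id, sd)
  expect_gt(mean(by_subj_sd[grp == "LTP"]), mean(by_subj_sd[grp == "HTP"]))
})

test_that("group variability gap grows with the temperature jitter and vanishes at zero", {
  gap <- function(temp_sd, seed = 31) {
    cfg <- cohort_config(n_htp = 120, n_ltp = 120, seed = seed,
                         ltp_temp_sd = temp_sd)
    tr <- simulate_cohort(cfg)$trials
    cp <- tr[tr$phase == "conditioning" & tr$condition == "placebo", ]
    by_subj <- tapply(cp$vas, cp$subject_id, sd)
    grp <- tapply(cp$group, cp$subject_id, `[`, 1L)
    mean(by_subj[grp == "LTP"]) - mean(by_subj[grp == "HTP"])
  }
  g0 <- gap(0); g3 <- gap(0.3); g55 <- gap(0.55)
  expect_lt(abs(g0), 1.5)   # exchangeable groups up to sampling noise
  expect_gt(g3, g0)
  expect_gt(g55, g3)
})

test_that("ground-truth posteriors are the integration of prior and likelihood", {
  gt <- simulate_cohort(cohort_config(n_htp = 10, n_ltp = 10, seed = 5,
                                      fraction_bayes_subjects = 0.5))$ground_truth
  expect_setequal(unique(gt$generating_model), c("bayes", "null"))
  expect_equal(sum(gt$generating_model == "bayes"), 10L)
  for (i in seq_len(nrow(gt))) {
    post <- integrate_gaussians(
      gaussian_params(gt$prior_mu[i], gt$prior_sigma[i]),
      gaussian_params(gt$like_mu[i], gt$like_sigma[i]))
    expect_equal(post$mu, gt$post_mu[i], tolerance = 1e-12)
    expect_equal(post$sigma, gt$post_sigma[i], tolerance = 1e-12)
  }
})

test_that("cohort configuration is validated", {
  expect_error(cohort_config(n_htp = 0), "n_htp")
  expect_error(cohort_config(vas_test_mean = 130), "VAS")
  expect_error(cohort_config(ltp_temp_sd = 0.9, ltp_temp_max_offset = 0.8),
               "ltp_temp_sd")
  expect_error(cohort_config(fraction_bayes_subjects = 1.2), "fraction")
  expect_error(cohort_config(rating_noise_sd_range = c(5, 2)), "range")
  expect_equal(cohort_config_heterogeneous()$fraction_bayes_subjects, 0.9)
})
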