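#' Configuration of a simulated conditioning/test cohort
#'
#' Collects the design parameters of the two-group placebo-conditioning
#' experiment the simulator emulates. Two groups undergo conditioning with a
#' placebo ("treated") condition calibrated to VAS 30 and a control condition
#' at VAS 70; in the test phase both conditions are delivered at the VAS-50
#' temperature. The high-treatment-precision (HTP) group receives the
#' conditioning placebo at a constant temperature; the
#' low-treatment-precision (LTP) group receives it with a balanced schedule
#' of temperature offsets (SD `ltp_temp_sd`, capped at
#' `ltp_temp_max_offset`), inflating the variability of their treatment
#' expectation.
#'
#' @param n_htp,n_ltp Subjects per group (default 31 each).
#' @param trials_per_condition Trials per phase-condition cell (default 12).
#' @param vas_cond_placebo_mean,vas_cond_control_mean,vas_test_mean Target
#'   VAS levels of the conditioning placebo, conditioning control and test
#'   stimuli (defaults 30, 70, 50).
#' @param ltp_temp_sd Sample SD of the LTP conditioning-placebo temperature
#'   offsets, degrees C (default 0.55).
#' @param ltp_temp_max_offset Largest admissible absolute offset, degrees C
#'   (default 0.8).
#' @param rating_noise_sd_range Per-subject trial-to-trial rating noise SD
#'   is drawn uniformly from this interval, VAS units (default c(9, 18)).
#' @param psychometric_slope_range Per-subject psychometric slope at the
#'   midpoint, VAS per degree C, drawn uniformly (default c(28, 42)).
#' @param psychometric_midpoint_range Per-subject VAS-50 temperature,
#'   degrees C, drawn uniformly (default c(44, 46)).
#' @param fraction_bayes_subjects Proportion of subjects whose test-placebo
#'   ratings are generated from the Bayesian-integration posterior rather
#'   than the Null posterior (default 1; `cohort_config_heterogeneous()`
#'   presets 0.9).
#' @param seed Integer seed; equal seeds give bit-identical cohorts.
#' @param truncation_policy How ratings outside \eqn{[0, 100]} are handled:
#'   `"resample"` (default) draws from the truncated normal, preserving the
#'   approximate Gaussian shape the fitting stage assumes; `"clip"` clamps.
#' @return An object of class `"cohort_config"` (a validated list).
#' @export
cohort_config <- function(n_htp = 31L, n_ltp = 31L, trials_per_condition = 12L,
                          vas_cond_placebo_mean = 30,
                          vas_cond_control_mean = 70,
                          vas_test_mean = 50,
                          ltp_temp_sd = 0.55, ltp_temp_max_offset = 0.8,
                          rating_noise_sd_range = c(9, 18),
                          psychometric_slope_range = c(28, 42),
                          psychometric_midpoint_range = c(44, 46),
                          fraction_bayes_subjects = 1,
                          seed = 1L,
                          truncation_policy = c("resample", "clip")) {
  truncation_policy <- match.arg(truncation_policy)
  cfg <- list(n_htp = as.integer(n_htp), n_ltp = as.integer(n_ltp),
              trials_per_condition = as.integer(trials_per_condition),
              vas_cond_placebo_mean = vas_cond_placebo_mean,
              vas_cond_control_mean = vas_cond_control_mean,
              vas_test_mean = vas_test_mean,
              ltp_temp_sd = ltp_temp_sd,
              ltp_temp_max_offset = ltp_temp_max_offset,
              rating_noise_sd_range = as.numeric(rating_noise_sd_range),
              psychometric_slope_range = as.numeric(psychometric_slope_range),
              psychometric_midpoint_range = as.numeric(psychometric_midpoint_range),
              fraction_bayes_subjects = fraction_bayes_subjects,
              seed = as.integer(seed),
              truncation_policy = truncation_policy)
  validate_cohort_config(cfg)
  structure(cfg, class = "cohort_config")
}

#' @rdname cohort_config
#' @export
cohort_config_heterogeneous <- function(...) {
  cohort_config(fraction_bayes_subjects = 0.9, ...)
}

validate_cohort_config <- function(cfg) {
  stopifnot(cfg$n_htp >= 1L, cfg$n_ltp >= 1L, cfg$trials_per_condition >= 1L)
  vas_means <- c(cfg$vas_cond_placebo_mean, cfg$vas_cond_control_mean,
                 cfg$vas_test_mean)
  if (any(vas_means < 0 | vas_means > 100))
    stop("VAS target means must lie in [0, 100]", call. = FALSE)
  if (cfg$ltp_temp_sd < 0 || cfg$ltp_temp_max_offset <= 0)
    stop("temperature spread parameters must be non-negative", call. = FALSE)
  if (cfg$ltp_temp_sd > cfg$ltp_temp_max_offset)
    stop("'ltp_temp_sd' may not exceed 'ltp_temp_max_offset'", call. = FALSE)
  rngs <- list(rating_noise_sd_range = cfg$rating_noise_sd_range,
               psychometric_slope_range = cfg$psychometric_slope_range,
               psychometric_midpoint_range = cfg$psychometric_midpoint_range)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2L || any(!is.finite(r)) || r[1L] > r[2L])
      stop("'", nm, "' must be a finite increasing interval", call. = FALSE)
  }
  if (any(cfg$rating_noise_sd_range <= 0) ||
      any(cfg$psychometric_slope_range <= 0))
    stop("noise SDs and slopes must be positive", call. = FALSE)
  if (cfg$fraction_bayes_subjects < 0 || cfg$fraction_bayes_subjects > 1)
    stop("'fraction_bayes_subjects' must lie in [0, 1]", call. = FALSE)
  invisible(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("Cohort configuration\n")
  cat(sprintf("  groups: HTP n = %d, LTP n = %d; %d trials per condition\n",
              x$n_htp, x$n_ltp, x$trials_per_condition))
  cat(sprintf("  VAS anchors: conditioning placebo %g / control %g, test %g\n",
              x$vas_cond_placebo_mean, x$vas_cond_control_mean, x$vas_test_mean))
  cat(sprintf("  LTP temperature jitter: SD %g C, max |offset| %g C\n",
              x$ltp_temp_sd, x$ltp_temp_max_offset))
  cat(sprintf("  fraction of Bayes-generated subjects: %g; seed %d; truncation: %s\n",
              x$fraction_bayes_subjects, x$seed, x$truncation_policy))
  invisible(x)
}

#' Balanced temperature-offset schedule for the LTP group
#'
#' Constructs the deterministic schedule of conditioning-placebo temperature
#' offsets that induces low treatment precision: `n_trials` offsets in
#' plus/minus pairs (so the mean is exactly 0), with sample SD (n-1
#' denominator) equal to `target_sd` and every magnitude at most
#' `max_offset`. Magnitudes are linear in rank and scaled to meet the SD;
#' when the scaled top magnitude would exceed `max_offset`, the top is
#' anchored there and the lower anchor is solved for instead. A deterministic
#' schedule is used rather than i.i.d. draws because the design prescribes an
#' exact SD and range over only 12 trials, which a small random sample would
#' miss; trial order is shuffled separately by the cohort seed.
#'
#' @param n_trials Even number of trials (default 12).
#' @param target_sd Desired sample SD of the offsets, degrees C.
#' @param max_offset Largest admissible absolute offset, degrees C; must be
#'   at least `target_sd`.
#' @return Numeric vector of `n_trials` offsets, ordered smallest to largest.
#' @examples
#' sched <- ltp_offset_schedule(12, 0.55, 0.8)
#' mean(sched); sd(sched); max(abs(sched))
#' @export
ltp_offset_schedule <- function(n_trials = 12L, target_sd = 0.55,
                                max_offset = 0.8) {
  stopifnot(is.numeric(n_trials), length(n_trials) == 1L, n_trials >= 2L)
  if (n_trials %% 2L != 0L)
    stop("'n_trials' must be even so offsets pair to a zero mean", call. = FALSE)
  stopifnot(is.numeric(target_sd), target_sd >= 0,
            is.numeric(max_offset), max_offset > 0)
  if (target_sd > max_offset)
    stop("infeasible schedule: 'target_sd' exceeds 'max_offset'", call. = FALSE)

  n <- as.integer(n_trials)
  if (target_sd == 0) return(numeric(n))
  p <- n %/% 2L
  target_ssq <- (n - 1L) * target_sd^2 / 2  # sum of squared magnitudes

  if (p == 1L) {
    m <- sqrt(target_ssq)
  } else {
    b <- (seq_len(p) - 1) / (p - 1)         # 0 .. 1, linear in rank
    s <- sqrt(target_ssq / sum(b^2))
    if (s <= max_offset) {
      m <- s * b
    } else {
      # anchor the top at max_offset; solve the lower anchor w in [0, 1]
      # for sum (max_offset * (w + (1 - w) b))^2 = target_ssq
      f <- function(w) sum((max_offset * (w + (1 - w) * b))^2) - target_ssq
      w <- stats::uniroot(f, c(0, 1), tol = 1e-14)$root
      m <- max_offset * (w + (1 - w) * b)
    }
  }
  sort(c(-m, m))
}

#' Simulate a two-group conditioning/test cohort
#'
#' Generates trial-level ratings with the experiment's statistical structure.
#' Each subject gets a logistic psychometric function (midpoint and slope
#' drawn from the configured ranges) used to back-compute the stimulus
#' temperatures for the VAS 30/70/50 anchors; conditioning and test-control
#' ratings are the psychometric expectation at the delivered temperature plus
#' Gaussian rating noise. Test-placebo ratings are drawn from the subject's
#' generating-model posterior: the precision-weighted combination of the true
#' treatment-expectation prior and the true sensory likelihood for
#' Bayes-generated subjects, or of the conditioning-control prior for
#' Null-generated subjects. Ratings are kept in \eqn{[0, 100]} by the
#' configured truncation policy.
#'
#' @param config A [cohort_config()].
#' @return List of class `"cohort"` with elements
#' \describe{
#'   \item{trials}{data frame: `subject_id`, `group`, `phase`, `condition`,
#'     `trial`, `temperature_c`, `vas`.}
#'   \item{ground_truth}{data frame, one row per subject: psychometric
#'     parameters, rating noise SD, generating model, and the true prior /
#'     likelihood / posterior mean and SD (for parameter-recovery studies).}
#'   \item{config}{the configuration used.}
#' }
#' @examples
#' cohort <- simulate_cohort(cohort_config(n_htp = 4, n_ltp = 4, seed = 7))
#' head(cohort$trials)
#' @export
simulate_cohort <- function(config = cohort_config()) {
  if (!inherits(config, "cohort_config"))
    stop("'config' must be a cohort_config object", call. = FALSE)
  validate_cohort_config(config)
  with_preserved_rng(config$seed, simulate_cohort_impl(config))
}

simulate_cohort_impl <- function(cfg) {
  n_tot <- cfg$n_htp + cfg$n_ltp
  groups <- rep(c("HTP", "LTP"), c(cfg$n_htp, cfg$n_ltp))
  ids <- sprintf("S%03d", seq_len(n_tot))
  ntr <- cfg$trials_per_condition

  # exact count of Bayes-generated subjects, positions drawn by the seed
  n_bayes <- round(cfg$fraction_bayes_subjects * n_tot)
  bayes_idx <- if (n_bayes >= n_tot) seq_len(n_tot)
               else sort(sample.int(n_tot, n_bayes))
  gen_model <- ifelse(seq_len(n_tot) %in% bayes_idx, "bayes", "null")

  sched <- if (cfg$ltp_temp_sd == 0) numeric(ntr)
           else ltp_offset_schedule(ntr, cfg$ltp_temp_sd, cfg$ltp_temp_max_offset)

  trials <- vector("list", n_tot)
  truth <- vector("list", n_tot)
  for (i in seq_len(n_tot)) {
    t50 <- stats::runif(1L, cfg$psychometric_midpoint_range[1L],
                        cfg$psychometric_midpoint_range[2L])
    slope <- stats::runif(1L, cfg$psychometric_slope_range[1L],
                          cfg$psychometric_slope_range[2L])
    noise <- stats::runif(1L, cfg$rating_noise_sd_range[1L],
                          cfg$rating_noise_sd_range[2L])
    psy <- make_psychometric(t50, slope)
    t30 <- psy$inverse(cfg$vas_cond_placebo_mean)
    t70 <- psy$inverse(cfg$vas_cond_control_mean)
    t50c <- psy$inverse(cfg$vas_test_mean)

    # LTP: anchor the jittered schedule so the *mean expected rating* sits at
    # the placebo target (a symmetric schedule around the VAS-30 temperature
    # would drift upward through the sigmoid's curvature)
    cond_plac_temps <- if (groups[i] == "HTP") rep(t30, ntr)
    else {
      base <- stats::uniroot(function(b)
        mean(psy$forward(b + sched)) - cfg$vas_cond_placebo_mean,
        interval = t30 + c(-1, 1) * (cfg$ltp_temp_max_offset + 2),
        tol = 1e-12)$root
      base + sample(sched)
    }
    exp_plac <- psy$forward(cond_plac_temps)

    # true treatment-expectation prior: mixture over the delivered
    # temperatures -> mean of expectations, noise plus between-trial spread
    prior_mu <- mean(exp_plac)
    prior_sigma <- sqrt(noise^2 + sum((exp_plac - prior_mu)^2) / ntr)
    like_mu <- cfg$vas_test_mean
    like_sigma <- noise
    null_prior_mu <- cfg$vas_cond_control_mean
    null_prior_sigma <- noise

    post_bayes <- integrate_gaussians(gaussian_params(prior_mu, prior_sigma),
                                      gaussian_params(like_mu, like_sigma))
    post_null <- integrate_gaussians(gaussian_params(null_prior_mu,
                                                     null_prior_sigma),
                                     gaussian_params(like_mu, like_sigma))
    post <- if (gen_model[i] == "bayes") post_bayes else post_null

    draw <- function(mu, sd, n) bounded_normal(n, mu, sd, cfg$truncation_policy)
    cells <- list(
      list(phase = "conditioning", condition = "placebo",
           temp = cond_plac_temps, vas = draw(exp_plac, noise, ntr)),
      list(phase = "conditioning", condition = "control",
           temp = rep(t70, ntr), vas = draw(psy$forward(t70), noise, ntr)),
      list(phase = "test", condition = "placebo",
           temp = rep(t50c, ntr), vas = draw(post$mu, post$sigma, ntr)),
      list(phase = "test", condition = "control",
           temp = rep(t50c, ntr), vas = draw(psy$forward(t50c), noise, ntr)))
    trials[[i]] <- do.call(rbind, lapply(cells, function(cl)
      data.frame(subject_id = ids[i], group = groups[i], phase = cl$phase,
                 condition = cl$condition, trial = seq_len(ntr),
                 temperature_c = cl$temp, vas = cl$vas,
                 stringsAsFactors = FALSE)))

    gen_prior_mu <- if (gen_model[i] == "bayes") prior_mu else null_prior_mu
    gen_prior_sigma <- if (gen_model[i] == "bayes") prior_sigma else null_prior_sigma
    truth[[i]] <- data.frame(
      subject_id = ids[i], group = groups[i], generating_model = gen_model[i],
      t50 = t50, slope = slope, rating_noise_sd = noise,
      prior_mu = gen_prior_mu, prior_sigma = gen_prior_sigma,
      like_mu = like_mu, like_sigma = like_sigma,
      post_mu = post$mu, post_sigma = post$sigma,
      stringsAsFactors = FALSE)
  }
  structure(list(trials = do.call(rbind, trials),
                 ground_truth = do.call(rbind, truth),
                 config = cfg),
            class = "cohort")
}

# Gaussian draws kept inside [0, 100]: either truncated-normal sampling via
# the inverse CDF (with the location shifted so the truncated mean equals the
# intended expectation -- plain truncation would drag cell means away from
# their VAS anchors at large noise SDs), or plain clamping.
bounded_normal <- function(n, mu, sd, policy) {
  if (policy == "resample") {
    loc <- vapply(rep_len(mu, n), truncnorm_location, numeric(1L), sd = sd)
    lo <- stats::pnorm(0, loc, sd)
    hi <- stats::pnorm(100, loc, sd)
    stats::qnorm(lo + stats::runif(n) * (hi - lo), loc, sd)
  } else {
    pmin(pmax(stats::rnorm(n, mu, sd), 0), 100)
  }
}

# Location parameter whose [0, 100]-truncated normal has mean `target`.
truncnorm_location <- function(target, sd) {
  tmean <- function(loc) {
    a <- (0 - loc) / sd
    b <- (100 - loc) / sd
    z <- stats::pnorm(b) - stats::pnorm(a)
    loc + sd * (stats::dnorm(a) - stats::dnorm(b)) / z
  }
  if (abs(tmean(target) - target) < 1e-10) return(target)
  stats::uniroot(function(l) tmean(l) - target,
                 interval = c(target - 5 * sd, target + 5 * sd),
                 tol = 1e-12)$root
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d subjects (%d HTP, %d LTP), %d trials each\n",
              nrow(x$ground_truth), x$config$n_htp, x$config$n_ltp,
              4L * x$config$trials_per_condition))
  cat(sprintf("  seed %d; %d Bayes-generated, %d Null-generated subjects\n",
              x$config$seed, sum(x$ground_truth$generating_model == "bayes"),
              sum(x$ground_truth$generating_model == "null")))
  invisible(x)
}
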