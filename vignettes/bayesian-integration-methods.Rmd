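---
title: "Methods: Bayesian integration modelling of placebo hypoalgesia"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: Bayesian integration modelling of placebo hypoalgesia}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bayesplacebo)
```

## The model

Placebo hypoalgesia is treated as Bayesian cue integration. During
conditioning, a subject acquires a *treatment expectation*: repeated placebo
("treated") stimulations calibrated to VAS 30 build a belief about how painful
treated stimuli are. At test, both treated and untreated stimuli are delivered
at the identical VAS-50 temperature; the perceived pain of the treated
stimulus is modelled as the posterior combination of

* the **prior** — a Gaussian \(N(\mu_{prior}, \sigma_{prior}^2)\) fitted by
  maximum likelihood to the conditioning-phase placebo ratings, and
* the **likelihood** — a Gaussian \(N(\mu_{like}, \sigma_{like}^2)\) fitted to
  the test-phase control ratings, i.e. the incoming nociceptive evidence.

Conjugacy gives the posterior in closed form. With attraction weights

\[
w_{prior} = \frac{1/\sigma_{prior}^2}{1/\sigma_{prior}^2 + 1/\sigma_{like}^2},
\qquad w_{like} = 1 - w_{prior},
\]

the predicted treated percept is

\[
\mu_{post} = w_{prior}\,\mu_{prior} + w_{like}\,\mu_{like}, \qquad
\frac{1}{\sigma_{post}^2} = \frac{1}{\sigma_{prior}^2} +
\frac{1}{\sigma_{like}^2},
\]

and the predicted placebo effect is \(\mu_{like} - \mu_{post}\): the more
precise the treatment expectation relative to the sensory evidence, the
further the percept is pulled toward it. The **Null model** is identical
except that its prior is fitted to the conditioning-phase *control* ratings —
the belief a subject would hold if the treatment experience left no trace.
Because both models share the likelihood, any evidence difference between
them is attributable to the prior alone.

### Model evidence

Each model is scored on the subject's test-phase placebo ratings
\(X = \{x_i\}_{i=1}^n\) by the conjugate Gaussian marginal likelihood,
integrating over the unknown rating mean:

\[
p(X \mid \mu_M, \sigma_{obs}^2, \sigma_M^2) =
\int \Big[\prod_i N(x_i \mid \mu_{obs}, \sigma_{obs}^2)\Big]
N(\mu_{obs} \mid \mu_M, \sigma_M^2)\, d\mu_{obs},
\]

with \((\mu_M, \sigma_M)\) the model's predicted posterior. The package
evaluates this in the algebraically equivalent, numerically stable form

\[
\log p = -\tfrac{n-1}{2}\log(2\pi\sigma_{obs}^2) - \tfrac12\log n
 - \frac{\sum_i (x_i-\bar x)^2}{2\sigma_{obs}^2}
 + \log N\!\big(\bar x \mid \mu_M, \sigma_M^2 + \sigma_{obs}^2/n\big),
\]

which avoids the cancellation of \(\pm\mu_M^2/\sigma_M^2\) terms in the
expanded expression when \(\sigma_M\) is small (a floored, near-degenerate
fit). The test suite asserts equivalence with adaptive quadrature to a
relative \(10^{-6}\) across random instances including tiny and large
\(\sigma_M\).

The Bayes factor \(BF_{10}\) is the evidence ratio of the integration model
over the Null model; with equal model priors,
\(p(M_{Bay}\mid X) = BF_{10}/(BF_{10}+1)\). Across subjects the package
reports the positive evidence ratio (count of subjects with \(BF_{10} > 3\)
over count with \(BF_{01} > 3\), strict inequalities) and random-effects
Bayesian model selection: a variational Dirichlet scheme in which subject
responsibilities are proportional to
\(\exp\{\log p(X_n|M_k) + \psi(\alpha_k) - \psi(\textstyle\sum_j\alpha_j)\}\)
and \(\alpha_k = \alpha_k^{(0)} + \sum_n r_{nk}\), iterated to convergence.
Two-model exceedance probabilities are computed exactly from the Beta CDF at
1/2 rather than by sampling, keeping the headline quantity free of
Monte-Carlo noise; the seeded sampler is retained for three or more models
and doubles as the test oracle.

## Tunable parameters

| Parameter | Default | Units | Why |
|---|---|---|---|
| `sigma_floor` | 0.5 | VAS | Smallest admissible fitted SD. A subject rating every trial identically yields a zero ML variance; the floor keeps precisions finite. Flagged in output. |
| `sigma_obs_convention` | `n_minus_1` | — | The observation-noise SD in the evidence stage is the sample SD of the test-placebo ratings, shared by both models so the comparison isolates the prior. The `n` (ML) convention is available. |
| `evidence_model_input` | `posterior` | — | Which model distribution enters the marginal likelihood as \((\mu_M,\sigma_M)\). The posterior is the model's prediction of the treated percept; the prior is offered as the alternative reading. |
| `per_threshold` | 3 | BF | "Larger than three" = at least moderate evidence; strict inequality. |
| `rfx_prior_alpha` | 1 | — | Uniform Dirichlet prior over model frequencies. Convergence at max \(|\Delta\alpha| < 10^{-8}\), cap 10 000 iterations. |

Estimation conventions: Gaussian fitting maximises the likelihood, so the
internal SD uses the \(n\) denominator and the numeric optimiser (a simplex
search initialised at the closed form) agrees with the closed-form ML
estimates to \(10^{-6}\). Descriptive statistics — individual treatment
variability, group summaries — use the \(n-1\) sample SD, the standard
reporting convention. The two are never mixed within one statistic.

## What the synthetic cohort emulates

`simulate_cohort()` generates the two-group conditioning/test design so every
stage is testable without real data:

* Two groups of 31 subjects, 12 trials per phase-condition cell.
* A per-subject logistic psychometric function maps temperature to expected
  VAS. The curve family is logistic because the design requires inverting a
  sigmoid to find the VAS-30/50/70 temperatures. Midpoints are drawn from
  44–46 °C and slopes from 28–42 VAS/°C, so the VAS-30-to-70 calibration span
  averages about 1.2 °C — consistent with group-mean calibrated temperatures
  about 1.1 °C apart.
* High-treatment-precision (HTP) subjects receive the conditioning placebo at
  a constant temperature; low-treatment-precision (LTP) subjects receive a
  deterministic balanced schedule of offsets (± pairs, sample SD exactly
  0.55 °C, no magnitude above 0.8 °C, order shuffled by the cohort seed). A
  deterministic schedule is used because the design fixes an exact SD and
  range over only 12 trials, which i.i.d. draws would miss.
* Trial ratings are the psychometric expectation plus Gaussian noise with a
  per-subject SD drawn from 9–18 VAS. These ranges put the mean HTP
  within-subject conditioning-placebo SD near 13 VAS and the LTP mean near
  20–22 VAS, matching the reported group variability ordering and approximate
  magnitudes.
* Test-placebo ratings are drawn from the subject's generating-model
  posterior (Bayesian integration by default;
  `fraction_bayes_subjects` < 1 mixes in Null-generated subjects,
  with a 0.9 preset for cohort heterogeneity).

Two numerical subtleties are handled explicitly. First, a jitter schedule
symmetric in °C around the VAS-30 temperature does *not* produce ratings
centred at VAS 30: the logistic is convex below its midpoint, so the mean
expected rating drifts upward by 1–3 VAS at realistic slopes. The schedule's
anchor temperature is therefore solved (by root finding) so the mean expected
rating equals the placebo target, while the offsets themselves stay mean-zero
in temperature. Second, ratings are bounded to [0, 100]; plain truncated-normal
sampling would shift cell means away from their anchors by up to ~2 VAS at the
largest noise SDs, so the default `resample` policy shifts the truncated
normal's location so that its *mean* equals the intended expectation (a
`clip` policy is available and makes no such correction).

What passing tests on this generator do **not** show about real data: real
rating distributions are bounded, often skewed and sometimes multimodal;
real psychometric functions drift over a session; real subjects mix
strategies within the experiment. The simulator shows that the pipeline
recovers its own generative structure (parameter recovery, evidence
direction, group contrasts), not that the Gaussian assumptions hold
empirically.

## Behavioural statistics

The observed placebo effect is the mean test-phase control rating minus the
mean test-phase placebo rating. Sub-sample selection flags subjects in whom
the precision manipulation demonstrably worked, using variance cut-offs from
an independent behavioural sample: HTP kept when the conditioning-placebo
rating variance is strictly below 384.08 (SD 19.60), LTP kept when strictly
above 194.90 (SD 13.96). Flags never alter ratings. Pearson correlations use
the standard t-based two-sided test; the regression of the observed effect on
\(\sigma_{prior}\) and \(\sigma_{like}\) is ordinary least squares with an
intercept, reporting unstandardised coefficients (the scale of a prediction
equation) alongside standardised ones, since the two conventions are easy to
conflate. No multiple-testing correction is applied to the behavioural
correlations. The condition-by-group mixed-effects tests are deliberately not
re-implemented: the pipeline exports a tidy long-format table
(`long_format.csv`) so any standard mixed-model tool can fit them.

## Design choices where the design was open

* **Prior and likelihood are fitted independently per cell** — no joint
  objective links them.
* **\(\sigma_{obs}\) is shared between models** and estimated from the data
  being scored; giving each model its own noise estimate would let the noise
  term absorb prior differences.
* **Degenerate fits** (zero spread) take the sigma floor and are flagged
  rather than erroring: an HTP subject who rates identically on every trial
  is a legitimate, indeed expected, outcome of the manipulation.
* **Undefined positive evidence ratios** (no subject favouring the Null
  model) are reported as `NA` with both counts preserved, never as infinity.
* **Attraction weights are computed on the variance ratio**
  \(\sigma_{like}^2/(\sigma_{like}^2+\sigma_{prior}^2)\) rather than raw
  precisions, so floored sigmas cannot overflow.
* **Natural log** is used for the exported `log_sigma_prior` covariate.

## Problem sizes and runtimes

The bundled tests and the acceptance script run on deliberately modest
problem sizes chosen to exercise every code path while staying quick on a
single CPU: the study-sized cohort (62 subjects, 12 trials/cell) for
end-to-end checks, 100–1000 random instances for oracle-equivalence sweeps,
200 trials/condition for estimator-consistency checks, and \(10^6\) draws for
the Monte-Carlo exceedance oracle. A full `run_pipeline()` on the default
cohort takes a few seconds.

## Known limitations

* Gaussians on a bounded 0–100 scale are an approximation; fits near the
  scale ends are shrunk toward the interior by truncation in the generator
  but the fitting stage itself ignores the bounds.
* The marginal likelihood treats the model's predicted posterior as a fixed
  hypothesis about the rating mean; uncertainty in the fitted prior and
  likelihood parameters is not propagated.
* Random-effects model selection is implemented for the two-model comparison
  it is used for; protected exceedance probabilities and family inference are
  out of scope.
* No sequential (trial-by-trial) belief updating: the prior is a static
  summary of the conditioning phase.
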