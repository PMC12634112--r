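---
title: "Equity-aware risk adjustment and hospital profiling: models and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Equity-aware risk adjustment and hospital profiling: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(hospprofile)
```

# The problem

Hospitals admit very different patient populations, so crude mortality and
readmission rates are not comparable across institutions. Risk-standardized
rates adjust each hospital's outcomes for its case mix, and the question this
package operationalizes is whether *equity-related factors* — disability,
homelessness, and neighborhood marginalization — should enter that
adjustment, and what changes when they do. Hospitals serving many
marginalized patients may look worse under purely clinical adjustment if
those factors carry outcome risk that clinical covariates do not capture;
conversely, adjusting for them can mask inequitable care. The package
implements the full measurement pipeline so that the behaviour of both
choices can be studied end to end on synthetic data with known ground truth.

The pipeline has six stages, each exposed as ordinary R functions:

1. **Synthetic cohort generation** (`cohort_config()`, `generate_cohort()`)
2. **Cohort construction** (`apply_mortality_exclusions()`,
   `build_episodes()`, `label_readmissions()`,
   `apply_readmission_exclusions()`, `truncate_reporting_tail()`, wrapped by
   `build_outcome_cohort()`)
3. **Risk-adjustment models** (`fit_risk_models()`, with `rcs_basis()`,
   `pool_small_groups()`, `fit_penalized_logistic()`,
   `select_penalty_aicc()`)
4. **Model evaluation** (`iecv()`, the eight metrics, `pool_random_effects()`)
5. **Hospital standardization** (`hospital_profile()`, built on
   `fit_random_intercept_glmm()`, `risk_standardized_rates()`,
   `cluster_bootstrap_ci()`, `classify_hospitals()`,
   `compare_classifications()`)
6. **Equity profiling** (`reference_hospital()`,
   `hospital_equity_effects()`, `heatmap_table()`)

`run_pipeline()` sequences all of them behind one configuration.

# Risk-adjustment models

Outcomes are in-hospital mortality (admission level) and 7-/30-day
readmission (episode-of-care level). Within each diagnosis group a separate
logistic regression is fit with:

* age as a 4-knot restricted cubic spline (`rcs_basis()`, Harrell's
  parameterization normalized by the knot range; knots at the 0.05, 0.35,
  0.65, 0.95 quantiles of age within the model group — standard practice
  when knot locations are not prespecified);
* sex, admission urgency (elective/urgent), Charlson comorbidity category
  (0/1/2+), and mLAPS (a laboratory-based acute physiology score) as a
  continuous linear term;
* restricted two-way interactions among age, Charlson, and mLAPS. "Restricted"
  is interpreted as interactions with the *linear* age component only
  (products of nonlinear spline terms are rarely identifiable at clinical
  sample sizes); this is configurable via `feature_spec(interactions =)`;
* for readmission outcomes, the number of discharges in the prior 6 months
  (0/1/2+);
* optionally the six equity-related factors: homelessness, disability (both
  binary), and four continuous neighborhood-marginalization dimensions
  (housing and dwellings, racialized and newcomer population, material
  resources, age and labor force; higher = more marginalized). The expanded
  model contains every base-model column plus exactly these six.

Diagnosis groups with fewer than 200 outcome events (strict bound) are pooled
into three "other" groups by tertile of their observed event rate, so sparse
groups borrow strength from groups of similar risk.

Each group's model carries an L2 penalty on the standardized non-intercept
coefficients (the intercept is never penalized; standardization makes the
penalty scale-free). The penalty is selected per model group by maximizing
the corrected AIC

$$2\,\ell(\hat\beta_\lambda) - 2\,df(\lambda) -
  \frac{2\,df(\lambda)\,(df(\lambda)+1)}{n - df(\lambda) - 1},$$

where $\ell$ is the unpenalized log-likelihood at the penalized estimate and
$df(\lambda) = \operatorname{tr}\!\left[I(\hat\beta)\,(I(\hat\beta) +
P_\lambda)^{-1}\right]$ is the effective degrees of freedom of the ridge
fit. Ties go to the smaller penalty. The default grid is $\{0, 1, 2, 4,
\dots, 1024\}$; whether the optimum should be searched per group or shared
globally is not settled in the methodology this follows — per-group search
is used because the groups' sample sizes differ by orders of magnitude.
Fitting is iteratively reweighted least squares with the ridge term in the
normal equations and step-halving on the penalized log-likelihood
(convergence on the gradient max-norm, tolerance $10^{-9}$, 50 iterations).

At prediction time a diagnosis group unseen in training falls back to the
"other" pool whose training event rate is nearest the global rate (with a
message); with no pools available this is an error rather than a silent
guess.

# Evaluating the models: internal–external cross-validation

Transportability across hospitals — not within-sample fit — is what matters
for profiling, so evaluation removes one hospital entirely, fits the whole
modeling pipeline (pooling, knots, penalty selection) on the remainder, and
scores predictions on the held-out hospital; every hospital serves once as
the external set. Eight metrics are computed per held-out hospital: AUC,
Brier Skill Score (reference: a constant prediction at the *held-out
hospital's own* event rate), calibration slope, calibration intercept,
Nagelkerke's $R^2$, discrimination slope, and the Integrated Calibration
Index (ICI) and E95 — the mean and 95th percentile of the absolute vertical
distance between a smoothed calibration curve and the diagonal, evaluated at
each observation's prediction.

Numerical choices worth knowing:

* The calibration smoother is `lowess` (local linear, span 0.75,
  configurable) with **no robustness iterations** — robustness reweighting
  treats the large residuals inherent to 0/1 outcomes as outliers and
  biases the curve severely.
* The calibration intercept uses the offset convention (slope fixed at 1);
  the slope comes from the unconstrained logistic recalibration. Both
  conventions appear in the literature; the offset intercept is reported
  because it separates calibration-in-the-large from slope shrinkage.
* Probabilities are clipped to $[10^{-12}, 1-10^{-12}]$ for likelihood-based
  quantities.
* Per-hospital standard errors come from a nonparametric bootstrap of
  $(p, y)$ pairs (default 1000 iterations); resamples on which a metric is
  undefined (single-class draws) are redrawn, and more than 50% degenerate
  draws is an error.

Per-hospital estimates are pooled by DerSimonian–Laird random-effects
meta-analysis (written from its closed formulas; `metafor::rma` backs the
optional REML estimator and serves as a cross-check in the tests), with a
Wald 95% interval on the pooled mean.

# Risk-standardized rates and classification

For reporting-period comparisons, the risk-model probability enters a
mixed-effects logistic model as the logit of the probability with an
estimated slope (linear-in-logit is the standard recalibration encoding; a
probability-scale covariate is a config option), with a hospital random
intercept $u_h \sim N(0, \sigma^2)$:

$$\operatorname{logit} P(y_i = 1) = a + b\,\operatorname{logit}(p_i) + u_{h(i)}.$$

The marginal likelihood is maximized by adaptive Gauss–Hermite quadrature
(10 nodes by default; 1 node is the Laplace approximation). The fitter is
specialized to this scalar-random-intercept, single-covariate model: the
posterior mode and curvature per hospital are found by vectorized Newton
steps and the node evaluations are done in one pass, which makes the
cluster bootstrap below affordable. It agrees with `lme4::glmer` (nAGQ = 10)
to about $10^{-4}$ on shared fixtures, and that agreement is asserted in the
test suite. The optimizer is `nlminb` over $(a, b, \sigma)$ with
$\sigma \ge 10^{-6}$; a boundary estimate is reported as $\sigma = 0$ with
all hospital intercepts exactly zero.

The hospital's **risk-standardized rate** is

$$\mathrm{RSR}_h = \frac{\sum_{i \in h} \operatorname{expit}(a + b x_i + u_h)}
                        {\sum_{i \in h} \operatorname{expit}(a + b x_i)}
                   \times \bar{y},$$

predicted over expected events, times the cohort crude rate; the "typical"
hospital is $u = 0$. Empirical-Bayes shrinkage pulls small hospitals toward
the mean, so the variance of RSRs never exceeds the variance of crude
per-hospital rates (a property test).

Intervals are a **cluster bootstrap**: hospitals are fixed entities;
admissions are resampled with replacement within hospital at the observed
sample size; the mixed model is refit and RSRs recomputed per replicate
(risk models are *not* refit — they belong to the training period, and the
bootstrap addresses reporting-period sampling only); the interval is the
2.5th/97.5th percentile over (by default) 1000 replicates. The crude rate is
recomputed per replicate, since it is itself a reporting-period statistic.
Replicates that fail to converge are dropped and redrawn; more than 5%
failures is an error. A hospital is *below average* when its interval lies
strictly below the crude rate, *above average* when strictly above, and
*average* otherwise — an endpoint exactly equal to the crude rate counts as
crossing.

`compare_classifications()` reports the 3×3 transition matrix between base
and equity-expanded adjustment, the movers, and each hospital's relative
change $(\mathrm{RSR}_{eq} - \mathrm{RSR}_{base})/\mathrm{RSR}_{base}$.

# Equity profiling

To see *which* equity factors track reclassification,
`hospital_equity_effects()` fits univariable models with hospital as the
categorical exposure and the equity factor as the outcome: logistic
regression for binary factors, proportional-odds (cumulative logit)
regression for continuous ones. A cumulative-logit model needs ordered
categories, so continuous marginalization dimensions are binned into
cohort-wide quintiles first (quintiles are also how such indices are
conventionally reported); the bin count is configurable. Fitting uses
`MASS::polr`. The reference hospital for each variable is the one whose
hospital-level median (proportion for binary variables) sits at the middle
rank, $\lceil k/2 \rceil$ — rank 12 of 23 hospitals — with ties broken by
hospital id so the choice is order-invariant. Log odds ratios beyond ±10
(separation) are truncated and flagged. `heatmap_table()` orders hospitals
by their relative RSR change, the display used to inspect the gradient.

# The synthetic cohort generator

The generator is first-class, tested code: every downstream stage is
validated against its ground truth. It emulates:

* 20 hospitals (default) of heterogeneous size; diagnosis-group prevalence
  with a long tail (geometric weights);
* covariate marginals matched to published cohort tables: age from a
  truncated normal (median ≈ 72, IQR ≈ 58–83), mLAPS from a rounded
  exponential with scale 23 (median ≈ 16, IQR ≈ 5–30 — only location and
  spread are pinned down, so any right-skewed shape matching them is
  acceptable), Charlson 0/1/2+ at 51.3/18.4/30.3%, urgent admissions 97.9%,
  prior-discharge categories at 69/19/12%;
* hospital random intercepts on the log-odds scale, default
  `hospital_sigma = 0.15` — a free parameter (per-hospital outcome
  dispersion is not published), documented as arbitrary;
* between-hospital equity gradients: logit shifts for homelessness
  (base prevalence 2%) and disability subtypes (cognitive 1.5%, physical
  12%, sensory 0.8%; the disability flag is their union), location shifts
  for the four continuous marginalization dimensions, plus one designated
  outlier hospital with extreme homelessness (+2 logits) and housing
  marginalization (+1.5), mirroring the single-outlier structure seen in
  real networks;
* outcome intercepts calibrated by root-finding so crude rates hit the
  targets (mortality 6.3%, 30-day readmission 13.1%), inflated by the
  expected fraction of follow-on records so the *final* table hits the
  target after transfer and readmission rows dilute the denominator;
* readmission chains constructed by design: events draw a gap from a
  truncated geometric on days 1–30 with decay 0.962, chosen once so that
  ~34% of 30-day readmissions fall within 7 days (the ratio of the 4.5% and
  13.1% target rates), and materialize as a follow-on admission (70% to the
  same hospital). Chains are single-level: a generated readmission does not
  itself spawn another. Deaths preclude readmission;
* contiguous interfacility transfers (follow-on admission at another
  hospital within hours, `transfer_in` set), out-of-network discharges,
  self sign-outs, and records violating each exclusion rule (age > 120,
  stay > 1 year, palliative/MAID diagnosis, missing dissemination area,
  invalid health card) in configurable proportions, each tagged with a
  hidden ground-truth label so filter counts can be verified exactly;
* a configurable fraction of discharges forced into the final 60 days of
  the window to exercise reporting-tail truncation.

All randomness derives from one seed with deterministic per-hospital child
seeds; regeneration is bit-for-bit reproducible. What the generator does
**not** emulate: realistic diagnosis-code sequences, seasonality, epidemic
shocks, within-patient correlation beyond readmission chains, and
correlation between equity factors and clinical covariates other than
through the outcome model. Passing tests therefore demonstrate the
*machinery* — recovery of known structure, leak-free validation, nominal
coverage — not that any particular real-world cohort would show the same
gradients.

# Cohort-construction conventions

Decisions the underlying methodology leaves open, and what this package
does:

* **Episode contiguity**: admissions of the same patient chain when the
  next admission begins within 12 hours of the prior discharge, overlaps
  it, or carries a transfer flag (configurable). "Contiguous" has no
  published operational definition; 12 hours is wide enough for
  administrative gaps in real transfers.
* **Readmission window**: "within 7/30 days" is read as $(0, w]$ whole days
  from discharge — day 7 (or 30) inclusive.
* **Tail truncation**: the most recent 37 days (7-day outcome) or 60 days
  (30-day outcome) are measured from *each hospital's own* maximum
  discharge date, matching data collected per hospital; measuring from the
  global study end is the other defensible reading.
* **Multi-rule rows** are counted under every exclusion rule they violate
  but removed once (counts are rule attributions, not a partition).
* **Length of stay** is discharge minus admission in days, with strictly
  more than 365 excluded.
* **Training/reporting split** is by discharge date with the boundary date
  in training. Hospitals whose reporting-period discharge span covers less
  than 95% (configurable) of the typical window are dropped from reporting;
  the window is measured to the *median* of per-hospital last discharges so
  a few year-long stays spilling past the calendar end do not distort the
  rule.

# Problem sizes used in the tests

The test suite runs the full statistical checks at sizes chosen to make the
properties sharp yet affordable: metric oracles on 100 random fixtures (n ≤
200); coefficient recovery on 20 replicates of a 50,000-row single-group
cohort; mixed-model recovery at 25 hospitals × 2,000 admissions (σ = 0.3);
the degenerate σ = 0 check at 25 × 20,000 — at 2,000 per hospital the MLE of
σ exceeds 0.02 on roughly a third of draws (verified against `lme4`), so the
boundary collapse is only statistically guaranteed at the larger size; null
coverage with 4 replications of 25 hospitals × 120 admissions at 200
bootstrap iterations; and equity-null/equity-gradient studies at 10–12
hospitals with ~1,000–2,500 admissions each. In the equity-null comparison,
base and expanded bootstrap runs share the resampling seed, so
classification flips can arise only from the tiny prediction differences;
a single borderline flip (an interval endpoint landing within that delta of
the crude rate) is sampling noise, not systematic reclassification, and the
test treats it as such.

# Known limitations

* The proportional-odds step bins continuous marginalization scores before
  fitting; with many tied values the quintile breaks may collapse (an error
  asks for fewer bins).
* The specialized mixed-model fitter handles exactly one fixed covariate
  plus a scalar random intercept — the model this methodology needs — and
  is not a general GLMM engine.
* Bootstrap intervals treat risk-model probabilities as fixed inputs;
  uncertainty from the training-period model fit is deliberately out of
  scope, as in the method this follows.
* With few admissions per hospital the random-intercept variance often
  collapses to zero, making every RSR equal the crude rate; this is the
  honest small-sample behaviour of the estimator, not a failure of the
  pipeline.
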