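---
title: "Modelling PSA kinetics and progression under androgen deprivation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling PSA kinetics and progression under androgen deprivation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(psaprog)
```

## The problem

Most men with hormone-sensitive prostate cancer respond to androgen
deprivation therapy (ADT) with an LHRH agonist such as leuprorelin, but
the response is transient: the PSA level falls, reaches a nadir, and in
many patients rises again as castration-resistant disease emerges.
`psaprog` models the population kinetics of serum PSA — used here as a
proxy for tumour burden — in treated patients, quantifies how baseline
covariates shift those kinetics, and converts the fitted model into
clinically interpretable quantities: the fraction of the tumour that was
resistant before treatment, doubling times of the sensitive and
resistant compartments, and the probability of PSA progression under
the Prostate Cancer Working Group (PCWG2) definition within one to
three years.

Because individual-level claims data of the kind such analyses are run
on cannot be redistributed, the package also contains a synthetic-cohort
generator that emulates the statistical structure of a claims-derived
cohort (264 subjects, ~1113 irregularly sampled PSA values, published
covariate summaries). Every fitting, selection, and simulation routine
is exercised against this generator in the test suite.

## Structural models

Two resistance mechanisms are implemented, both anchored at the
subject's observed baseline PSA (`BAS`, a data item, not an estimated
parameter), with `t1` the day of the first dose, pre-treatment growth
time $t_s = \min(t, t_1)$ and treatment time $t_k = \max(0, t - t_1)$:

* **Adaptation** (`predict_psa_adaptation()`): a single population whose
  drug response decays as resistance is acquired,
  $$PSA(t) = BAS\, e^{G t_s}\left(e^{-D t_k} + e^{G t_k} - 1\right).$$

* **Clonal selection** (`predict_psa_clonal()`): a small pre-existing
  resistant subpopulation (fraction $R = e^{-RP}$ of the initial tumour)
  grows through treatment while the sensitive compartment is killed,
  $$PSA_R(t) = BAS\,R\,e^{G_R t}, \qquad
    PSA_S(t) = BAS (1 - R)\, e^{G_S t_s} e^{-D_S t_k}.$$

The treatment-time clock is taken as $t_k = \max(0, t - t_1)$, the
only definition that keeps the trajectories continuous at $t_1$; the
tests assert that continuity. The resistant compartment grows as $e^{G_R t}$ from the
time origin, taken literally from its defining equation. A typical
trajectory under treatment from day 0 has a single interior minimum at
$t^* = \log\{D_S(1-R)/(G_R R)\}/(D_S + G_R)$
(`nadir_time_closed_form()`), which the progression simulations use as
an independent oracle for the nadir search.

Inter-individual variability is lognormal, $\theta_i = \theta_{typ}
e^{\eta_i}$ with $\eta_i \sim N(0, \omega^2)$ and a diagonal
$\Omega$. Continuous covariates enter as median-normalised power terms
$(x/\tilde x)^{\theta_{cov}}$ and categorical covariates as
exponentiated indicators, so on the log-parameter scale the whole
covariate model is linear — the property the estimation engine exploits.
Residual error is additive on log concentration with SD
$\sigma_{add}$; PSA values below the 0.1 ng/mL quantification limit
are fixed-point censored and contribute
$\Phi\{(\log LLOQ - \hat y)/\sigma_{add}\}$ to the likelihood (the M3
method).

`final_psa_model()` carries the published population estimates of the
final covariate model (kill rate modified by baseline PSA and
antiandrogen co-medication, resistant fraction modified by
haemoglobin); it is the default generative model of the synthetic
cohort and the input to the simulation layer.

## Estimation: MCPEM

`fit_psa_model()` maximises the marginal likelihood by Monte Carlo
Parametric Expectation Maximization. Each E step estimates, per
subject, the conditional mean and variance of the log individual
parameters by importance sampling with `isample` draws; each M step
updates the fixed effects by per-parameter least squares of the
conditional means on the covariate design (which reduces to the plain
mean update of `m_step()` when no covariates are present), the
variances by the spread of the conditional means plus the mean
conditional variance, and $\sigma_{add}$ from the expected squared log
residuals, with censored observations contributing truncated-normal
expected squares.

Numerical choices that matter:

* **Proposal.** The population density itself is a valid proposal but
  collapses at this problem's scale: with $\omega^2$ up to 3.8 and
  $\sigma_{add} \approx 0.2$, a subject's posterior occupies a vanishing
  fraction of the prior and the effective sample size approaches 1,
  after which the residual-variance update absorbs the
  inter-individual variability. The engine therefore re-centres the
  proposal per subject after every iteration (previous conditional
  mean; twice the conditional variance plus 5% of the current
  $\Omega$ as a floor) and weights draws by
  $l_i(\phi)\,h(\phi)/q(\phi)$. The first iteration still uses the
  population density. `e_step()`, the exported single-subject
  operation, keeps the plain population proposal, which is adequate at
  the large `isample` used in its oracle tests.
* **Residual damping.** $\sigma_{add}$ may change by at most a factor
  of $[0.7, 1.25]$ per iteration, preventing an early overshoot from
  flattening the weights before the fixed effects have moved.
* **Variance floor.** Free variances are floored at `1e-6` (and
  started no lower than 0.01) so the sampler never degenerates; a
  variance fixed at zero is honoured exactly.
* **Schedules.** The default staged schedule (`mcpem_control()`) is
  300 draws for 100 iterations, 1000 for 20, 5000 for 10 — a
  desk-scale analogue of the production schedule (1000/2000/50000),
  which can be requested explicitly. Estimates are taken at the final
  iteration; the objective function (OFV, $-2\log L$) is re-estimated
  at the final parameters with fresh draws and reported together with
  its Monte-Carlo standard error, so that the 10.83 likelihood-ratio
  threshold can be read against the sampling noise.
* **Convergence.** Over the last five final-stage iterations each
  traced parameter is regressed on the iteration number; the fit is
  declared converged when no slope differs from zero at the
  Bonferroni-adjusted level $\alpha/B$ (`convergence_check()`).
* **Anchoring.** Day 0 is the baseline observation and supplies `BAS`;
  that observation has identically zero residual and is excluded from
  the likelihood and the $\sigma$ update.
* **Reproducibility.** All draws derive from the master seed through
  fixed per-iteration, per-chunk substreams; the same seed and
  schedule give a bit-identical trace regardless of memory chunking.

The fixed-effect covariance (`estimate_covariance()`) is the inverse of
a central-finite-difference Hessian of the importance-sampled OFV with
common random numbers across perturbations, evaluated with the fit's
adapted proposals; a non-positive-definite Hessian falls back to an
eigenvalue pseudo-inverse with a warning. %CV is reported as
$100\,SE/\hat\theta$, which for lognormal typical values equals
$100\,SE(\log\hat\theta)$ by the delta method.

Model comparison (`compare_models()`) follows the conventions of the
field: nested models by the OFV difference against $\chi^2$ at
$p = 0.001$ (10.83 for one degree of freedom — deliberately stringent
because of multiple comparisons and Monte-Carlo noise), non-nested
models (adaptation vs clonal selection) by AIC $= OFV + 2\,N_{par}$.

## Covariate selection: WAM-BE

With 11 covariates and 4 parameters there are $2^{44}$ possible
covariate submodels; refitting is out of the question. The
Wald-approximation screen (`wam_backward_eliminate()`) uses a single
full-model fit: for a coefficient subvector $\theta_2$ restricted to
zero, $\Lambda' = \theta_2' C_{22}^{-1} \theta_2$ approximates the
likelihood-ratio statistic, where $C_{22}$ is the corresponding block
of the full-model covariance. Backward elimination greedily removes
the candidate whose conditional $\Lambda'$ increment is smallest until
every survivor exceeds 10.83 per degree of freedom, re-partitioning the
same covariance at each step (no refits); for a single coefficient the
rule is exactly $|z| > 3.29$. Multi-level categorical covariates enter
as one indicator per non-reference level and are screened jointly with
a $\chi^2_{levels-1}$ threshold at the same significance level — a
design choice where the convention was open. The survivors are then
confirmed by actual refits (`confirmatory_backward_elimination()`),
dropping a link whenever its removal costs less than 10.83 OFV points
and conservatively retaining any candidate whose refit fails.

A practical note on power: at the source study's scale (264 subjects)
the three published covariate effects sit at $z \approx 2.9$–$4.4$, so
any selection procedure with a $|z| > 3.29$ retention rule keeps all
three simultaneously only about a third of the time. The package's
selection-consistency test therefore runs at 800 synthetic subjects,
inside the asymptotic regime the screen presumes; this is a property of
the published effect sizes, not of the implementation.

## Progression simulation

`simulate_population()` draws per-subject random effects, evaluates
noise-free individual trajectories on a 7-day grid over three years
with continuous treatment from day 0, and applies the PCWG2 rule
(`pcwg2_progression_time()`): progression is the first grid time at
which PSA rises at least 25% *and* at least 2 ng/mL above the running
nadir, confirmed by any later value at least 21 days on that again
qualifies against the nadir fixed at the candidate time. Unconfirmed
transients are skipped and scanning continues. The simulation protocol
(noise-free individual predictions, weekly grid, common random numbers
across scenarios) was an open design point; noise-free predictions make
the confirmation clause deterministic, and residual error can be
switched on via `include_residual`. Nadir time and level are the grid
minimum over on-treatment times, ties to the earliest.

`predictive_check()` provides plain simulation-based predictive bands
(replicate cohorts on the observed designs, with residual error and
LLOQ censoring; 5/50/95 percentile bands of median log PSA per
time bin) as the diagnostics plumbing in place of a prediction-corrected
visual predictive check.

## The synthetic cohort

`cohort_design()` fixes the study conditions: 264 subjects; covariates
calibrated to the published medians and ranges (haemoglobin as a
truncated normal whose SD 1.55 matches the printed 5th/95th percentiles
10.9/16.0 g/dL; baseline PSA as a truncated lognormal with log-SD 1.65
matching 0.515/120 ng/mL; antiandrogen use Bernoulli 33/264; published
race/region frequencies; remaining laboratories as truncated normals or
lognormals median-matched within the printed ranges). Schedules mimic
claims-based PSA monitoring: the baseline measurement defines day 0,
treatment starts 60–180 days later, one extra pre-treatment value with
probability 0.5, a response check 60–120 days after the first dose (the
usual ~3-month PSA recheck after starting ADT — also what identifies
the kill-rate covariates), then visits every 210 ± 60 days over a
240–900-day follow-up. This yields ~4.3 observations per subject,
~1130 in total, matching the source cohort's density; the baseline
anchor is written noise-free so the generative law coincides exactly
with the fitted model family. The generator returns a truth ledger
(per-subject random effects and individual parameters) for recovery
experiments, and `generate_edge_case_fixtures()` builds one subject per
exclusion rule for the filter tests.

What the generator does *not* emulate: the selection process that
excluded 86% of treated patients from the source cohort, intermittent
dosing, measurement-frequency feedback (sicker patients being measured
more often), assay changes over time, or errors in the baseline
anchor. Passing recovery tests therefore show estimator correctness
under the stated generative law, not robustness to those real-data
features.

## Problem sizes and known limitations

The test suite runs the full recovery experiment at the study scale
(264 subjects, schedule 300×100 + 1000×20, about 1.5 minutes), ten
model-discrimination replicates at 64 subjects, the WAM consistency
experiment at 800 subjects, and 1000-subject progression simulations;
these sizes were chosen so the whole suite completes in minutes on one
core. At the study scale several parameters (sensitive growth rate,
resistant growth rate, the haemoglobin and antiandrogen coefficients)
carry 20–30% sampling uncertainty — matching the published %CVs — so
single-dataset recovery errors of that order are expected and the
recovery test at its fixed seed documents exactly that. Other known
limitations: $\Omega$ is diagonal (no correlated random effects in
v1); the importance-sampling proposal is diagonal-normal (no t tails);
the adaptation-model variant shares the engine but has no published
covariate model; and PSA is the sole state variable — no
testosterone/receptor pharmacology and no survival linkage.
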