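# psaprog

Population disease-progression modelling of PSA kinetics in
hormone-sensitive prostate cancer under androgen deprivation therapy
(ADT) with an LHRH agonist.

Serum PSA in a treated patient typically falls, reaches a nadir, and
rises again as castration resistance emerges. `psaprog` fits nonlinear
mixed-effects models of that time course to long-format PSA series,
selects covariates, and simulates clinical progression. It is written
for pharmacometricians and outcomes researchers who want the full
pipeline — data filtering, estimation, covariate selection, trial
simulation — as ordinary R functions with a classed model object.

## The models

Two resistance mechanisms, with `BAS` the observed baseline PSA,
`t1` the day of the first dose, `ts = min(t, t1)`, `tk = max(0, t - t1)`:

* **Adaptation** — initially sensitive cells acquire resistance:
  `PSA(t) = BAS * exp(G*ts) * (exp(-D*tk) + exp(G*tk) - 1)`
* **Clonal selection** — a pre-existing resistant fraction
  `R = exp(-RP)` outgrows the killed sensitive pool:
  `PSA_R(t) = BAS * R * exp(GR*t)`,
  `PSA_S(t) = BAS * (1-R) * exp(GS*ts) * exp(-DS*tk)`

Individual parameters are lognormal about covariate-adjusted typical
values (`theta_i = theta_typ * exp(eta_i)`, diagonal `Omega`); residual
error is additive on log PSA, and values below the 0.1 ng/mL assay
limit enter the likelihood as censored (M3). Estimation is Monte Carlo
Parametric Expectation Maximization (MCPEM) with a staged sampling
schedule; covariate selection is a Wald-approximation screen with
backward elimination (`Λ' = θ₂' C₂₂⁻¹ θ₂` from a single full-model
fit) confirmed by refits; progression uses the PCWG2 rule (≥25% and
≥2 ng/mL above the nadir, confirmed ≥3 weeks later).

Because the claims data behind such analyses cannot be shipped, the
package includes a synthetic-cohort generator calibrated to the
published cohort summaries; all tests run against it.

## Worked example

Simulate PSA progression under the published final model at the
5th-percentile haemoglobin, median covariates, and 95th-percentile
baseline PSA:

```r
library(psaprog)
m <- final_psa_model()          # published population estimates
covariate_scenario_table(m,
  list(HGB_p5  = list(HGB = 10.9, BAS = 8.5, AND = 0),
       median  = list(HGB = 13.6, BAS = 8.5, AND = 0),
       BAS_p95 = list(HGB = 13.6, BAS = 120, AND = 0)),
  n = 1000, seed = 1)
#>  scenario pct_1yr pct_2yr pct_3yr median_nadir_time median_nadir_level
#>    HGB_p5    19.6    29.5    34.9               154              1.155
#>    median    13.2    22.6    28.0               203              0.277
#>   BAS_p95    24.8    37.1    43.8               140              3.460
```

Low haemoglobin (larger resistant fraction) and high baseline PSA both
roughly double the one-year progression risk relative to the median
patient, and high-baseline patients reach a deeper-relative but
higher-absolute nadir sooner — the kinetic signature of a strong kill
rate over a larger tumour burden.

Fitting a synthetic cohort and reading the estimates table:

```r
co  <- generate_cohort(cohort_design(60), seed = 42)
fit <- fit_psa_model(co,
         psa_model("clonal",
           theta = c(DS = 0.02, GS = 0.005, RP = 2, GR = 0.002),
           omega = c(DS = 0.5, GS = 0.5, RP = 0.5, GR = 0.5), sigma = 0.3,
           links = list(cov_link("RP", "HGB", "power", ref = 13.6),
                        cov_link("DS", "BAS", "power", ref = 8.5),
                        cov_link("DS", "AND", "indicator"))),
         mcpem_control(stages = data.frame(isample = c(300, 1000),
                                           iters = c(60, 10))),
         seed = 7)
summary(fit)
#> OFV 459.225 (MC SE 2.32)   AIC 483.225   parameters 12
#>  parameter      block estimate pct_cv
#>         DS structural 0.039020   13.5
#>     DS:BAS  covariate 0.227200   39.2
#>     DS:AND  covariate 0.815900   52.8
#>         GS structural 0.001513   32.7
#>         RP structural 3.413000   12.8
#>     RP:HGB  covariate 1.900000   58.1
#>         GR structural 0.000513   42.4
#>  omega2_DS        IIV 0.460000     NA
#>  omega2_GS        IIV 1.478000     NA
#>  omega2_RP        IIV 0.750000     NA
#>  omega2_GR        IIV 6.060000     NA
#>  sigma_add   residual 0.218200     NA
```

At 60 subjects the kill rate `DS` (0.039/day, generative value
0.0378/day) and resistant-fraction parameter `RP` are estimated
precisely; the growth rates and covariate coefficients carry the
20–50% uncertainty expected at this sample size. `doubling_time(GS)`
and `100 * resistant_fraction(RP)` convert estimates to the clinical
scale, `predict(fit)` / `plot(fit)` give per-subject profiles, and
`compare_models()` performs the nested-LRT / AIC comparison.

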