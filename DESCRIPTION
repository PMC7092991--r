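Package: psaprog
Title: Population PSA Kinetics and Disease-Progression Modelling for
    Androgen Deprivation Therapy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Nonlinear mixed-effects modelling of prostate-specific
    antigen (PSA) kinetics in patients with hormone-sensitive prostate
    cancer on luteinizing hormone-releasing hormone (LHRH) agonist
    therapy.  Implements two structural tumour models (acquired
    adaptation resistance and clonal selection of a pre-existing
    resistant subpopulation), Monte Carlo Parametric Expectation
    Maximization (MCPEM) estimation with censored below-quantification
    observations, Wald-approximation covariate screening with backward
    elimination (WAM-BE), and clinical-trial simulation of PSA
    progression under Prostate Cancer Working Group (PCWG2) criteria.
    Includes a synthetic claims-like cohort generator so the full
    analysis pipeline can be exercised and tested without access to
    protected health data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, graphics
Suggests: testthat (>= 3.0.0), jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
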