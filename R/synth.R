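#' @title Synthetic claims-like cohort generation
#' @name synthetic-cohort
#' @description
#' Real leuprorelin claims data cannot be redistributed, so the package
#' ships a generator that emulates the statistical structure of the
#' analysis cohort: 264 subjects, baseline covariates calibrated to the
#' published summary medians/ranges (median age 80, median baseline PSA
#' 8.5 ng/mL, median haemoglobin 13.6 g/dL, antiandrogen use in
#' 33/264), irregular claims-like PSA monitoring schedules with a
#' pre-treatment window, lognormal inter-individual variability, additive
#' log-scale residual error, and fixed-point censoring at the 0.1 ng/mL
#' assay limit.  The generative law is exactly the fitted model family,
#' so parameter-recovery experiments have no structural mismatch.
NULL

#' Design of a synthetic cohort
#'
#' Distribution families are chosen to reproduce the published medians
#' within the published ranges: truncated normals for symmetric
#' laboratory values (HGB SD matched to the printed 5th/95th
#' percentiles 10.9/16.0 g/dL), truncated lognormals for right-skewed
#' ones (baseline PSA log-SD matched to the printed 5th/95th
#' percentiles 0.515/120 ng/mL), category frequencies as printed.
#' Observation schedules mimic claims-based PSA monitoring: the
#' baseline measurement defines day 0, treatment starts 60-180 days
#' later, an extra pre-treatment measurement occurs with probability
#' 0.5, the treatment response is rechecked 60-120 days after the first
#' dose (the usual ~3-month PSA check after starting ADT), and later
#' measurements recur every ~210 +/- 60 days over a 240-900 day
#' follow-up (about 4-5 observations per subject, of the order of the
#' 1113 observations in the source cohort).
#'
#' @param n_subjects cohort size (default 264).
#' @param model generative population model (default the published
#'   final model, [final_psa_model()]).
#' @param lloq assay lower limit of quantification, ng/mL.
#' @param t1_range days from baseline to the first dose.
#' @param pre_visit_prob probability of one extra pre-treatment visit.
#' @param first_visit range (days after the first dose) of the first
#'   on-treatment measurement.
#' @param visit_gap mean and half-width (days) of the later on-treatment
#'   visit spacing.
#' @param followup_range on-treatment follow-up length range, days.
#' @return a list of class `"cohort_design"`.
#' @export
cohort_design <- function(n_subjects = 264, model = final_psa_model(),
                          lloq = 0.1, t1_range = c(60, 180),
                          pre_visit_prob = 0.5,
                          first_visit = c(60, 120),
                          visit_gap = c(210, 60),
                          followup_range = c(240, 900)) {
  structure(list(
    n_subjects = n_subjects, model = model, lloq = lloq,
    t1_range = t1_range, pre_visit_prob = pre_visit_prob,
    first_visit = first_visit, visit_gap = visit_gap,
    followup_range = followup_range,
    covariates = list(
      AGE = list(kind = "truncnorm", mean = 80, sd = 8, lo = 60, hi = 100),
      AST = list(kind = "trunclnorm", med = 20, sdlog = 0.40, lo = 9, hi = 91),
      ALT = list(kind = "trunclnorm", med = 18, sdlog = 0.55, lo = 4, hi = 110),
      SCR = list(kind = "trunclnorm", med = 1.10, sdlog = 0.30, lo = 0.70, hi = 9.30),
      ALP = list(kind = "trunclnorm", med = 76.5, sdlog = 0.50, lo = 23, hi = 3640),
      ALB = list(kind = "truncnorm", mean = 4.13, sd = 0.35, lo = 2.90, hi = 4.80),
      HGB = list(kind = "truncnorm", mean = 13.6, sd = 1.55, lo = 6.80, hi = 17.4),
      BAS = list(kind = "trunclnorm", med = 8.50, sdlog = 1.65, lo = 0.20, hi = 782),
      AND = list(kind = "bernoulli", p = 33 / 264),
      RACE = list(kind = "categorical",
                  p = c(Caucasian = 189, Black = 59, Hispanic_other = 16) / 264),
      REGION = list(kind = "categorical",
                    p = c(South = 196, West = 20, Midwest = 42,
                          Northeast = 6) / 264))),
    class = "cohort_design")
}

#' Sample baseline covariates from a design
#'
#' @param design a [cohort_design()].
#' @param n number of subjects (default the design's cohort size).
#' @param seed optional RNG seed.
#' @return data.frame of covariates, one row per subject.
#' @export
sample_covariates <- function(design, n = design$n_subjects, seed = NULL) {
  draw <- function(spec) {
    switch(spec$kind,
      truncnorm = rtruncnorm(n, spec$mean, spec$sd, spec$lo, spec$hi),
      trunclnorm = rtrunclnorm(n, log(spec$med), spec$sdlog, spec$lo, spec$hi),
      bernoulli = as.integer(stats::runif(n) < spec$p),
      categorical = names(spec$p)[1L + findInterval(stats::runif(n),
                                                    cumsum(spec$p))],
      stop("unknown covariate kind"))
  }
  with_seed(seed,
            as.data.frame(lapply(design$covariates, draw),
                          stringsAsFactors = FALSE))
}

#' Generate a synthetic cohort with a truth ledger
#'
#' Per subject: covariates are sampled, random effects drawn from the
#' generative model's `omega`, a claims-like observation schedule laid
#' out, noise-free predictions evaluated, residual error added on the
#' log scale (except at the baseline anchor, which defines `BAS`), and
#' values falling below the LLOQ flagged as censored and reported at
#' the limit.
#'
#' @param design a [cohort_design()].
#' @param seed RNG seed (the generator is fully seed-deterministic).
#' @return a [psa_cohort()]; attribute `"truth"` holds the per-subject
#'   random effects and individual parameters.
#' @export
generate_cohort <- function(design, seed = 1) {
  with_seed(seed, {
    n <- design$n_subjects
    model <- design$model
    pn <- names(model$theta)
    cov <- sample_covariates(design, n)
    typ <- typical_params(model, cov)
    eta <- sapply(pn, function(p) stats::rnorm(n, 0, sqrt(model$omega[[p]])))
    if (n == 1) eta <- matrix(eta, 1, dimnames = list(NULL, pn))
    par <- individual_params(typ, eta)
    subjects <- vector("list", n)
    for (i in seq_len(n)) {
      t1 <- round(stats::runif(1, design$t1_range[1], design$t1_range[2]))
      times <- 0
      if (stats::runif(1) < design$pre_visit_prob) {
        v <- round(stats::runif(1, 0.3, 0.7) * t1)
        if (v > 0 && v < t1) times <- c(times, v)
      }
      fu <- stats::runif(1, design$followup_range[1], design$followup_range[2])
      tt <- t1 + round(stats::runif(1, design$first_visit[1],
                                    design$first_visit[2]))
      while (tt <= t1 + fu) {
        times <- c(times, tt)
        tt <- tt + round(stats::runif(1, design$visit_gap[1] - design$visit_gap[2],
                                      design$visit_gap[1] + design$visit_gap[2]))
      }
      if (max(times) <= t1)                    # guarantee an on-treatment value
        times <- c(times, t1 + round(mean(design$first_visit)))
      times <- sort(unique(times))
      bas <- cov$BAS[i]
      pred <- predict_psa_clonal(par[i, ], bas, times, t1)$psa_total
      lognoise <- stats::rnorm(length(times), 0, model$sigma)
      lognoise[times == 0] <- 0            # the anchor defines BAS
      dv <- exp(log(pred) + lognoise)
      blq <- dv < design$lloq
      dv[blq] <- design$lloq
      subjects[[i]] <- psa_subject(id = sprintf("S%03d", i), time = times,
                                   dv = dv, blq = blq, t1 = t1,
                                   cov = as.list(cov[i, , drop = FALSE]))
    }
    cohort <- psa_cohort(subjects, lloq = design$lloq)
    truth <- data.frame(ID = vapply(subjects, function(s) s$id, ""),
                        cov, eta = eta, par)
    attr(cohort, "truth") <- truth
    cohort
  })
}

#' Deterministic edge-case fixture cohort
#'
#' A small in-memory cohort holding one subject violating each exclusion
#' rule (decreasing pre-treatment PSA; undetectable baseline; duplicate
#' same-day values; all on-treatment values censored; missing
#' demographics; haemoglobin below 6 g/dL) plus clean subjects, used to
#' exercise [apply_exclusion_filters()].
#'
#' @return a [psa_cohort()].
#' @export
generate_edge_case_fixtures <- function() {
  base_cov <- list(AGE = 75, RACE = "Caucasian", REGION = "South", AND = 0,
                   AST = 20, ALT = 18, SCR = 1.1, ALP = 76, ALB = 4.1,
                   HGB = 13.6, BAS = 10)
  mk <- function(id, time, dv, blq, t1, cov = base_cov, validate = TRUE)
    psa_subject(id, time, dv, blq, t1, cov, validate = validate)
  subjects <- list(
    # rule a: strictly decreasing PSA before treatment
    mk("EX_A", c(0, 40, 120, 220), c(12, 9, 3, 1.5),
       c(FALSE, FALSE, FALSE, FALSE), t1 = 80),
    # rule b: undetectable baseline
    mk("EX_B", c(0, 100, 200), c(0.1, 0.5, 0.8), c(TRUE, FALSE, FALSE),
       t1 = 30),
    # rule c: duplicate same-day measurements (invalid by construction)
    mk("EX_C", c(0, 90, 90, 180), c(8, 4, 4.2, 2), rep(FALSE, 4), t1 = 30,
       validate = FALSE),
    # rule d: every on-treatment value censored
    mk("EX_D", c(0, 90, 200, 300), c(4, 0.1, 0.1, 0.1),
       c(FALSE, TRUE, TRUE, TRUE), t1 = 30),
    # rule e: missing demographics
    mk("EX_E", c(0, 100, 200), c(6, 2, 1), rep(FALSE, 3), t1 = 30,
       cov = utils::modifyList(base_cov, list(AGE = NA))),
    # rule f: haemoglobin below 6 g/dL
    mk("EX_F", c(0, 100, 200), c(9, 3, 1.5), rep(FALSE, 3), t1 = 30,
       cov = utils::modifyList(base_cov, list(HGB = 5.9))),
    # clean subjects: rising pre-treatment PSA, detectable baseline,
    # mixed on-treatment values, complete demographics
    mk("OK_1", c(0, 40, 150, 300, 500), c(8, 9.5, 2, 0.1, 0.8),
       c(FALSE, FALSE, FALSE, TRUE, FALSE), t1 = 60),
    mk("OK_2", c(0, 120, 350), c(15, 5, 1.2), rep(FALSE, 3), t1 = 20))
  psa_cohort(subjects, lloq = 0.1)
}
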