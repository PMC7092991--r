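#' @title PCWG2 PSA progression and clinical-trial simulation
#' @name progression
#' @description
#' PSA progression follows the Prostate Cancer Working Group (PCWG2/3)
#' definition: the date of a 25% or greater increase *and* an absolute
#' increase of at least 2 ng/mL above the running nadir, confirmed by a
#' second qualifying value at least three weeks later.  Populations are
#' simulated from a fitted model by sampling per-subject random effects
#' and evaluating individual (noise-free) predictions on a regular grid
#' from treatment start.
NULL

#' Time of confirmed PCWG2 PSA progression
#'
#' Scans the trajectory for the first time exceeding
#' `max(1.25 * nadir, nadir + 2)` over the running nadir; the call is
#' confirmed if any value at least `confirm_days` later also qualifies
#' against the nadir fixed at the candidate time.  Unconfirmed
#' candidates are skipped and scanning continues.
#'
#' @param time grid times in days (step must resolve the three-week
#'   confirmation window, i.e. <= 21 days).
#' @param psa PSA values on the grid, ng/mL.
#' @param confirm_days confirmation delay (default 21).
#' @param require_absolute apply the +2 ng/mL absolute criterion (the
#'   PCWG2 rule; disabling it can only add progression calls).
#' @return day of the first confirmed progression, or `NA` if none.
#' @export
pcwg2_progression_time <- function(time, psa, confirm_days = 21,
                                   require_absolute = TRUE) {
  if (length(time) == 0) stop("empty trajectory")
  if (length(time) != length(psa)) stop("time and psa lengths differ")
  nadir <- cummin(psa)
  thr <- if (require_absolute) pmax(1.25 * nadir, nadir + 2) else 1.25 * nadir
  cand <- which(psa >= thr)
  for (j in cand) {
    later <- time >= time[j] + confirm_days
    if (any(later & psa >= thr[j])) return(time[j])
  }
  NA_real_
}

#' Nadir time and level of a trajectory
#'
#' @param time grid times, days.
#' @param psa PSA on the grid, ng/mL.
#' @param t_start restrict the search to on-treatment times
#'   (`time >= t_start`); ties break to the earliest time.
#' @return named vector `c(nadir_time, nadir_level)`.
#' @export
nadir_metrics <- function(time, psa, t_start = 0) {
  on <- which(time >= t_start)
  if (!length(on)) stop("no on-treatment grid times")
  k <- on[which.min(psa[on])]
  c(nadir_time = time[k], nadir_level = psa[k])
}

#' Simulate PSA progression in a treated population
#'
#' Samples `n` subjects' random effects from the model's `omega`,
#' evaluates each individual trajectory on a regular grid with treatment
#' from day 0, and summarises confirmed PCWG2 progression and nadir
#' kinetics.  Trajectory metrics use noise-free individual predictions
#' by default; residual error can be switched on.
#'
#' @param model a [psa_model()] (normally with final covariate links).
#' @param covariates named list/one-row data.frame of covariates shared
#'   by all simulated subjects (a scenario), e.g.
#'   `list(HGB = 13.6, BAS = 8.5, AND = 0)`.
#' @param n number of simulated subjects.
#' @param horizon simulation horizon, days (>= 365).
#' @param grid_step grid spacing, days (<= 21).
#' @param include_residual add lognormal residual error to the
#'   trajectories before applying the progression rule.
#' @param seed RNG seed.
#' @return object of class `"psa_progression_summary"`: percent
#'   progressed by 1/2/3 years, median nadir time and level, and the
#'   per-subject records.
#' @export
simulate_population <- function(model, covariates = list(HGB = 13.6, BAS = 8.5,
                                                         AND = 0),
                                n = 1000, horizon = 1095, grid_step = 7,
                                include_residual = FALSE, seed = 1) {
  stopifnot(horizon >= 365, grid_step <= 21)
  if (model$structure != "clonal")
    stop("population simulation is defined for the clonal model")
  cov <- as.data.frame(covariates, stringsAsFactors = FALSE)
  if (!"BAS" %in% names(cov)) stop("covariates must include BAS")
  bas <- cov$BAS
  typ <- typical_params(model, cov)   # 1 x p
  tg <- seq(0, horizon, by = grid_step)
  with_seed(seed, {
    eta <- sapply(names(model$theta), function(p)
      stats::rnorm(n, 0, sqrt(model$omega[[p]])))
    par <- individual_params(matrix(typ, n, ncol(typ), byrow = TRUE,
                                    dimnames = list(NULL, colnames(typ))), eta)
    R <- exp(-par[, "RP"])
    # n x T trajectory matrix; treatment from day 0 so ts = 0, tk = t
    TR <- (bas * R) * exp(outer(par[, "GR"], tg)) +
      (bas * (1 - R)) * exp(-outer(par[, "DS"], tg))
    if (include_residual)
      TR <- TR * exp(matrix(stats::rnorm(length(TR), 0, model$sigma),
                            nrow(TR), ncol(TR)))
    rec <- t(vapply(seq_len(n), function(i) {
      nm <- nadir_metrics(tg, TR[i, ])
      c(progression_time = pcwg2_progression_time(tg, TR[i, ]), nm)
    }, numeric(3)))
    records <- data.frame(subject = seq_len(n), rec)
    pct <- vapply(c(365, 730, 1095), function(d)
      100 * mean(!is.na(records$progression_time) &
                   records$progression_time <= d), 0)
    structure(list(
      pct_progressed = stats::setNames(pct, c("1yr", "2yr", "3yr")),
      median_nadir_time = stats::median(records$nadir_time),
      median_nadir_level = stats::median(records$nadir_level),
      records = records, covariates = cov, n = n, horizon = horizon,
      grid_step = grid_step, seed = seed),
      class = "psa_progression_summary")
  })
}

#' @export
print.psa_progression_summary <- function(x, ...) {
  cat("Simulated PSA progression (", x$n, " subjects, ",
      x$horizon, "-day horizon)\n", sep = "")
  cat("  covariates:", paste(sprintf("%s=%s", names(x$covariates),
                                     unlist(x$covariates)), collapse = ", "), "\n")
  cat(sprintf("  %% progressed: 1 yr %.1f, 2 yr %.1f, 3 yr %.1f\n",
              x$pct_progressed["1yr"], x$pct_progressed["2yr"],
              x$pct_progressed["3yr"]))
  cat(sprintf("  median nadir: %.3g ng/mL at day %.0f\n",
              x$median_nadir_level, x$median_nadir_time))
  invisible(x)
}

#' Progression summaries across covariate scenarios
#'
#' @param model a [psa_model()].
#' @param scenarios named list of covariate sets (each a named
#'   list/one-row data.frame).
#' @param ... forwarded to [simulate_population()] (`n`, `horizon`,
#'   `grid_step`, `seed`, ...).  The same seed is used for every
#'   scenario, so scenarios share their random-effect draws (common
#'   random numbers).
#' @return data.frame, one row per scenario: percent progressed at
#'   1/2/3 years and median nadir time/level.
#' @export
covariate_scenario_table <- function(model, scenarios, ...) {
  rows <- lapply(names(scenarios), function(nm) {
    s <- simulate_population(model, covariates = scenarios[[nm]], ...)
    data.frame(scenario = nm,
               pct_1yr = s$pct_progressed[["1yr"]],
               pct_2yr = s$pct_progressed[["2yr"]],
               pct_3yr = s$pct_progressed[["3yr"]],
               median_nadir_time = s$median_nadir_time,
               median_nadir_level = s$median_nadir_level)
  })
  do.call(rbind, rows)
}

#' Simulation-based predictive check
#'
#' Simulates `n_rep` replicate cohorts on the observed designs
#' (observation times, treatment starts and covariates), with residual
#' error and LLOQ censoring, and compares percentile bands of median log
#' PSA per time bin against the observed medians.
#'
#' @param model a [psa_model()] (or the `model` of a fit).
#' @param cohort the observed cohort.
#' @param n_rep number of replicate cohorts.
#' @param bins number of on-treatment-time bins (quantile-spaced).
#' @param probs percentiles of the replicate medians reported as bands.
#' @param seed RNG seed.
#' @return object of class `"psa_ppc"` with per-bin observed medians and
#'   simulated bands.
#' @export
predictive_check <- function(model, cohort, n_rep = 200, bins = 6,
                             probs = c(0.05, 0.5, 0.95), seed = 1) {
  if (inherits(model, "psa_fit")) model <- model$model
  dat <- .prep_fit_data(cohort, model)
  tk <- dat$tk
  brk <- unique(stats::quantile(tk, probs = seq(0, 1, length.out = bins + 1)))
  bin <- cut(tk, brk, include.lowest = TRUE)
  obs_med <- tapply(dat$y, bin, stats::median)
  typ <- typical_params(model, dat$cov)
  p <- length(dat$params)
  with_seed(seed, {
    sim_med <- matrix(NA_real_, n_rep, nlevels(bin))
    for (r in seq_len(n_rep)) {
      eta <- matrix(stats::rnorm(dat$m * p), dat$m, p)
      eta <- sweep(eta, 2, sqrt(model$omega), "*")
      phi <- log(typ) + eta
      lp <- numeric(dat$n_obs)
      for (i in seq_len(dat$m)) {
        oi <- which(dat$sub == i)
        if (!length(oi)) next
        lp[oi] <- .subject_logpred(model, phi[i, , drop = FALSE],
                                   dat$bas[i], dat$t[oi], dat$t1[i])[1, ]
      }
      ysim <- lp + stats::rnorm(dat$n_obs, 0, model$sigma)
      ysim <- pmax(ysim, log(dat$lloq))   # censored values reported at LLOQ
      sim_med[r, ] <- tapply(ysim, bin, stats::median)
    }
    bands <- apply(sim_med, 2, stats::quantile, probs = probs, na.rm = TRUE)
    colnames(bands) <- levels(bin)
    structure(list(bins = levels(bin),
                   bin_mid = (utils::head(brk, -1) + utils::tail(brk, -1)) / 2,
                   observed_median = obs_med, bands = bands,
                   within = obs_med >= bands[1, ] & obs_med <= bands[nrow(bands), ],
                   n_rep = n_rep, probs = probs), class = "psa_ppc")
  })
}

#' @export
print.psa_ppc <- function(x, ...) {
  cat("Predictive check (", x$n_rep, " replicates): observed median log PSA ",
      "within the ", 100 * (x$probs[length(x$probs)] - x$probs[1]),
      "% band in ", sum(x$within), "/", length(x$within), " time bins\n",
      sep = "")
  invisible(x)
}

#' @export
plot.psa_ppc <- function(x, ...) {
  ylim <- range(c(x$observed_median, x$bands), na.rm = TRUE)
  graphics::plot(x$bin_mid, x$observed_median, type = "b", pch = 16,
                 ylim = ylim, xlab = "days on treatment",
                 ylab = "median log PSA", ...)
  graphics::lines(x$bin_mid, x$bands[1, ], lty = 2, col = "steelblue")
  graphics::lines(x$bin_mid, x$bands[nrow(x$bands), ], lty = 2,
                  col = "steelblue")
  graphics::lines(x$bin_mid, x$bands[2, ], lty = 1, col = "steelblue")
  invisible(x)
}
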