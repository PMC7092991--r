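#' @title Monte Carlo Parametric Expectation Maximization
#' @name mcpem
#' @description
#' Population parameters are estimated by MCPEM: the E step evaluates
#' each subject's conditional mean and variance of the log individual
#' parameters by importance sampling, drawing `isample` parameter
#' vectors from the current population density and weighting them by the
#' subject likelihood; the M step updates the population location by
#' (per-parameter) least squares of the conditional means on the
#' covariate design, and the variances by the empirical spread of the
#' conditional means plus the mean conditional variance.  A staged
#' sampling schedule (small `isample` burn-in, large `isample` finish)
#' trades Monte-Carlo noise against run time; convergence over the final
#' stage is declared when no traced parameter shows a regression slope
#' significantly different from zero at a Bonferroni-adjusted level.
NULL

#' Control settings for the MCPEM fit
#'
#' @param stages data.frame with columns `isample` (Monte-Carlo draws per
#'   subject per E step) and `iters` (EM iterations at that draw count).
#'   The default `(300 x 100, 1000 x 20, 5000 x 10)` is a desk-scale
#'   schedule; a production schedule such as
#'   `(1000 x 150, 2000 x 50, 50000 x 50)` can be supplied instead.
#' @param window number of final-stage iterations examined by the
#'   convergence regression (>= 3).
#' @param alpha significance level before Bonferroni adjustment.
#' @param fix names of fixed-effect components held at their starting
#'   values (structural parameter names for log typical values, link
#'   names such as `"RP:HGB"` for coefficients).
#' @param fix_omega structural parameter names whose variance is not
#'   updated.
#' @param fix_sigma hold the residual SD at its starting value.
#' @param omega_floor lower bound applied to free variances so the
#'   importance-sampling proposal never degenerates.
#' @param vcov estimate the fixed-effect covariance after fitting.
#' @param vcov_isample Monte-Carlo size for the covariance Hessian.
#' @param ofv_isample Monte-Carlo size for the final objective-function
#'   evaluation (default: the last stage's `isample`).
#' @param chunk_limit memory cap (elements) per E-step work chunk.
#' @return a list of class `"mcpem_control"`.
#' @export
mcpem_control <- function(stages = data.frame(isample = c(300, 1000, 5000),
                                              iters = c(100, 20, 10)),
                          window = 5, alpha = 0.05,
                          fix = character(), fix_omega = character(),
                          fix_sigma = FALSE, omega_floor = 1e-6,
                          vcov = TRUE, vcov_isample = 1000,
                          ofv_isample = NULL, chunk_limit = 4e6) {
  stopifnot(all(stages$isample >= 1), all(stages$iters >= 1), window >= 3)
  structure(list(stages = stages, window = window, alpha = alpha,
                 fix = fix, fix_omega = fix_omega, fix_sigma = fix_sigma,
                 omega_floor = omega_floor, vcov = vcov,
                 vcov_isample = vcov_isample, ofv_isample = ofv_isample,
                 chunk_limit = chunk_limit),
            class = "mcpem_control")
}

# Importance-sampled conditional moments for an arbitrary log-likelihood.
# Kept separate from the model so conjugate toys can exercise it directly.
.e_step_core <- function(llfun, mu, omega, isample) {
  p <- length(mu)
  eta <- matrix(stats::rnorm(isample * p), isample, p)
  eta <- sweep(eta, 2, sqrt(pmax(omega, 0)), "*")
  phi <- sweep(eta, 2, mu, "+")
  colnames(phi) <- names(mu)
  ll <- llfun(phi)
  mx <- max(ll)
  if (!is.finite(mx))
    stop("all importance weights underflowed; increase isample")
  w <- exp(ll - mx)
  W <- w / sum(w)
  tb <- colSums(W * phi)
  dev <- sweep(phi, 2, tb, "-")
  B <- crossprod(dev * sqrt(W), dev * sqrt(W))
  list(theta_bar = stats::setNames(tb, names(mu)),
       B_bar = B, logmarg = mx + log(mean(w)), ess = 1 / sum(W^2))
}

#' Conditional moments of one subject's log parameters (E step)
#'
#' Draws `isample` log-parameter vectors from the population density and
#' returns the self-normalised importance-weighted mean and covariance,
#' with weights proportional to the subject likelihood.
#'
#' @param model a [psa_model()] providing the population location
#'   (covariate-adjusted log typical values) and `omega`.
#' @param subject a [psa_subject()].
#' @param isample number of Monte-Carlo draws.
#' @param seed RNG seed (the caller's RNG state is restored).
#' @return list with `theta_bar` (conditional mean, log scale), `B_bar`
#'   (conditional covariance), `logmarg` (log marginal likelihood
#'   estimate) and `ess` (effective sample size).
#' @export
e_step <- function(model, subject, isample, seed = 1) {
  cov <- .subject_cov(subject)
  mu <- log(drop(typical_params(model, cov)))
  llfun <- function(phi) {
    eta <- sweep(phi, 2, mu, "-")
    subject_loglik(model, subject, eta)
  }
  with_seed(seed, .e_step_core(llfun, mu, model$omega, isample))
}

#' Population update from conditional moments (M step)
#'
#' The population mean is the average of the conditional means; the
#' variance is the empirical second central moment of the conditional
#' means plus the average conditional variance.
#'
#' @param moments list of E-step results (elements with `theta_bar` and
#'   `B_bar`).
#' @param diagonal zero the off-diagonal covariance entries (the default;
#'   only variances are estimated).
#' @return list with `mu` and `Omega`.
#' @export
m_step <- function(moments, diagonal = TRUE) {
  m <- length(moments)
  if (m < 1) stop("need at least one subject")
  TB <- do.call(rbind, lapply(moments, `[[`, "theta_bar"))
  mu <- colMeans(TB)
  dev <- sweep(TB, 2, mu, "-")
  Omega <- crossprod(dev) / m +
    Reduce(`+`, lapply(moments, `[[`, "B_bar")) / m
  if (diagonal) Omega <- diag(diag(Omega), nrow = ncol(TB))
  dimnames(Omega) <- list(colnames(TB), colnames(TB))
  list(mu = mu, Omega = Omega)
}

#' Fit a population PSA kinetics model by MCPEM
#'
#' @param cohort a [psa_cohort()] that has passed the exclusion filters.
#' @param model a [psa_model()] supplying the structure, covariate links
#'   and starting values.
#' @param control an [mcpem_control()].
#' @param seed master seed; the full iteration trace is reproducible
#'   bit-for-bit given the same seed and schedule.
#' @return an object of class `"psa_fit"`: the final model, objective
#'   function value (`ofv`, -2 log marginal likelihood), `aic`,
#'   fixed-effect covariance and %CV (when `control$vcov`), per-iteration
#'   trace, convergence verdicts, and the conditional log-parameter
#'   means used by [predict.psa_fit()] and [residuals.psa_fit()].
#' @export
fit_psa_model <- function(cohort, model, control = mcpem_control(), seed = 1) {
  stopifnot(inherits(cohort, "psa_cohort"), inherits(model, "psa_model"))
  dat <- .prep_fit_data(cohort, model)
  pn <- dat$params
  beta <- .model_beta(model)
  omega <- model$omega
  free_om <- setdiff(pn, control$fix_omega)
  omega[free_om] <- pmax(omega[free_om], 0.01)  # free variances must move
  sigma <- model$sigma
  base_seed <- as.integer(seed) %% 2147483629L

  n_it <- sum(control$stages$iters)
  trace <- vector("list", n_it)
  it <- 0L
  prop_mean <- NULL; prop_var <- NULL
  for (st in seq_len(nrow(control$stages))) {
    N <- control$stages$isample[st]
    for (k in seq_len(control$stages$iters[st])) {
      it <- it + 1L
      pass <- .mc_pass(dat, beta, omega, sigma, N,
                       draw_seed = (base_seed + 1000003L * it) %% 2147483629L,
                       want_moments = TRUE, want_sigma = !control$fix_sigma,
                       prop_mean = prop_mean, prop_var = prop_var,
                       chunk_limit = control$chunk_limit)
      # posterior-centred proposal for the next E step: previous
      # conditional mean, inflated conditional variance plus a floor so
      # the proposal keeps covering the population density
      prop_mean <- pass$thetabar
      prop_var <- 2 * pass$Bdiag +
        matrix(0.05 * omega, dat$m, length(pn), byrow = TRUE)
      trace[[it]] <- c(iter = it, isample = N, ofv = pass$ofv,
                       beta, omega = omega, sigma = sigma)
      # M step: per-parameter least squares of conditional means on the
      # covariate design; variances from spread + mean conditional var.
      for (j in seq_along(pn)) {
        p <- pn[j]
        X <- dat$X[[p]]; cols <- colnames(X)
        freeC <- setdiff(cols, control$fix)
        off <- if (length(freeC) < length(cols))
          drop(X[, setdiff(cols, freeC), drop = FALSE] %*%
                 beta[setdiff(cols, freeC)]) else 0
        resid <- pass$thetabar[, j] - off
        if (length(freeC)) {
          bf <- qr.solve(X[, freeC, drop = FALSE], resid)
          beta[freeC] <- bf
          resid <- resid - drop(X[, freeC, drop = FALSE] %*% bf)
        } else resid <- resid - drop(X %*% beta[cols]) + off
        if (p %in% free_om)
          omega[p] <- max(mean(resid^2) + mean(pass$Bdiag[, j]),
                          control$omega_floor)
      }
      if (!control$fix_sigma && dat$n_obs > 0) {
        # damp the residual update: an early sigma overshoot flattens the
        # importance weights and stalls the fixed-effect updates
        sig_new <- sqrt(pass$sig_ss / dat$n_obs)
        sigma <- min(max(sig_new, sigma * 0.7), sigma * 1.25)
      }
      last <- pass
    }
  }
  trace <- as.data.frame(do.call(rbind, trace))

  N_ofv <- control$ofv_isample %||% utils::tail(control$stages$isample, 1)
  fpass <- .mc_pass(dat, beta, omega, sigma, N_ofv,
                    draw_seed = (base_seed + 1000003L * (it + 1L)) %% 2147483629L,
                    want_moments = TRUE, want_sigma = FALSE,
                    prop_mean = prop_mean, prop_var = prop_var,
                    chunk_limit = control$chunk_limit)

  final_model <- .set_model_beta(model, beta)
  final_model$omega <- omega
  final_model$sigma <- sigma

  n_free_beta <- length(setdiff(names(beta), control$fix))
  npar <- n_free_beta + length(free_om) + (!control$fix_sigma)
  ofv <- fpass$ofv
  fit <- structure(list(
    model = final_model, beta = beta, omega = omega, sigma = sigma,
    ofv = ofv, ofv_mc_se = fpass$ofv_mc_se, npar = npar,
    aic = ofv + 2 * npar,
    trace = trace, seed = seed, control = control,
    cond_mean = fpass$thetabar, cond_var = fpass$Bdiag,
    prop_mean = prop_mean, prop_var = prop_var,
    cohort = cohort, dat = dat, signature = dat$signature,
    vcov = NULL, se = NULL, pct_cv = NULL, vcov_pd = NA), class = "psa_fit")

  final_iters <- trace$isample == utils::tail(control$stages$isample, 1)
  if (sum(final_iters) >= control$window) {
    fit$convergence <- convergence_check(
      trace[final_iters, , drop = FALSE],
      window = control$window, alpha = control$alpha)
    fit$converged <- attr(fit$convergence, "converged")
  } else {
    fit$convergence <- NULL
    fit$converged <- NA
  }

  if (control$vcov) {
    vc <- estimate_covariance(fit, isample = control$vcov_isample,
                              seed = (base_seed + 777L) %% 2147483629L)
    fit$vcov <- vc$cov; fit$se <- vc$se; fit$pct_cv <- vc$pct_cv
    fit$vcov_pd <- vc$positive_definite
  }
  fit
}

#' Test convergence of an MCPEM trace
#'
#' For each traced parameter, an ordinary least-squares regression of the
#' last `window` iterations against the iteration number is tested
#' against zero slope at level `alpha / B` (Bonferroni over the `B`
#' tested parameters).  The run has converged when no slope is
#' significant.
#'
#' @param trace data.frame of per-iteration parameter values (columns
#'   other than `iter`, `isample`, `ofv` are tested).
#' @param window number of trailing iterations used (>= 3).
#' @param alpha overall significance level.
#' @return data.frame of per-parameter slopes and p-values, with
#'   attribute `converged`.
#' @export
convergence_check <- function(trace, window = 5, alpha = 0.05) {
  stopifnot(window >= 3)
  if (nrow(trace) < window)
    stop("trace has fewer than ", window, " iterations")
  tr <- utils::tail(trace, window)
  pars <- setdiff(names(tr), c("iter", "isample", "ofv", "stage"))
  B <- length(pars)
  x <- seq_len(window)
  res <- lapply(pars, function(pn) {
    yv <- tr[[pn]]
    if (stats::sd(yv) == 0) return(c(slope = 0, p = 1))
    f <- stats::lm(yv ~ x)
    sm <- summary(f)$coefficients
    se <- sm["x", "Std. Error"]
    if (!is.finite(se) || se == 0) {
      pval <- if (abs(sm["x", "Estimate"]) > 0) 0 else 1
    } else pval <- sm["x", "Pr(>|t|)"]
    c(slope = unname(sm["x", "Estimate"]), p = pval)
  })
  out <- data.frame(parameter = pars,
                    slope = vapply(res, `[[`, 0, "slope"),
                    p_value = vapply(res, `[[`, 0, "p"),
                    converged = vapply(res, `[[`, 0, "p") >= alpha / B,
                    row.names = NULL)
  attr(out, "converged") <- all(out$converged)
  attr(out, "level") <- alpha / B
  out
}

#' Compare two fitted models
#'
#' Nested fits (same structure, one link set containing the other) are
#' compared by a likelihood-ratio test on the difference in objective
#' function values against a chi-square threshold at level 0.001 per
#' degree of freedom (10.83 for one df, matching the stringent criterion
#' used with Monte-Carlo noisy objective functions); non-nested fits by
#' AIC.
#'
#' @param fit_a,fit_b `"psa_fit"` objects fitted to the same cohort.
#' @param alpha LRT significance level (default 0.001).
#' @return a list of class `"psa_model_comparison"`.
#' @export
compare_models <- function(fit_a, fit_b, alpha = 0.001) {
  if (!identical(fit_a$signature, fit_b$signature))
    stop("fits are not on the same cohort")
  la <- names(fit_a$model$links); lb <- names(fit_b$model$links)
  nested <- fit_a$model$structure == fit_b$model$structure &&
    (all(la %in% lb) || all(lb %in% la)) && fit_a$npar != fit_b$npar
  if (nested) {
    full_is <- if (fit_a$npar > fit_b$npar) "a" else "b"
    full <- if (full_is == "a") fit_a else fit_b
    red <- if (full_is == "a") fit_b else fit_a
    df <- full$npar - red$npar
    delta <- red$ofv - full$ofv
    thr <- stats::qchisq(1 - alpha, df)
    winner <- if (delta > thr) "full" else "reduced"
    out <- list(method = "LRT", delta_ofv = delta, df = df, threshold = thr,
                winner = winner, full_is = full_is, alpha = alpha,
                aic = c(a = fit_a$aic, b = fit_b$aic))
  } else {
    winner <- if (fit_a$aic <= fit_b$aic) "a" else "b"
    out <- list(method = "AIC", aic = c(a = fit_a$aic, b = fit_b$aic),
                delta_aic = fit_a$aic - fit_b$aic, winner = winner)
  }
  class(out) <- "psa_model_comparison"
  out
}

#' @export
print.psa_model_comparison <- function(x, ...) {
  if (x$method == "LRT") {
    cat(sprintf("LRT: delta OFV = %.3f on %d df (threshold %.2f) -> keep %s model\n",
                x$delta_ofv, x$df, x$threshold, x$winner))
  } else {
    cat(sprintf("AIC: a = %.3f, b = %.3f -> model %s preferred\n",
                x$aic["a"], x$aic["b"], x$winner))
  }
  invisible(x)
}

#' Covariance of the fixed effects
#'
#' Central-finite-difference Hessian of the importance-sampled -2 log
#' marginal likelihood at the estimates, with common random numbers
#' across perturbations (the Monte-Carlo noise is frozen, so the
#' differenced surface is smooth).  The covariance is twice the inverse
#' Hessian of the objective function; a non-positive-definite Hessian
#' triggers a warning and an eigenvalue pseudo-inverse.
#'
#' @param object a `"psa_fit"`, or a [psa_model()] evaluated at the
#'   values of interest (then `cohort` is required).
#' @param cohort cohort for a model-object call.
#' @param isample Monte-Carlo draws per likelihood evaluation.
#' @param seed seed for the common random numbers.
#' @param free names of fixed-effect components to include (default: all
#'   not fixed during fitting).
#' @param h finite-difference steps (default `max(0.01 |b|, 0.005)`).
#' @return list with `cov`, `se`, `pct_cv` (100 SE/estimate on the
#'   natural scale) and `positive_definite`.
#' @export
estimate_covariance <- function(object, cohort = NULL, isample = 1000,
                                seed = 101, free = NULL, h = NULL) {
  if (inherits(object, "psa_fit")) {
    dat <- object$dat
    beta <- object$beta; omega <- object$omega; sigma <- object$sigma
    if (is.null(free)) free <- setdiff(names(beta), object$control$fix)
    chunk <- object$control$chunk_limit
    pm <- object$prop_mean; pv <- object$prop_var
  } else if (inherits(object, "psa_model")) {
    if (is.null(cohort)) stop("a cohort is required with a model object")
    dat <- .prep_fit_data(cohort, object)
    beta <- .model_beta(object); omega <- object$omega; sigma <- object$sigma
    if (is.null(free)) free <- names(beta)
    chunk <- 4e6
    pm <- NULL; pv <- NULL
  } else stop("object must be a psa_fit or psa_model")
  ds <- as.integer(seed) %% 2147483629L
  f <- function(b) {
    bb <- beta; bb[free] <- b
    .mc_pass(dat, bb, omega, sigma, isample, draw_seed = ds,
             want_moments = FALSE, prop_mean = pm, prop_var = pv,
             chunk_limit = chunk)$ofv
  }
  b0 <- beta[free]
  k <- length(b0)
  if (is.null(h)) h <- pmax(0.01 * abs(b0), 0.005)
  H <- matrix(NA_real_, k, k, dimnames = list(free, free))
  f0 <- f(b0)
  for (i in seq_len(k)) {
    ei <- replace(numeric(k), i, h[i])
    H[i, i] <- (f(b0 + ei) - 2 * f0 + f(b0 - ei)) / h[i]^2
    if (i > 1) for (j in seq_len(i - 1)) {
      ej <- replace(numeric(k), j, h[j])
      H[i, j] <- H[j, i] <-
        (f(b0 + ei + ej) - f(b0 + ei - ej) - f(b0 - ei + ej) +
           f(b0 - ei - ej)) / (4 * h[i] * h[j])
    }
  }
  H <- (H + t(H)) / 2
  ev <- eigen(H, symmetric = TRUE)
  pd <- all(ev$values > 1e-10 * max(abs(ev$values)))
  if (pd) {
    cov <- 2 * chol2inv(chol(H))
  } else {
    warning("Hessian of the objective function is not positive definite; ",
            "using a pseudo-inverse")
    pos <- ev$values > 1e-10 * max(abs(ev$values))
    cov <- 2 * ev$vectors[, pos, drop = FALSE] %*%
      diag(1 / ev$values[pos], sum(pos)) %*%
      t(ev$vectors[, pos, drop = FALSE])
  }
  dimnames(cov) <- list(free, free)
  se <- sqrt(pmax(diag(cov), 0))
  # intercept components live on the log scale: SE(log theta) is already
  # the natural-scale coefficient of variation (delta method)
  is_icpt <- free %in% dat$params
  pct_cv <- ifelse(is_icpt, 100 * se, 100 * se / abs(b0))
  list(cov = cov, se = stats::setNames(se, free),
       pct_cv = stats::setNames(pct_cv, free), positive_definite = pd)
}
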