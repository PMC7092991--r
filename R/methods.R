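# S3 methods for "psa_fit" objects.

#' @export
print.psa_fit <- function(x, ...) {
  cat("Population PSA kinetics fit (", x$model$structure,
      " model, MCPEM)\n", sep = "")
  cat("  subjects:", x$dat$m, " observations:", x$dat$n_obs,
      "(excluding baseline anchors)\n")
  cat(sprintf("  OFV %.3f (MC SE %.2f), AIC %.3f, %d parameters\n",
              x$ofv, x$ofv_mc_se, x$aic, x$npar))
  if (!is.na(x$converged))
    cat("  converged:", x$converged, "\n")
  print(coef(x))
  invisible(x)
}

#' @export
coef.psa_fit <- function(object, ...) {
  b <- object$beta
  icpt <- names(b) %in% names(object$model$theta)
  out <- ifelse(icpt, exp(b), b)
  names(out) <- names(b)
  out
}

#' @export
vcov.psa_fit <- function(object, ...) object$vcov

#' @export
logLik.psa_fit <- function(object, ...) {
  structure(-object$ofv / 2, df = object$npar, class = "logLik")
}

#' Summarise a population PSA kinetics fit
#'
#' Prints an estimates table in the conventional population-model
#' layout: structural typical values, inter-individual variances,
#' covariate coefficients and residual error, each with its %CV when
#' the fixed-effect covariance was estimated.
#'
#' @param object a `"psa_fit"`.
#' @param ... unused.
#' @return a data.frame of estimates (invisibly classed for printing).
#' @export
summary.psa_fit <- function(object, ...) {
  b <- object$beta
  icpt <- names(b) %in% names(object$model$theta)
  est <- ifelse(icpt, exp(b), b)
  cv <- rep(NA_real_, length(b))
  if (!is.null(object$pct_cv))
    cv[match(names(object$pct_cv), names(b))] <- object$pct_cv
  tab <- data.frame(
    parameter = c(names(b), paste0("omega2_", names(object$omega)), "sigma_add"),
    block = c(ifelse(icpt, "structural", "covariate")[seq_along(b)],
              rep("IIV", length(object$omega)), "residual"),
    estimate = c(est, unname(object$omega), object$sigma),
    pct_cv = c(cv, rep(NA_real_, length(object$omega) + 1)),
    row.names = NULL)
  structure(list(table = tab, ofv = object$ofv, aic = object$aic,
                 npar = object$npar, converged = object$converged,
                 ofv_mc_se = object$ofv_mc_se),
            class = "summary.psa_fit")
}

#' @export
print.summary.psa_fit <- function(x, ...) {
  cat(sprintf("OFV %.3f (MC SE %.2f)   AIC %.3f   parameters %d\n",
              x$ofv, x$ofv_mc_se, x$aic, x$npar))
  tab <- x$table
  tab$estimate <- signif(tab$estimate, 4)
  tab$pct_cv <- signif(tab$pct_cv, 3)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Predicted PSA trajectories from a fit
#'
#' @param object a `"psa_fit"`.
#' @param id subject ids (default: all fitted subjects).
#' @param times prediction grid; default each subject's observation
#'   times.
#' @param type `"individual"` (empirical-Bayes conditional-mean
#'   parameters) or `"typical"` (covariate-adjusted population
#'   parameters).
#' @param ... unused.
#' @return data.frame with `ID`, `t` and the predicted components.
#' @export
predict.psa_fit <- function(object, id = NULL, times = NULL,
                            type = c("individual", "typical"), ...) {
  type <- match.arg(type)
  dat <- object$dat
  ids <- id %||% dat$ids
  out <- lapply(ids, function(one) {
    i <- match(one, dat$ids)
    if (is.na(i)) stop("unknown subject id: ", one)
    s <- object$cohort$subjects[[i]]
    tt <- times %||% s$time
    phi <- if (type == "individual") object$cond_mean[i, ] else
      vapply(dat$params, function(p)
        drop(dat$X[[p]][i, ] %*% object$beta[colnames(dat$X[[p]])]), 0)
    p <- exp(phi)
    pr <- if (dat$structure == "clonal")
      predict_psa_clonal(p, dat$bas[i], tt, dat$t1[i])
    else predict_psa_adaptation(p, dat$bas[i], tt, dat$t1[i])
    cbind(ID = one, pr)
  })
  do.call(rbind, out)
}

#' Individual weighted residuals
#'
#' `(log DV - log IPRED) / sigma` at the conditional-mean parameters,
#' for uncensored non-anchor observations.
#'
#' @param object a `"psa_fit"`.
#' @param ... unused.
#' @return data.frame with `ID`, `t`, `iwres`.
#' @export
residuals.psa_fit <- function(object, ...) {
  dat <- object$dat
  keep <- !dat$blq
  ipred <- numeric(dat$n_obs)
  for (i in seq_len(dat$m)) {
    oi <- which(dat$sub == i)
    if (!length(oi)) next
    ipred[oi] <- .subject_logpred(object$model,
                                  object$cond_mean[i, , drop = FALSE],
                                  dat$bas[i], dat$t[oi], dat$t1[i])[1, ]
  }
  data.frame(ID = dat$ids[dat$sub[keep]], t = dat$t[keep],
             iwres = (dat$y[keep] - ipred[keep]) / object$sigma)
}

#' Plot observed and fitted PSA profiles
#'
#' @param x a `"psa_fit"`.
#' @param id subject ids to draw (default: the first up to 9).
#' @param log_scale plot PSA on the log axis.
#' @param ... forwarded to [graphics::plot()].
#' @export
plot.psa_fit <- function(x, id = NULL, log_scale = TRUE, ...) {
  dat <- x$dat
  ids <- id %||% utils::head(dat$ids, 9)
  old <- graphics::par(mfrow = grDevices::n2mfrow(length(ids)),
                       mar = c(4, 4, 2, 1))
  on.exit(graphics::par(old))
  for (one in ids) {
    i <- match(one, dat$ids)
    s <- x$cohort$subjects[[i]]
    tt <- seq(0, max(s$time), length.out = 100)
    pr <- predict(x, id = one, times = tt)
    graphics::plot(s$time, s$dv, log = if (log_scale) "y" else "",
                   xlab = "day", ylab = "PSA (ng/mL)", main = one,
                   pch = ifelse(s$blq, 1, 16), ...)
    graphics::lines(pr$t, pr$psa_total)
    graphics::abline(v = s$t1, lty = 3)
    graphics::abline(h = x$model$lloq, lty = 3, col = "grey50")
  }
  invisible(x)
}

#' Simulate replicate cohorts from a fit
#'
#' Replicates are drawn on the observed designs (times, treatment
#' starts, covariates) with fresh random effects, residual error and
#' LLOQ censoring -- the plumbing behind [predictive_check()].
#'
#' @param object a `"psa_fit"`.
#' @param nsim number of replicate cohorts.
#' @param seed RNG seed.
#' @param ... unused.
#' @return list of [psa_cohort()] objects.
#' @export
simulate.psa_fit <- function(object, nsim = 1, seed = 1, ...) {
  model <- object$model
  dat <- object$dat
  pn <- dat$params
  typ <- typical_params(model, dat$cov)
  with_seed(seed, {
    lapply(seq_len(nsim), function(r) {
      eta <- sweep(matrix(stats::rnorm(dat$m * length(pn)), dat$m), 2,
                   sqrt(model$omega), "*")
      subs <- lapply(seq_len(dat$m), function(i) {
        s <- object$cohort$subjects[[i]]
        phi <- log(typ[i, ]) + eta[i, ]
        lp <- .subject_logpred(model, matrix(phi, 1,
                                             dimnames = list(NULL, pn)),
                               dat$bas[i], s$time, s$t1)[1, ]
        noise <- stats::rnorm(length(s$time), 0, model$sigma)
        noise[s$time == 0] <- 0
        dv <- exp(lp + noise)
        blq <- dv < dat$lloq
        dv[blq] <- dat$lloq
        psa_subject(s$id, s$time, dv, blq, s$t1, s$cov, validate = FALSE)
      })
      psa_cohort(subs, lloq = dat$lloq)
    })
  })
}
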