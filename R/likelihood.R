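#' @title Observation and subject likelihood with BLQ censoring
#' @name likelihood
#' @description
#' Residual error is additive on log concentration: for an uncensored
#' observation the log-likelihood is the Gaussian density of
#' `log(value)` at the model's log prediction with SD `sigma`.  PSA
#' values below the lower limit of quantification are fixed-point
#' censored: their likelihood is the probability that the observation is
#' truly below the limit, `pnorm((log(lloq) - pred_log)/sigma)` (the M3
#' method).
NULL

#' Log-likelihood of a single PSA observation
#'
#' @param pred_log model-predicted log concentration.
#' @param value observed PSA, ng/mL (ignored when `blq` is `TRUE`).
#' @param blq logical; observation below the limit of quantification.
#' @param sigma additive error SD on the log scale.
#' @param lloq lower limit of quantification, ng/mL.
#' @return log-likelihood, vectorised over observations.
#' @export
observation_loglik <- function(pred_log, value, blq = FALSE, sigma, lloq = 0.1) {
  if (sigma <= 0) stop("sigma must be positive")
  n <- max(length(pred_log), length(value), length(blq))
  pred_log <- rep_len(pred_log, n)
  value <- rep_len(value, n)
  blq <- rep_len(as.logical(blq), n)
  out <- numeric(n)
  if (any(!blq))
    out[!blq] <- stats::dnorm(log(value[!blq]), pred_log[!blq], sigma, log = TRUE)
  if (any(blq))
    out[blq] <- stats::pnorm((log(lloq) - pred_log[blq]) / sigma, log.p = TRUE)
  out
}

# Log predictions for one subject at a matrix of log-parameters `phi`
# (draws x parameters).  Returns a draws x n_obs matrix, computed in log
# space throughout so extreme random effects cannot underflow.
.subject_logpred <- function(model, phi, bas, time, t1) {
  ts <- pmin(time, t1)
  tk <- pmax(0, time - t1)
  lbas <- log(bas)
  if (model$structure == "clonal") {
    RP <- exp(phi[, "RP", drop = TRUE])
    GR <- exp(phi[, "GR", drop = TRUE])
    GS <- exp(phi[, "GS", drop = TRUE])
    DS <- exp(phi[, "DS", drop = TRUE])
    logres <- sweep(outer(GR, time), 1, RP, "-") + lbas
    logsen <- outer(GS, ts) - outer(DS, tk) + log1p(-exp(-RP)) + lbas
    hi <- pmax(logres, logsen)
    hi + log1p(exp(pmin(logres, logsen) - hi))
  } else {
    D <- exp(phi[, "D", drop = TRUE])
    G <- exp(phi[, "G", drop = TRUE])
    Gtk <- outer(G, tk)
    br <- exp(-outer(D, tk)) + expm1(Gtk)
    logbr <- ifelse(Gtk > 30, Gtk, log(br))
    outer(G, ts) + logbr + lbas
  }
}

#' Joint log-likelihood of one subject's observations
#'
#' Individual parameters are
#' `individual_params(typical_params(model, cov), eta)`; the prediction
#' at each observation time is scored with [observation_loglik()].
#'
#' @param model a [psa_model()].
#' @param subject a [psa_subject()]; its baseline observation (day 0)
#'   supplies `BAS`.
#' @param eta vector of random effects (one per structural parameter,
#'   model order), or a draws x parameters matrix for vectorised
#'   evaluation.
#' @return scalar log-likelihood (or a vector, one per draw).
#' @export
subject_loglik <- function(model, subject, eta = NULL) {
  pn <- names(model$theta)
  if (is.null(eta)) eta <- stats::setNames(numeric(length(pn)), pn)
  if (is.null(dim(eta))) eta <- matrix(eta, 1, length(pn))
  if (ncol(eta) != length(pn)) stop("eta dimension must match the model")
  colnames(eta) <- pn                    # columns follow the model order
  if (length(subject$time) == 0) return(numeric(nrow(eta)))
  cov <- .subject_cov(subject)
  typ <- typical_params(model, cov)
  phi <- sweep(eta, 2, log(drop(typ)), "+")
  bas <- subject$dv[.baseline_idx(subject)]
  lp <- .subject_logpred(model, phi, bas, subject$time, subject$t1)
  ll <- matrix(0, nrow(lp), ncol(lp))
  for (j in seq_along(subject$time)) {
    ll[, j] <- observation_loglik(lp[, j], subject$dv[j], subject$blq[j],
                                  model$sigma, model$lloq)
  }
  drop(rowSums(ll))
}

# Covariates of a subject as a one-row data.frame, with BAS defaulting to
# the baseline observation when not recorded explicitly.
.subject_cov <- function(subject) {
  cv <- subject$cov
  if (is.null(cv[["BAS"]]) || is.na(cv[["BAS"]]))
    cv[["BAS"]] <- subject$dv[.baseline_idx(subject)]
  as.data.frame(cv[!vapply(cv, is.null, TRUE)], stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# Flattened cohort representation used by the estimation engine.
#
# The baseline observation anchors the trajectory (BAS is a data item, not
# an estimated parameter), so its residual is identically zero; it is
# removed from the likelihood and from the residual-variance update.
.prep_fit_data <- function(cohort, model) {
  subs <- cohort$subjects
  m <- length(subs)
  if (m == 0) stop("empty cohort")
  bas <- vapply(subs, function(s) s$dv[.baseline_idx(s)], 0)
  bl_blq <- vapply(subs, function(s) s$blq[.baseline_idx(s)], TRUE)
  if (any(bl_blq))
    stop("baseline PSA below LLOQ for subject(s) ",
         paste(names(subs)[bl_blq], collapse = ", "),
         "; apply the exclusion filters first")
  cov <- do.call(rbind, lapply(subs, function(s) .subject_cov(s)[1,
    intersect(names(.subject_cov(s)), .cov_names), drop = FALSE]))
  if (!"BAS" %in% names(cov)) cov$BAS <- bas
  rownames(cov) <- NULL

  sub <- integer(0); tt <- numeric(0); y <- numeric(0); blq <- logical(0)
  for (i in seq_len(m)) {
    s <- subs[[i]]
    keep <- seq_along(s$time)[-.baseline_idx(s)]
    sub <- c(sub, rep.int(i, length(keep)))
    tt <- c(tt, s$time[keep]); y <- c(y, log(s$dv[keep]))
    blq <- c(blq, s$blq[keep])
  }
  t1 <- vapply(subs, function(s) s$t1, 0)
  list(m = m, ids = names(subs), params = names(model$theta),
       structure = model$structure, lloq = cohort$lloq,
       X = .design_matrices(model, cov), cov = cov,
       bas = unname(bas), lbas = unname(log(bas)), t1 = unname(t1),
       sub = sub, t = tt, y = y, blq = blq,
       ts = pmin(tt, t1[sub]), tk = pmax(0, tt - t1[sub]),
       n_obs = length(tt),
       signature = c(m = m, n_obs = length(tt),
                     y_sum = round(sum(y), 6)))
}

# One Monte-Carlo pass over the cohort: importance-sampled conditional
# moments (E step), per-subject log marginal likelihood, and the
# accumulator for the residual-variance update.  Draws come from a
# diagonal-normal proposal per subject -- the population density itself
# when `prop_mean`/`prop_var` are NULL, otherwise a posterior-centred
# proposal (previous conditional mean, inflated conditional variance)
# with proper importance weights l_i(phi) h(phi) / q(phi).  Posterior
# re-centring is what keeps the effective sample size usable when the
# inter-individual variances are large relative to the residual error.
# `draw_seed` makes the pass reproducible; identical seeds give common
# random numbers across calls (used by the finite-difference
# covariance).  Work is chunked over subjects so memory stays bounded
# for large isample.
.mc_pass <- function(dat, beta, omega, sigma, isample, draw_seed,
                     want_moments = TRUE, want_sigma = FALSE,
                     prop_mean = NULL, prop_var = NULL,
                     chunk_limit = 4e6) {
  m <- dat$m; p <- length(dat$params); N <- isample
  sq_om <- sqrt(pmax(omega, 0))
  mu <- vapply(dat$params, function(pp)
    drop(dat$X[[pp]] %*% beta[colnames(dat$X[[pp]])]), numeric(m))
  if (m == 1) mu <- matrix(mu, 1, p, dimnames = list(NULL, dat$params))

  nobs_i <- tabulate(dat$sub, m)
  # contiguous subject chunks with N * (obs + p) elements under the cap
  loads <- N * (nobs_i + p)
  grp <- integer(m); g <- 1L; acc <- 0
  for (i in seq_len(m)) {
    if (acc + loads[i] > chunk_limit && acc > 0) { g <- g + 1L; acc <- 0 }
    grp[i] <- g; acc <- acc + loads[i]
  }

  logmarg <- numeric(m)
  ess <- numeric(m)
  thetabar <- if (want_moments) matrix(0, m, p,
                                       dimnames = list(NULL, dat$params))
  Bdiag <- if (want_moments) matrix(0, m, p,
                                    dimnames = list(NULL, dat$params))
  sig_ss <- 0
  loglloq <- log(dat$lloq)

  for (cix in seq_len(max(grp))) {
    S <- which(grp == cix); mS <- length(S)
    set.seed((draw_seed + 7919L * cix) %% 2147483629L)
    Zc <- matrix(stats::rnorm(mS * N * p), mS * N, p)
    mu_rep <- mu[rep(S, each = N), , drop = FALSE]
    if (is.null(prop_mean)) {
      phi <- sweep(Zc, 2, sq_om, "*") + mu_rep
      lratio <- NULL          # proposal == population density
    } else {
      qm <- prop_mean[rep(S, each = N), , drop = FALSE]
      qs <- sqrt(prop_var[rep(S, each = N), , drop = FALSE])
      phi <- Zc * qs + qm
      lr <- 0
      for (j in seq_len(p)) {
        if (sq_om[j] <= 0) next        # degenerate dimension: phi == mu
        lr <- lr + stats::dnorm(phi[, j], mu_rep[, j], sq_om[j], log = TRUE) -
          stats::dnorm(phi[, j], qm[, j], qs[, j], log = TRUE)
      }
      lratio <- matrix(lr, N, mS)
    }
    oi <- which(dat$sub %in% S)
    nobsC <- length(oi)
    if (nobsC > 0) {
      li <- match(dat$sub[oi], S)
      IDX <- rep((li - 1L) * N, each = N) + seq_len(N)
      t_o <- dat$t[oi]; ts_o <- dat$ts[oi]; tk_o <- dat$tk[oi]
      lbas_o <- dat$lbas[dat$sub[oi]]
      if (dat$structure == "clonal") {
        DSm <- matrix(exp(phi[IDX, 1L]), N, nobsC)
        GSm <- matrix(exp(phi[IDX, 2L]), N, nobsC)
        RPm <- matrix(exp(phi[IDX, 3L]), N, nobsC)
        GRm <- matrix(exp(phi[IDX, 4L]), N, nobsC)
        logres <- sweep(sweep(GRm, 2, t_o, "*") - RPm, 2, lbas_o, "+")
        logsen <- sweep(sweep(GSm, 2, ts_o, "*") - sweep(DSm, 2, tk_o, "*") +
                          log1p(-exp(-RPm)), 2, lbas_o, "+")
        hi <- pmax(logres, logsen)
        LP <- hi + log1p(exp(pmin(logres, logsen) - hi))
      } else {
        Dm <- matrix(exp(phi[IDX, 1L]), N, nobsC)
        Gm <- matrix(exp(phi[IDX, 2L]), N, nobsC)
        Gtk <- sweep(Gm, 2, tk_o, "*")
        br <- exp(-sweep(Dm, 2, tk_o, "*")) + expm1(Gtk)
        logbr <- ifelse(Gtk > 30, Gtk, log(br))
        LP <- sweep(sweep(Gm, 2, ts_o, "*") + logbr, 2, lbas_o, "+")
      }
      E <- sweep(LP, 2, dat$y[oi], "-")      # pred - obs, log scale
      LL <- -log(sigma) - 0.918938533204673 - 0.5 * (E / sigma)^2
      bl <- dat$blq[oi]
      if (any(bl)) {
        A <- (loglloq - LP[, bl, drop = FALSE]) / sigma
        LL[, bl] <- stats::pnorm(A, log.p = TRUE)
      }
      gr <- rowsum(t(LL), li)
      ll_sd <- matrix(0, N, mS)
      ll_sd[, as.integer(rownames(gr))] <- t(gr)
    } else {
      ll_sd <- matrix(0, N, mS)
    }
    if (!is.null(lratio)) ll_sd <- ll_sd + lratio
    mx <- apply(ll_sd, 2, max)
    if (any(!is.finite(mx)))
      stop("all importance weights underflowed for subject(s) ",
           paste(dat$ids[S[!is.finite(mx)]], collapse = ", "),
           "; increase isample or improve starting values")
    Wu <- exp(sweep(ll_sd, 2, mx, "-"))
    sw <- colSums(Wu)
    W <- sweep(Wu, 2, sw, "/")
    logmarg[S] <- mx + log(sw) - log(N)
    ess[S] <- 1 / colSums(W^2)
    if (want_moments) {
      for (j in seq_len(p)) {
        PH <- matrix(phi[, j], N, mS)
        tb <- colSums(W * PH)
        thetabar[S, j] <- tb
        Bdiag[S, j] <- pmax(colSums(W * PH * PH) - tb^2, 0)
      }
    }
    if (want_sigma && nobsC > 0) {
      e2 <- E^2
      if (any(bl)) {
        A <- (loglloq - LP[, bl, drop = FALSE]) / sigma
        r <- exp(stats::dnorm(A, log = TRUE) - stats::pnorm(A, log.p = TRUE))
        e2[, bl] <- sigma^2 * (1 - A * r)
      }
      sig_ss <- sig_ss + sum(W[, li, drop = FALSE] * e2)
    }
  }
  list(logmarg = logmarg, ofv = -2 * sum(logmarg), thetabar = thetabar,
       Bdiag = Bdiag, sig_ss = sig_ss, ess = ess,
       ofv_mc_se = 2 * sqrt(sum(pmax(1 / ess - 1 / N, 0))))
}
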