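#' @title Covariate selection by Wald approximation with backward elimination
#' @name wam
#' @description
#' Screening all covariate-parameter relationships by refitting is
#' infeasible (with 11 covariates on 4 parameters there are 2^44
#' submodels), so candidate coefficients are screened from a *single*
#' full-model fit: the Wald approximation to the likelihood-ratio
#' statistic for restricting a coefficient subvector
#' \eqn{\theta_2} to zero is \eqn{\Lambda' = \theta_2' C_{22}^{-1}
#' \theta_2}, with \eqn{C_{22}} the corresponding block of the
#' full-model fixed-effect covariance.  Backward elimination removes the
#' candidate whose conditional \eqn{\Lambda'} increment is smallest
#' until every survivor exceeds the threshold (10.83 per df, i.e. p <
#' 0.001); the surviving set is then confirmed by actual refits.
NULL

#' Add candidate covariate links to a base model
#'
#' Each candidate becomes one coefficient initialised at zero (no
#' effect).  Continuous candidates are normalised by the cohort median,
#' frozen into the link so later predictions are reproducible.
#'
#' @param base a [psa_model()].
#' @param candidates data.frame with columns `parameter`, `covariate` and
#'   `kind` (`"power"`/`"indicator"`), or a list of [cov_link()]s.
#' @param cohort cohort whose covariate medians set the power-link
#'   references.
#' @return the full [psa_model()] with all candidate links at zero.
#' @export
build_full_model <- function(base, candidates, cohort = NULL) {
  if (length(candidates) == 0) return(base)
  if (is.data.frame(candidates)) {
    candidates <- lapply(seq_len(nrow(candidates)), function(i) {
      k <- candidates$kind[i]
      ref <- NULL
      if (k == "power") {
        if (is.null(cohort))
          stop("a cohort is needed to set power-link reference medians")
        vals <- vapply(cohort$subjects,
                       function(s) .subject_cov(s)[[candidates$covariate[i]]] %||% NA_real_,
                       0)
        ref <- stats::median(vals, na.rm = TRUE)
      }
      cov_link(candidates$parameter[i], candidates$covariate[i], k,
               ref = ref, theta = 0)
    })
  }
  nms <- vapply(candidates, function(l) l$name, "")
  if (anyDuplicated(c(names(base$links), nms)))
    stop("duplicate covariate candidate")
  base$links <- c(base$links, stats::setNames(candidates, nms))
  base
}

#' Wald approximation to the likelihood-ratio statistic
#'
#' @param theta2 coefficient subvector restricted to zero under the
#'   hypothesised submodel.
#' @param C full fixed-effect covariance matrix.
#' @param idx index (positions or names) of `theta2` within `C`.
#' @return the quadratic form \eqn{\theta_2' C_{22}^{-1} \theta_2}.
#' @export
wald_statistic <- function(theta2, C, idx = seq_along(theta2)) {
  if (length(theta2) == 0) return(0)
  C22 <- C[idx, idx, drop = FALSE]
  if (!all(is.finite(C22))) stop("covariance block contains non-finite values")
  ch <- tryCatch(chol(C22), error = function(e)
    stop("C22 block is not positive definite"))
  drop(crossprod(backsolve(ch, theta2, transpose = TRUE)))
}

#' Screen covariate candidates by backward elimination on Wald statistics
#'
#' Starting from the full-model estimates and covariance, candidates are
#' removed greedily: at each step the candidate whose removal increases
#' the joint \eqn{\Lambda'} of the removed set the least is dropped,
#' provided that increment is below the threshold; conditional
#' statistics are re-partitioned from the same full-fit covariance (no
#' refitting).  Multi-coefficient candidates are tested jointly with a
#' chi-square threshold at their degrees of freedom.
#'
#' @param fit a `"psa_fit"` of the full model with covariance available.
#' @param candidates names of the candidate links to screen (default:
#'   all links of the fitted model).
#' @param threshold elimination threshold for one df (default 10.83,
#'   p < 0.001); multi-df candidates use the matching chi-square
#'   quantile.
#' @param groups optional named list collecting several link names into
#'   one jointly-tested candidate (e.g. indicator contrasts of one
#'   multi-level covariate).
#' @return a list of class `"wam_path"`: elimination `steps` (candidate,
#'   conditional \eqn{\Lambda'}, action), `surviving` link names,
#'   `eliminated` link names, and the per-candidate marginal statistics.
#' @export
wam_backward_eliminate <- function(fit, candidates = NULL, threshold = 10.83,
                                   groups = NULL) {
  if (is.null(fit$vcov)) stop("fit carries no fixed-effect covariance")
  theta <- fit$beta
  C <- fit$vcov
  if (is.null(candidates)) candidates <- names(fit$model$links)
  if (!all(candidates %in% rownames(C)))
    stop("candidate coefficients missing from the covariance: ",
         paste(setdiff(candidates, rownames(C)), collapse = ", "))
  cand <- stats::setNames(as.list(candidates), candidates)
  if (!is.null(groups)) {
    for (g in names(groups)) cand[groups[[g]]] <- NULL
    cand <- c(cand, groups)
  }
  alpha1 <- stats::pchisq(threshold, 1, lower.tail = FALSE)
  thr_for <- function(df) if (df == 1) threshold else
    stats::qchisq(1 - alpha1, df)

  marginal <- vapply(cand, function(ix) wald_statistic(theta[ix], C, ix), 0)
  removed <- character(0)      # link names already restricted to zero
  remaining <- names(cand)
  steps <- list()
  lam_removed <- 0
  repeat {
    if (!length(remaining)) break
    inc <- vapply(remaining, function(g) {
      ix <- c(removed, unlist(cand[[g]], use.names = FALSE))
      wald_statistic(theta[ix], C, ix) - lam_removed
    }, 0)
    dfs <- vapply(remaining, function(g) length(cand[[g]]), 0L)
    # compare each increment to its df-specific threshold
    below <- inc < vapply(dfs, thr_for, 0)
    if (!any(below)) break
    drop_g <- remaining[below][which.min(inc[below])]
    removed <- c(removed, unlist(cand[[drop_g]], use.names = FALSE))
    lam_removed <- wald_statistic(theta[removed], C, removed)
    steps[[length(steps) + 1L]] <-
      data.frame(candidate = drop_g, lambda_prime = unname(inc[drop_g]),
                 df = length(cand[[drop_g]]), action = "eliminate")
    remaining <- setdiff(remaining, drop_g)
  }
  for (g in remaining) {
    ix <- c(removed, unlist(cand[[g]], use.names = FALSE))
    steps[[length(steps) + 1L]] <-
      data.frame(candidate = g,
                 lambda_prime = wald_statistic(theta[ix], C, ix) - lam_removed,
                 df = length(cand[[g]]), action = "retain")
  }
  structure(list(
    steps = do.call(rbind, steps),
    surviving = unlist(cand[remaining], use.names = FALSE),
    eliminated = removed,
    marginal = marginal, threshold = threshold), class = "wam_path")
}

#' @export
print.wam_path <- function(x, ...) {
  cat("WAM backward elimination (threshold", x$threshold, "per df)\n")
  print(x$steps, row.names = FALSE)
  cat("surviving:", if (length(x$surviving))
    paste(x$surviving, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Confirm surviving covariates by actual refits
#'
#' For each covariate link surviving the Wald screen, the model is refit
#' without it; the link is dropped when the objective-function increase
#' is below 10.83 (one df, p < 0.001).  The process repeats from the
#' reduced model until no link can be dropped.  A refit that fails is
#' recorded and the candidate retained conservatively.
#'
#' @param start a [psa_model()] containing the links to confirm (e.g.
#'   the WAM survivors), with starting values for refitting.
#' @param cohort the fitted cohort.
#' @param control an [mcpem_control()] for the refits (covariance is not
#'   needed; disable it for speed).
#' @param links names of the links subject to confirmation (default all).
#' @param threshold OFV difference threshold per df.
#' @param seed seed forwarded to every refit so objective functions share
#'   their Monte-Carlo noise.
#' @return list of class `"psa_confirmatory_be"`: `model` (final), `fit`
#'   (final fit) and `log` (per-step candidate, delta OFV, action).
#' @export
confirmatory_backward_elimination <- function(start, cohort,
                                              control = mcpem_control(vcov = FALSE),
                                              links = NULL,
                                              threshold = 10.83, seed = 1) {
  current <- start
  testable <- links %||% names(start$links)
  log <- list()
  fit_cur <- fit_psa_model(cohort, current, control, seed = seed)
  repeat {
    if (!length(testable)) break
    best <- NULL
    for (nm in testable) {
      red <- current
      red$links[[nm]] <- NULL
      red_fit <- tryCatch(fit_psa_model(cohort, red, control, seed = seed),
                          error = function(e) e)
      if (inherits(red_fit, "error")) {
        log[[length(log) + 1L]] <- data.frame(
          candidate = nm, delta_ofv = NA_real_, action = "refit-failed")
        next
      }
      d <- red_fit$ofv - fit_cur$ofv
      log[[length(log) + 1L]] <- data.frame(
        candidate = nm, delta_ofv = d, action = "tested")
      if (is.null(best) || d < best$d) best <- list(nm = nm, d = d,
                                                    fit = red_fit)
    }
    if (is.null(best) || best$d >= threshold) break
    log[[length(log) + 1L]] <- data.frame(
      candidate = best$nm, delta_ofv = best$d, action = "dropped")
    current$links[[best$nm]] <- NULL
    fit_cur <- best$fit
    testable <- setdiff(testable, best$nm)
  }
  structure(list(model = fit_cur$model, fit = fit_cur,
                 log = do.call(rbind, log)),
            class = "psa_confirmatory_be")
}

#' @export
print.psa_confirmatory_be <- function(x, ...) {
  cat("Confirmatory backward elimination\n")
  if (!is.null(x$log)) print(x$log, row.names = FALSE)
  cat("final links:", if (length(x$model$links))
    paste(names(x$model$links), collapse = ", ") else "(none)", "\n")
  invisible(x)
}
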