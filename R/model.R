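#' @title Structural PSA kinetics models
#' @name structural-models
#' @description
#' Two exponential tumour-kinetics models describe the PSA time course
#' under LHRH-agonist treatment, with PSA as a proxy for tumour burden
#' and `BAS` the subject's observed baseline PSA.
#'
#' **Adaptation model** (resistance acquired by initially sensitive
#' cells):
#' \deqn{PSA(t) = BAS\, e^{G t_s} (e^{-D t_k} + e^{G t_k} - 1)}
#'
#' **Clonal-selection model** (a pre-existing resistant subpopulation,
#' fraction \eqn{R = e^{-RP}} of the original tumour):
#' \deqn{PSA_R(t) = BAS\, R\, e^{G_R t},\qquad
#'       PSA_S(t) = BAS (1-R) e^{G_S t_s} e^{-D_S t_k}}
#'
#' with \eqn{t_s = \min(t, t_1)} the pre-treatment growth time and
#' \eqn{t_k = \max(0, t - t_1)} the time on treatment (\eqn{t_1} = day
#' of the first dose).  All rates are day\eqn{^{-1}}.
#'
#' Individual parameters are lognormal about the typical value,
#' \eqn{\theta_i = \theta_{typ} e^{\eta_i}}, \eqn{\eta_i \sim N(0,
#' \omega^2)}; continuous covariates enter as median-normalised power
#' terms and categorical covariates as exponentiated indicators, so the
#' whole covariate model is linear on the log-parameter scale.
NULL

.struct_params <- list(clonal = c("DS", "GS", "RP", "GR"),
                       adaptation = c("D", "G"))

#' Declare a covariate-parameter link
#'
#' @param parameter structural parameter the covariate acts on
#'   (`"DS"`, `"GS"`, `"RP"`, `"GR"`; or `"D"`, `"G"`).
#' @param covariate covariate column name (e.g. `"HGB"`, `"BAS"`, `"AND"`).
#' @param kind `"power"` for continuous covariates
#'   (\eqn{(x/\mathrm{ref})^\theta}) or `"indicator"` for 0/1 categorical
#'   covariates (\eqn{e^{x\theta}}).
#' @param ref reference value for a power link, normally the cohort
#'   median; required for `kind = "power"`.
#' @param theta coefficient value (default 0 = no effect).
#' @return an object of class `"cov_link"`.
#' @export
cov_link <- function(parameter, covariate, kind = c("power", "indicator"),
                     ref = NULL, theta = 0) {
  kind <- match.arg(kind)
  if (kind == "power") {
    if (is.null(ref)) stop("a power link needs a reference value")
    if (ref <= 0) stop("reference value must be positive")
  }
  structure(list(parameter = parameter, covariate = covariate, kind = kind,
                 ref = ref, theta = theta,
                 name = paste0(parameter, ":", covariate)),
            class = "cov_link")
}

#' Define a population PSA kinetics model
#'
#' @param structure `"clonal"` (two subpopulations, the default) or
#'   `"adaptation"` (single population with decaying drug effect).
#' @param theta named vector of typical values, natural scale:
#'   `c(DS=, GS=, RP=, GR=)` or `c(D=, G=)`.
#' @param omega named vector of inter-individual variances (\eqn{\omega^2})
#'   for the same parameters; a parameter missing from `omega` gets 0
#'   (no variability).
#' @param sigma SD of the additive residual error on log PSA.
#' @param links list of [cov_link()] covariate-parameter relationships.
#' @param lloq lower limit of quantification, ng/mL.
#' @return an object of class `"psa_model"`.
#' @export
psa_model <- function(structure = c("clonal", "adaptation"),
                      theta, omega = NULL, sigma = 0.2, links = list(),
                      lloq = 0.1) {
  structure_ <- match.arg(structure)
  pn <- .struct_params[[structure_]]
  if (!all(pn %in% names(theta)))
    stop("theta must name all of: ", paste(pn, collapse = ", "))
  theta <- theta[pn]
  if (any(theta <= 0)) stop("typical values must be positive")
  om <- stats::setNames(numeric(length(pn)), pn)
  if (!is.null(omega)) om[names(omega)] <- omega
  if (any(om < 0)) stop("omega entries must be non-negative")
  if (sigma <= 0) stop("sigma must be positive")
  for (l in links) {
    if (!inherits(l, "cov_link")) stop("links must be cov_link objects")
    if (!(l$parameter %in% pn))
      stop("link on unknown parameter: ", l$parameter)
  }
  nms <- vapply(links, function(l) l$name, "")
  if (anyDuplicated(nms)) stop("duplicate covariate link: ",
                               nms[duplicated(nms)][1])
  names(links) <- nms
  structure(list(structure = structure_, theta = theta, omega = om,
                 sigma = sigma, links = links, lloq = lloq),
            class = "psa_model")
}

#' The published final covariate model
#'
#' Convenience constructor carrying the reported population estimates of
#' the final clonal-selection model: kill rate of sensitive cells
#' `DS = 3.78e-2 / day` (modified by baseline PSA, reference 8.5 ng/mL,
#' exponent 0.174, and by antiandrogen use, coefficient 0.677), sensitive
#' growth `GS = 1.96e-3 / day`, transformed resistant fraction
#' `RP = 3.94` (modified by haemoglobin, reference 13.6 g/dL, exponent
#' 2.30), resistant growth `GR = 6.54e-4 / day`, variances
#' `(0.453, 2.59, 0.944, 3.76)` and additive log-scale error SD 0.201.
#'
#' @return a [psa_model()].
#' @export
final_psa_model <- function() {
  psa_model("clonal",
            theta = c(DS = 3.78e-2, GS = 1.96e-3, RP = 3.94, GR = 6.54e-4),
            omega = c(DS = 0.453, GS = 2.59, RP = 0.944, GR = 3.76),
            sigma = 0.201,
            links = list(cov_link("RP", "HGB", "power", ref = 13.6, theta = 2.30),
                         cov_link("DS", "BAS", "power", ref = 8.5, theta = 0.174),
                         cov_link("DS", "AND", "indicator", theta = 0.677)))
}

#' @export
print.psa_model <- function(x, ...) {
  cat("PSA kinetics model (", x$structure, " resistance)\n", sep = "")
  cat("  typical values:",
      paste(sprintf("%s=%.4g", names(x$theta), x$theta), collapse = ", "), "\n")
  cat("  omega^2:      ",
      paste(sprintf("%s=%.4g", names(x$omega), x$omega), collapse = ", "), "\n")
  cat("  sigma (log):  ", format(x$sigma, digits = 4), "\n")
  if (length(x$links)) {
    cat("  covariate links:\n")
    for (l in x$links)
      cat(sprintf("    %s -> %s (%s%s): theta = %.4g\n", l$covariate,
                  l$parameter, l$kind,
                  if (l$kind == "power") paste0(", ref ", l$ref) else "",
                  l$theta))
  }
  invisible(x)
}

# Per-parameter design matrices for a covariate data.frame (one row per
# subject).  Column 1 is the intercept (log typical value); subsequent
# columns are log(x/ref) for power links and the raw indicator for
# indicator links.  The fixed-effect vector of the model is the
# concatenation of these per-parameter coefficient blocks.
.design_matrices <- function(model, cov) {
  cov <- as.data.frame(cov)
  m <- nrow(cov)
  out <- list()
  for (p in names(model$theta)) {
    X <- matrix(1, m, 1, dimnames = list(NULL, p))
    for (l in model$links) {
      if (l$parameter != p) next
      x <- cov[[l$covariate]]
      if (is.null(x)) stop("covariate ", l$covariate, " absent from data")
      if (l$kind == "power") {
        if (any(x <= 0)) stop("non-positive value of covariate ", l$covariate,
                              " cannot enter a power link")
        col <- log(x / l$ref)
      } else col <- as.numeric(x)
      X <- cbind(X, stats::setNames(col, NULL))
      colnames(X)[ncol(X)] <- l$name
    }
    out[[p]] <- X
  }
  out
}

# Fixed effects as a flat vector: log typical values then link thetas,
# grouped by parameter (matching .design_matrices column order).
.model_beta <- function(model) {
  b <- c()
  for (p in names(model$theta)) {
    b <- c(b, stats::setNames(log(model$theta[[p]]), p))
    for (l in model$links) if (l$parameter == p)
      b <- c(b, stats::setNames(l$theta, l$name))
  }
  b
}

.set_model_beta <- function(model, beta) {
  for (p in names(model$theta)) model$theta[[p]] <- exp(beta[[p]])
  for (nm in names(model$links)) model$links[[nm]]$theta <- beta[[nm]]
  model
}

#' Typical (covariate-adjusted) parameter values
#'
#' Maps baseline covariates to the typical structural parameters via the
#' model's covariate links, e.g. under the published final model
#' \eqn{RP = \theta_{RP}\,(HGB/13.6)^{\theta_{HGB}}} and
#' \eqn{D_S = \theta_{D_S}\,(BAS/8.5)^{\theta_{BAS}}
#' e^{IND_{AND}\theta_{AND}}}.
#'
#' @param model a [psa_model()].
#' @param cov a named list or data.frame of covariates (one row per
#'   subject).
#' @return a matrix (subjects x parameters) of typical values; a single
#'   subject yields a one-row matrix.
#' @export
typical_params <- function(model, cov) {
  if (!is.data.frame(cov)) cov <- as.data.frame(cov, stringsAsFactors = FALSE)
  X <- .design_matrices(model, cov)
  beta <- .model_beta(model)
  out <- vapply(names(model$theta), function(p) {
    exp(drop(X[[p]] %*% beta[colnames(X[[p]])]))
  }, numeric(nrow(cov)))
  if (nrow(cov) == 1) out <- matrix(out, 1, length(model$theta),
                                    dimnames = list(NULL, names(model$theta)))
  out
}

#' Individual parameters from random effects
#'
#' Applies the lognormal inter-individual model
#' \eqn{\theta_i = \theta_{typ} e^{\eta_i}} parameter-wise.
#'
#' @param typical named vector (or subjects x parameters matrix) of
#'   typical values.
#' @param eta matching vector/matrix of random effects.
#' @return individual parameter values, same shape as `typical`.
#' @export
individual_params <- function(typical, eta) {
  typical * exp(eta)
}

#' Predict the clonal-selection model
#'
#' @param p named vector with `DS`, `GS`, `RP`, `GR` (day^-1 rates and the
#'   transformed resistant fraction).
#' @param bas baseline PSA, ng/mL.
#' @param t observation days (vectorised).
#' @param t1 treatment-start day.
#' @return data.frame with columns `t`, `psa_total`, `psa_sensitive`,
#'   `psa_resistant`.
#' @export
predict_psa_clonal <- function(p, bas, t, t1 = 0) {
  if (any(t < 0) || t1 < 0) stop("times must be non-negative")
  if (bas <= 0) stop("bas must be positive")
  ts <- pmin(t, t1)
  tk <- pmax(0, t - t1)
  R <- exp(-p[["RP"]])
  res <- bas * R * exp(p[["GR"]] * t)
  sen <- bas * (1 - R) * exp(p[["GS"]] * ts - p[["DS"]] * tk)
  data.frame(t = t, psa_total = res + sen, psa_sensitive = sen,
             psa_resistant = res)
}

#' Predict the adaptation model
#'
#' @param p named vector with `D` and `G` (day^-1).
#' @inheritParams predict_psa_clonal
#' @return data.frame with columns `t` and `psa_total`.
#' @export
predict_psa_adaptation <- function(p, bas, t, t1 = 0) {
  if (any(t < 0) || t1 < 0) stop("times must be non-negative")
  if (bas <= 0) stop("bas must be positive")
  ts <- pmin(t, t1)
  tk <- pmax(0, t - t1)
  data.frame(t = t,
             psa_total = bas * exp(p[["G"]] * ts) *
               (exp(-p[["D"]] * tk) + exp(p[["G"]] * tk) - 1))
}

#' PSA doubling time
#'
#' @param G exponential growth rate, day^-1 (must be positive).
#' @return doubling time in days, `log(2)/G`.
#' @export
doubling_time <- function(G) {
  if (any(G <= 0)) stop("G must be positive")
  log(2) / G
}

#' Resistant fraction of the original tumour
#'
#' @param RP transformed resistant-fraction parameter.
#' @return proportion `exp(-RP)` of tumour cells inherently resistant.
#' @export
resistant_fraction <- function(RP) exp(-RP)

#' Closed-form nadir time of a clonal-selection trajectory
#'
#' For treatment from day 0 the total PSA is
#' \eqn{BAS[R e^{G_R t} + (1-R) e^{-D_S t}]}, whose unique stationary
#' point is \eqn{t^* = \log\{D_S (1-R) / (G_R R)\} / (D_S + G_R)}.
#'
#' @param p named parameter vector with `DS`, `RP`, `GR`.
#' @return the stationary time in days (may be negative when the
#'   trajectory is increasing from the start).
#' @export
nadir_time_closed_form <- function(p) {
  R <- exp(-p[["RP"]])
  log(p[["DS"]] * (1 - R) / (p[["GR"]] * R)) / (p[["DS"]] + p[["GR"]])
}
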