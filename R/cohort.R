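#' @title PSA cohort construction and long-format dataset I/O
#' @name cohort-io
#' @description
#' A cohort is a set of subjects, each carrying an irregular PSA time
#' series (days since the baseline observation), the day of the first
#' LHRH-agonist dose (`t1`, same origin), a below-quantification flag per
#' observation, and a fixed set of baseline covariates.  Datasets travel
#' as plain long-format CSV with NONMEM-like columns:
#' `ID, TIME, DV, BLQ, TRT_START` plus one column per covariate
#' (`AGE, RACE, REGION, AND, AST, ALT, SCR, ALP, ALB, HGB, BAS`).
#' Censored rows use the M3 convention: `BLQ = 1` with `DV` set to the
#' lower limit of quantification (0.1 ng/mL by default).
NULL

# Covariate columns expected in a long-format dataset.
.cov_names <- c("AGE", "RACE", "REGION", "AND",
                "AST", "ALT", "SCR", "ALP", "ALB", "HGB", "BAS")
.num_cov_names <- setdiff(.cov_names, c("RACE", "REGION"))
.req_cols <- c("ID", "TIME", "DV", "BLQ", "TRT_START")

#' Construct a single subject record
#'
#' @param id subject identifier (coerced to character).
#' @param time observation days since the baseline observation (day 0).
#' @param dv PSA concentrations in ng/mL; censored rows carry the LLOQ.
#' @param blq logical (or 0/1) flag, `TRUE` for observations below the
#'   lower limit of quantification.
#' @param t1 day of the first LHRH-agonist dose, same time origin.
#' @param cov named list of baseline covariates (see [cohort-io]).
#' @param validate check ordering/positivity invariants (default `TRUE`).
#'   Deliberately invalid subjects (used to exercise the exclusion
#'   filters) can be built with `validate = FALSE`.
#' @return an object of class `"psa_subject"`.
#' @export
psa_subject <- function(id, time, dv, blq = rep(FALSE, length(time)),
                        t1 = 0, cov = list(), validate = TRUE) {
  s <- structure(list(id = as.character(id), time = as.numeric(time),
                      dv = as.numeric(dv), blq = as.logical(blq),
                      t1 = as.numeric(t1), cov = as.list(cov)),
                 class = "psa_subject")
  if (validate) validate_subject(s)
  s
}

validate_subject <- function(s) {
  if (length(s$time) != length(s$dv) || length(s$time) != length(s$blq))
    stop("subject ", s$id, ": time/dv/blq lengths differ")
  if (anyDuplicated(s$time))
    stop("subject ", s$id, ": duplicate observation times")
  if (is.unsorted(s$time, strictly = TRUE))
    stop("subject ", s$id, ": observation times not strictly increasing")
  if (any(s$time < 0) || s$t1 < 0)
    stop("subject ", s$id, ": negative times")
  if (any(!s$blq & s$dv <= 0))
    stop("subject ", s$id, ": non-positive PSA in an uncensored observation")
  if (!any(s$time <= s$t1))
    stop("subject ", s$id, ": no baseline observation at or before t1")
  if (!any(s$time > s$t1))
    stop("subject ", s$id, ": no on-treatment observation after t1")
  invisible(s)
}

#' Assemble subjects into a cohort
#'
#' @param subjects list of [psa_subject()] records with unique ids.
#' @param lloq lower limit of quantification in ng/mL (default 0.1).
#' @return an object of class `"psa_cohort"`.
#' @export
psa_cohort <- function(subjects, lloq = 0.1) {
  ids <- vapply(subjects, function(s) s$id, "")
  if (anyDuplicated(ids)) stop("duplicate subject ids: ",
                               paste(unique(ids[duplicated(ids)]), collapse = ", "))
  if (lloq <= 0) stop("lloq must be positive")
  names(subjects) <- ids
  structure(list(subjects = subjects, lloq = lloq), class = "psa_cohort")
}

#' @export
print.psa_cohort <- function(x, ...) {
  n_obs <- sum(vapply(x$subjects, function(s) length(s$time), 0))
  n_blq <- sum(vapply(x$subjects, function(s) sum(s$blq), 0))
  cat("PSA cohort:", length(x$subjects), "subjects,", n_obs, "observations (",
      n_blq, "below LLOQ of", x$lloq, "ng/mL )\n")
  invisible(x)
}

#' @export
length.psa_cohort <- function(x) length(x$subjects)

#' @export
as.data.frame.psa_cohort <- function(x, ...) {
  rows <- lapply(x$subjects, function(s) {
    cv <- s$cov
    cov_df <- as.data.frame(
      lapply(stats::setNames(.cov_names, .cov_names),
             function(nm) cv[[nm]] %||% NA),
      stringsAsFactors = FALSE)
    data.frame(ID = s$id, TIME = s$time, DV = s$dv, BLQ = as.integer(s$blq),
               TRT_START = s$t1, cov_df, row.names = NULL,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Read a long-format PSA dataset
#'
#' @param path CSV file with the columns described in [cohort-io].
#' @param lloq lower limit of quantification, ng/mL.
#' @return a [psa_cohort()].
#' @details Rows are grouped by `ID` and must be strictly increasing in
#'   `TIME` within a subject; duplicate same-day measurements are a
#'   validation error (such profiles are excluded upstream).
#' @export
read_psa_cohort <- function(path, lloq = 0.1) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  missing_cols <- setdiff(.req_cols, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  cov_present <- intersect(.cov_names, names(df))
  subjects <- lapply(split(df, factor(df$ID, levels = unique(df$ID))),
                     function(d) {
    cv <- as.list(d[1, cov_present, drop = FALSE])
    psa_subject(id = d$ID[1], time = d$TIME, dv = d$DV, blq = d$BLQ == 1,
                t1 = d$TRT_START[1], cov = cv)
  })
  psa_cohort(unname(subjects), lloq = lloq)
}

#' Write a cohort back to long-format CSV
#'
#' Numeric fields round-trip through [read_psa_cohort()] to at least six
#' significant digits.
#'
#' @param cohort a [psa_cohort()].
#' @param path output CSV path.
#' @export
write_psa_cohort <- function(cohort, path) {
  df <- as.data.frame(cohort)
  for (nm in c("TIME", "DV", "TRT_START", .num_cov_names)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], 10)
  }
  utils::write.csv(df, path, row.names = FALSE, quote = TRUE, na = "")
  invisible(path)
}

# Observations strictly before treatment start plus the baseline itself.
.pre_idx <- function(s) which(s$time <= s$t1)
.on_idx <- function(s) which(s$time > s$t1)
# Baseline = observation at day 0 (the time origin).
.baseline_idx <- function(s) which(s$time == min(s$time))[1]

#' Apply the cohort exclusion rules
#'
#' Subjects whose PSA profiles the kinetic models cannot represent are
#' removed before fitting:
#' \describe{
#'   \item{a}{pre-treatment PSA strictly decreasing across all
#'     pre-treatment observations (when at least `min_pre` exist);}
#'   \item{b}{undetectable (below-LLOQ) baseline PSA;}
#'   \item{c}{multiple measurements reported on the same day;}
#'   \item{d}{all on-treatment PSA values below the LLOQ;}
#'   \item{e}{missing demographic data (age, region, race);}
#'   \item{f}{extremely low haemoglobin (< 6 g/dL), indicating acute
#'     illness.}
#' }
#'
#' @param cohort a [psa_cohort()].
#' @param min_pre minimum number of pre-treatment observations before
#'   rule (a) is evaluated (default 2; whether the decreasing-PSA rule
#'   needs two or three points is a modelling choice, so it is exposed).
#' @return a list with elements `cohort` (retained subjects) and
#'   `report` (class `"psa_exclusion_report"`): per-subject disposition
#'   and per-rule tallies.
#' @export
apply_exclusion_filters <- function(cohort, min_pre = 2) {
  rules <- c("a", "b", "c", "d", "e", "f")
  dispo <- vapply(cohort$subjects, function(s) {
    pre <- .pre_idx(s)
    if (length(pre) >= min_pre &&
        all(diff(s$dv[pre]) < 0)) return("a")
    if (s$blq[.baseline_idx(s)]) return("b")
    if (anyDuplicated(s$time)) return("c")
    on <- .on_idx(s)
    if (length(on) && all(s$blq[on])) return("d")
    demo <- s$cov[c("AGE", "REGION", "RACE")]
    if (any(vapply(demo, function(v) is.null(v) || all(is.na(v)), TRUE)))
      return("e")
    hgb <- s$cov[["HGB"]]
    if (!is.null(hgb) && !is.na(hgb) && hgb < 6) return("f")
    "retained"
  }, "")
  keep <- dispo == "retained"
  report <- structure(list(
    disposition = data.frame(ID = names(dispo),
                             status = ifelse(keep, "retained", "excluded"),
                             rule = ifelse(keep, NA_character_, dispo),
                             stringsAsFactors = FALSE, row.names = NULL),
    counts = stats::setNames(vapply(rules, function(r) sum(dispo == r), 0L), rules),
    n_input = length(dispo), n_retained = sum(keep)),
    class = "psa_exclusion_report")
  list(cohort = psa_cohort(unname(cohort$subjects[keep]), lloq = cohort$lloq),
       report = report)
}

#' @export
print.psa_exclusion_report <- function(x, ...) {
  cat("Exclusion report:", x$n_retained, "of", x$n_input, "subjects retained\n")
  lab <- c(a = "decreasing pre-treatment PSA",
           b = "undetectable baseline PSA",
           c = "duplicate same-day measurements",
           d = "all on-treatment PSA below LLOQ",
           e = "missing demographics",
           f = "haemoglobin < 6 g/dL")
  for (r in names(x$counts))
    cat(sprintf("  rule %s (%s): %d\n", r, lab[[r]], x$counts[[r]]))
  invisible(x)
}

#' Write an exclusion report as CSV
#' @param report a `"psa_exclusion_report"`.
#' @param path output CSV path.
#' @export
write_exclusion_report <- function(report, path) {
  utils::write.csv(report$disposition, path, row.names = FALSE)
  invisible(path)
}

#' Truncate a subject's follow-up
#'
#' Drops observations recorded after `stop_day` (for example the start of
#' continuous antiandrogen therapy, surgery, radiotherapy or
#' chemotherapy).  The baseline and treatment start are preserved.
#'
#' @param subject a [psa_subject()].
#' @param stop_day last retained observation day; must be at or after the
#'   treatment start.
#' @return the truncated subject.
#' @export
truncate_followup <- function(subject, stop_day) {
  if (stop_day < subject$t1)
    stop("stop_day must be at or after treatment start (t1 = ", subject$t1, ")")
  keep <- subject$time <= stop_day
  out <- subject
  out$time <- subject$time[keep]
  out$dv <- subject$dv[keep]
  out$blq <- subject$blq[keep]
  if (!any(out$time > out$t1))
    stop("subject ", subject$id,
         ": truncation leaves no on-treatment observation")
  validate_subject(out)
  out
}
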