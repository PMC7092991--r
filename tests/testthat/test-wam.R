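test_that("the Wald quadratic form matches hand inversions", {
  expect_equal(wald_statistic(2, matrix(1)), 4)        # (est/SE)^2
  expect_equal(wald_statistic(c(0, 0), diag(2)), 0)
  # 2x2 inverse by hand: C22 = [[2,1],[1,2]], theta2 = (1,1)
  C <- matrix(c(2, 1, 1, 2), 2)
  expect_equal(wald_statistic(c(1, 1), C), 2 / 3)
  # invariance under index reordering
  C4 <- crossprod(matrix(c(2, 0.3, -0.1, 0.5, 1, 0.2, 0, -0.4, 0.9,
                           0.1, 0.2, 1.4, 0.3, 0, 0.1, 1.1), 4))
  dimnames(C4) <- list(letters[1:4], letters[1:4])
  th <- c(a = 0.5, b = -1, c = 2, d = 0.1)
  expect_equal(wald_statistic(th[c("b", "d")], C4, c("b", "d")),
               wald_statistic(th[c("d", "b")], C4, c("d", "b")))
  expect_error(wald_statistic(c(1, 1), matrix(c(1, 1, 1, 1), 2)),
               "positive definite")
})

test_that("building a full model adds one zero coefficient per candidate", {
  base <- start_model(links = FALSE)
  co <- generate_cohort(cohort_design(50), seed = 9)
  cands <- data.frame(parameter = c("RP", "DS", "DS", "GR"),
                      covariate = c("HGB", "BAS", "AND", "AGE"),
                      kind = c("power", "power", "indicator", "power"))
  full <- build_full_model(base, cands, co)
  expect_length(full$links, 4)
  expect_true(all(vapply(full$links, function(l) l$theta, 0) == 0))
  # references frozen at the cohort medians
  hgb_med <- median(vapply(co$subjects, function(s) s$cov$HGB, 0))
  expect_equal(full$links[["RP:HGB"]]$ref, hgb_med)
  # zero coefficients leave the typical values untouched
  tv <- typical_params(full, list(HGB = 9, BAS = 40, AND = 1, AGE = 70))
  expect_equal(unname(tv[1, ]), unname(base$theta))
  expect_error(build_full_model(full, cands, co), "duplicate")
  expect_identical(build_full_model(base, list()), base)
})

test_that("greedy elimination with a diagonal covariance orders by theta^2/var", {
  base <- start_model(links = FALSE)
  links <- list(cov_link("DS", "BAS", "power", ref = 8.5, theta = 0.05),
                cov_link("RP", "HGB", "power", ref = 13.6, theta = 1.0),
                cov_link("GR", "AGE", "power", ref = 80, theta = 0.2),
                cov_link("GS", "ALB", "power", ref = 4.1, theta = 4.0))
  model <- base; model$links <- stats::setNames(links,
    vapply(links, function(l) l$name, ""))
  beta <- psaprog:::.model_beta(model)
  vc <- diag(0.04, length(beta))
  dimnames(vc) <- list(names(beta), names(beta))
  fake <- structure(list(beta = beta, vcov = vc, model = model),
                    class = "psa_fit")
  path <- wam_backward_eliminate(fake)
  elim <- path$steps$candidate[path$steps$action == "eliminate"]
  # ascending theta^2/var: 0.0625 then 1, both below 10.83; the rest stay
  expect_equal(elim, c("DS:BAS", "GR:AGE"))
  expect_setequal(path$surviving, c("RP:HGB", "GS:ALB"))  # 25 and 400
  # marginal single-coefficient statistics are (estimate/SE)^2
  expect_equal(unname(path$marginal["RP:HGB"]), 1 / 0.04)
})

test_that("all weak coefficients are eliminated; a zero-candidate screen is a no-op", {
  base <- start_model(links = FALSE)
  links <- list(cov_link("DS", "BAS", "power", ref = 8.5, theta = 0.1),
                cov_link("RP", "HGB", "power", ref = 13.6, theta = -0.2))
  model <- base; model$links <- stats::setNames(links,
    vapply(links, function(l) l$name, ""))
  beta <- psaprog:::.model_beta(model)
  vc <- diag(1, length(beta)); dimnames(vc) <- list(names(beta), names(beta))
  fake <- structure(list(beta = beta, vcov = vc, model = model),
                    class = "psa_fit")
  path <- wam_backward_eliminate(fake)   # |theta/SE| < 1 everywhere
  expect_length(path$surviving, 0)
  path0 <- wam_backward_eliminate(fake, candidates = character(0))
  expect_length(path0$surviving, 0)
  expect_length(path0$eliminated, 0)
})

test_that("grouped multi-level candidates are tested jointly", {
  base <- start_model(links = FALSE)
  links <- list(cov_link("RP", "RACE_B", "indicator", theta = 0.4),
                cov_link("RP", "RACE_H", "indicator", theta = 0.3))
  model <- base; model$links <- stats::setNames(links,
    vapply(links, function(l) l$name, ""))
  beta <- psaprog:::.model_beta(model)
  vc <- diag(0.01, length(beta)); dimnames(vc) <- list(names(beta), names(beta))
  fake <- structure(list(beta = beta, vcov = vc, model = model),
                    class = "psa_fit")
  grp <- list(RACE = c("RP:RACE_B", "RP:RACE_H"))
  path <- wam_backward_eliminate(fake, groups = grp)
  # joint statistic 0.4^2/0.01 + 0.3^2/0.01 = 25 vs qchisq 2-df threshold
  st <- path$steps[path$steps$candidate == "RACE", ]
  expect_equal(st$lambda_prime, 25)
  expect_equal(st$df, 2L)
  expect_equal(st$action, "retain")
})

test_that("confirmatory refits drop a spurious survivor and keep true links testable", {
  gen <- psa_model("clonal", theta = c(DS = 3.78e-2, GS = 1.96e-3,
                                       RP = 3.94, GR = 6.54e-4),
                   omega = c(DS = 0.453, GS = 2.59, RP = 0.944, GR = 3.76),
                   sigma = 0.201)
  co <- generate_cohort(cohort_design(30, model = gen), seed = 61)
  start <- start_model(links = FALSE)
  start$links <- list("DS:AND" = cov_link("DS", "AND", "indicator"))
  res <- confirmatory_backward_elimination(start, co, fast_control(),
                                           seed = 62)
  expect_length(res$model$links, 0)              # the null link is dropped
  expect_true(any(res$log$action == "dropped"))
  # never retains what the OFV rejects: every retained candidate's final
  # tested delta OFV is above the threshold
  dropped <- res$log$candidate[res$log$action == "dropped"]
  expect_true(all(names(res$model$links) %in%
                    setdiff(res$log$candidate, dropped)))
  # zero survivors: nothing to test, the start model comes back
  res0 <- confirmatory_backward_elimination(start_model(links = FALSE), co,
                                            fast_control(), seed = 63)
  expect_null(res0$log)
  expect_length(res0$model$links, 0)
})
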