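test_that("doubling times match the published growth rates", {
  expect_equal(round(doubling_time(1.96e-3)), 354)
  expect_equal(round(doubling_time(6.54e-4)), 1060)
  expect_equal(doubling_time(log(2)), 1)
  expect_error(doubling_time(0), "positive")
})

test_that("resistant fractions transform as exp(-RP)", {
  expect_equal(signif(100 * resistant_fraction(3.94), 3), 1.94)
  # the published 9.36% comes from the unrounded RP at 5th-percentile HGB
  expect_equal(signif(100 * resistant_fraction(3.94 * (10.9 / 13.6)^2.30), 3),
               9.36)
  expect_equal(resistant_fraction(0), 1)
})

test_that("the covariate model reproduces the published typical values", {
  m <- final_psa_model()
  # 5th-percentile haemoglobin
  tp <- typical_params(m, list(HGB = 10.9, BAS = 8.5, AND = 0))
  expect_equal(tp[, "RP"], 2.37, tolerance = 0.005, ignore_attr = TRUE)
  expect_equal(signif(100 * resistant_fraction(tp[, "RP"]), 3), 9.36,
               ignore_attr = TRUE)
  # 95th-percentile baseline PSA
  tp2 <- typical_params(m, list(HGB = 13.6, BAS = 120, AND = 0))
  expect_equal(tp2[, "DS"], 5.99e-2, tolerance = 0.005, ignore_attr = TRUE)
  # reference covariates give the intercepts exactly
  tp3 <- typical_params(m, list(HGB = 13.6, BAS = 8.5, AND = 0))
  expect_equal(unname(tp3[1, ]), unname(m$theta))
  # antiandrogen multiplier: e^0.677, a 96.8% increase
  tp4 <- typical_params(m, list(HGB = 13.6, BAS = 8.5, AND = 1))
  expect_equal(tp4[, "DS"] / tp3[, "DS"], exp(0.677), ignore_attr = TRUE)
  expect_equal(signif(100 * (exp(0.677) - 1), 3), 96.8)
})

test_that("typical values are monotone in their covariates", {
  m <- final_psa_model()
  hgb <- typical_params(m, data.frame(HGB = c(8, 12, 16), BAS = 8.5, AND = 0))
  expect_true(all(diff(hgb[, "RP"]) > 0))
  bas <- typical_params(m, data.frame(HGB = 13.6, BAS = c(1, 10, 100), AND = 0))
  expect_true(all(diff(bas[, "DS"]) > 0))
  expect_error(typical_params(m, list(HGB = -1, BAS = 8.5, AND = 0)),
               "non-positive")
})

test_that("lognormal random effects act multiplicatively with median = typical", {
  typ <- c(DS = 0.04, GS = 0.002, RP = 4, GR = 6e-4)
  expect_equal(individual_params(typ, c(0, 0, 0, 0)), typ)
  doubled <- individual_params(typ, c(log(2), 0, 0, 0))
  expect_equal(unname(doubled), unname(typ) * c(2, 1, 1, 1))
  set.seed(4)
  eta <- matrix(rnorm(1e5 * 4, 0, 0.8), ncol = 4)
  draws <- individual_params(matrix(typ, 1e5, 4, byrow = TRUE,
                                    dimnames = list(NULL, names(typ))), eta)
  expect_equal(unname(apply(draws, 2, median)), unname(typ), tolerance = 0.02)
})

test_that("clonal trajectories decompose additively and start at baseline", {
  p <- c(DS = 0.0378, GS = 1.96e-3, RP = 3.94, GR = 6.54e-4)
  tr <- predict_psa_clonal(p, bas = 8.5, t = 0, t1 = 0)
  expect_equal(tr$psa_total, 8.5)
  tt <- seq(0, 1095, by = 3)
  set.seed(11)
  for (r in 1:20) {
    pr <- c(DS = runif(1, 0.005, 0.2), GS = runif(1, 1e-4, 0.01),
            RP = runif(1, 0.5, 8), GR = runif(1, 1e-4, 0.01))
    tr <- predict_psa_clonal(pr, bas = runif(1, 0.5, 100), tt,
                             t1 = sample(0:200, 1))
    expect_equal(tr$psa_total, tr$psa_sensitive + tr$psa_resistant)
    expect_true(all(tr$psa_total >= 0))
  }
})

test_that("a vanishing resistant pool reduces to the pure sensitive kinetics", {
  p <- c(DS = 0.04, GS = 0.002, RP = 40, GR = 0.001)
  tt <- seq(0, 500, by = 10)
  tr <- predict_psa_clonal(p, 10, tt, t1 = 100)
  pure <- 10 * exp(0.002 * pmin(tt, 100) - 0.04 * pmax(0, tt - 100))
  expect_equal(tr$psa_total, pure, tolerance = 1e-12)
})

test_that("both models are continuous at the treatment start", {
  eps <- 1e-9
  pc <- c(DS = 0.05, GS = 0.003, RP = 3, GR = 0.001)
  lhs <- predict_psa_clonal(pc, 12, 100 - eps, t1 = 100)$psa_total
  rhs <- predict_psa_clonal(pc, 12, 100 + eps, t1 = 100)$psa_total
  expect_equal(lhs, rhs, tolerance = 1e-6)
  pa <- c(D = 0.05, G = 0.003)
  lhs <- predict_psa_adaptation(pa, 12, 100 - eps, t1 = 100)$psa_total
  rhs <- predict_psa_adaptation(pa, 12, 100 + eps, t1 = 100)$psa_total
  expect_equal(lhs, rhs, tolerance = 1e-6)
})

test_that("on-treatment PSA is monotone in kill and resistant growth rates", {
  base <- c(DS = 0.03, GS = 0.002, RP = 3, GR = 0.001)
  tt <- c(150, 400, 900)
  for (ds in seq(0.01, 0.2, length.out = 8)) {
    lo <- predict_psa_clonal(replace(base, "DS", ds), 10, tt, 30)$psa_total
    hi <- predict_psa_clonal(replace(base, "DS", ds + 0.01), 10, tt, 30)$psa_total
    expect_true(all(hi <= lo + 1e-12))
  }
  for (gr in seq(1e-4, 0.01, length.out = 8)) {
    lo <- predict_psa_clonal(replace(base, "GR", gr), 10, tt, 30)$psa_total
    hi <- predict_psa_clonal(replace(base, "GR", gr + 1e-4), 10, tt, 30)$psa_total
    expect_true(all(hi >= lo - 1e-12))
  }
})

test_that("adaptation model collapses algebraically in its limits", {
  expect_equal(predict_psa_adaptation(c(D = 0.1, G = 0.004), 7,
                                      c(0, 10, 50), t1 = 50)$psa_total,
               7 * exp(0.004 * c(0, 10, 50)))
  tt <- c(0, 100, 300)
  expect_equal(predict_psa_adaptation(c(D = 0, G = 0.003), 7, tt, 100)$psa_total,
               7 * exp(0.003 * pmin(tt, 100)) * exp(0.003 * pmax(0, tt - 100)))
  expect_equal(predict_psa_adaptation(c(D = 0.02, G = 0), 5, tt, 0)$psa_total,
               5 * exp(-0.02 * tt))
})

test_that("the closed-form nadir matches grid minimisation within half a day", {
  m <- final_psa_model()
  p <- drop(typical_params(m, list(HGB = 13.6, BAS = 8.5, AND = 0)))
  tstar <- nadir_time_closed_form(p)
  tt <- seq(0, 1095, by = 0.25)
  tr <- predict_psa_clonal(p, 8.5, tt, 0)
  expect_lt(abs(tt[which.min(tr$psa_total)] - tstar), 0.5)
})
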