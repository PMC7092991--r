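test_that("a single-draw E step returns that draw with zero variance", {
  m <- final_psa_model()
  s <- generate_cohort(cohort_design(1), seed = 8)$subjects[[1]]
  r <- e_step(m, s, isample = 1, seed = 2)
  expect_equal(unname(r$B_bar), matrix(0, 4, 4))
  expect_true(all(is.finite(r$theta_bar)))
})

test_that("a flat likelihood returns the population density's own moments", {
  m <- psa_model("clonal", theta = c(DS = 0.03, GS = 0.002, RP = 3, GR = 1e-3),
                 omega = c(DS = 0.4, GS = 0.3, RP = 0.6, GR = 0.5), sigma = 0.2)
  s <- psa_subject("F", numeric(0), numeric(0), logical(0), t1 = 0,
                   cov = list(BAS = 8, HGB = 13, AND = 0), validate = FALSE)
  r <- e_step(m, s, isample = 1e5, seed = 5)
  expect_equal(unname(r$theta_bar), unname(log(m$theta)), tolerance = 0.02)
  expect_equal(unname(diag(r$B_bar)), unname(m$omega), tolerance = 0.05)
})

test_that("the E-step core matches the conjugate Gaussian posterior", {
  # one-dimensional linear-Gaussian toy: y_j ~ N(phi, s2), phi ~ N(mu0, w2)
  y <- c(1.2, 0.7, 1.05); s <- 0.3; mu0 <- 0; w2 <- 0.8
  post_var <- 1 / (1 / w2 + length(y) / s^2)
  post_mean <- post_var * (mu0 / w2 + sum(y) / s^2)
  llfun <- function(phi) rowSums(matrix(
    dnorm(rep(y, each = nrow(phi)), phi[, 1], s, log = TRUE),
    nrow(phi), length(y)))
  set.seed(9)
  r <- psaprog:::.e_step_core(llfun, mu = c(phi = mu0), omega = c(phi = w2),
                              isample = 1e5)
  expect_equal(unname(r$theta_bar), post_mean, tolerance = 0.01)
  expect_equal(unname(drop(r$B_bar)), post_var, tolerance = 0.02)
  # and the log marginal likelihood against its closed form
  marg <- sum(dnorm(y, post_mean, s, log = TRUE)) +
    dnorm(post_mean, mu0, sqrt(w2), log = TRUE) -
    dnorm(post_mean, post_mean, sqrt(post_var), log = TRUE)
  expect_equal(r$logmarg, marg, tolerance = 0.01)
})

test_that("conditional moments agree with a 2-d quadrature oracle within 1%", {
  m <- psa_model("clonal", theta = c(DS = 0.035, GS = 0.002, RP = 3.5, GR = 7e-4),
                 omega = c(DS = 0.45, GS = 0, RP = 0.9, GR = 0), sigma = 0.3)
  s <- psa_subject("Q", time = c(0, 90, 250), dv = c(9, 2.5, 0.9), t1 = 0,
                   cov = list(BAS = 9))
  q <- quadrature_moments(m, s, free = c("DS", "RP"))
  r <- e_step(m, s, isample = 1e5, seed = 21)
  for (p in c("DS", "RP")) {
    expect_equal(r$theta_bar[[p]], q$theta_bar[[p]],
                 tolerance = 0.01 * max(1, abs(q$theta_bar[[p]])))
    expect_equal(diag(r$B_bar)[[p]], q$B_diag[[p]], tolerance = 0.03)
  }
  # degenerate dimensions stay at their population values
  expect_equal(r$theta_bar[["GS"]], log(m$theta[["GS"]]))
})

test_that("the M step reproduces the population-moment update", {
  mk <- function(tb, B) list(theta_bar = tb, B_bar = B)
  one <- mk(c(a = 1, b = 2), diag(0, 2))
  expect_equal(m_step(list(one))$mu, c(a = 1, b = 2))
  # all conditional variances zero: Omega is the empirical second moment
  ms <- list(mk(c(a = 1, b = 0), diag(0, 2)), mk(c(a = 3, b = 1), diag(0, 2)),
             mk(c(a = 2, b = -1), diag(0, 2)))
  r <- m_step(ms)
  TB <- rbind(c(1, 0), c(3, 1), c(2, -1))
  expect_equal(unname(r$mu), colMeans(TB))
  expect_equal(unname(diag(r$Omega)),
               colMeans(sweep(TB, 2, colMeans(TB))^2))
  # hand-computed fixture with conditional variances
  ms2 <- list(mk(c(a = 1, b = 2), diag(c(0.1, 0.2))),
              mk(c(a = 2, b = 4), diag(c(0.3, 0.4))),
              mk(c(a = 3, b = 6), diag(c(0.2, 0.6))))
  r2 <- m_step(ms2)
  expect_equal(unname(r2$mu), c(2, 4))
  expect_equal(unname(diag(r2$Omega)),
               c(2 / 3 + 0.2, 8 / 3 + 0.4))
})

test_that("exact-E-step EM increases the marginal likelihood monotonically", {
  # linear-Gaussian toy with closed-form E step and marginal likelihood
  set.seed(13)
  mtrue <- 1.5; wtrue <- 0.5; s <- 0.4; n <- 40; k <- 3
  phi <- rnorm(n, mtrue, sqrt(wtrue))
  Y <- matrix(rnorm(n * k, rep(phi, each = k), s), n, k, byrow = TRUE)
  mu <- 0; w <- 2
  loglik <- function(mu, w) {
    # y_i ~ N(mu 1, s2 I + w 11')
    Sg <- diag(s^2, k) + w
    sum(apply(Y, 1, function(y) {
      -0.5 * (k * log(2 * pi) + determinant(Sg)$modulus +
                drop(t(y - mu) %*% solve(Sg) %*% (y - mu)))
    }))
  }
  lls <- numeric(15)
  for (it in 1:15) {
    lls[it] <- loglik(mu, w)
    pv <- 1 / (1 / w + k / s^2)
    pm <- pv * (mu / w + rowSums(Y) / s^2)
    moments <- lapply(seq_len(n), function(i)
      list(theta_bar = c(phi = pm[i]), B_bar = matrix(pv, 1, 1,
                                                      dimnames = list("phi", "phi"))))
    up <- m_step(moments)
    mu <- up$mu[["phi"]]; w <- up$Omega[1, 1]
  }
  expect_true(all(diff(lls) > -1e-8))
  expect_equal(mu, mean(Y), tolerance = 0.02)
})

test_that("convergence testing uses the Bonferroni-adjusted regression", {
  tr <- data.frame(iter = 1:5, isample = 500, ofv = rnorm(5),
                   a = rep(1, 5), b = rep(2, 5), c = 0, d = 0, e = 0)
  r <- convergence_check(tr, window = 5, alpha = 0.05)
  expect_equal(attr(r, "level"), 0.01)     # alpha / B with B = 5
  expect_true(attr(r, "converged"))        # constant traces converge
  set.seed(2)
  tr$a <- 1:5 + rnorm(5, 0, 1e-4)          # drift far above the noise
  r2 <- convergence_check(tr, window = 5)
  expect_false(r2$converged[r2$parameter == "a"])
  expect_false(attr(r2, "converged"))
  expect_error(convergence_check(tr[1:3, ], window = 5), "fewer")
})

test_that("model comparison applies the LRT threshold and AIC rule", {
  mkfit <- function(ofv, npar, links = list(), structure = "clonal") {
    ml <- psa_model(structure,
                    theta = if (structure == "clonal")
                      c(DS = 0.03, GS = 0.002, RP = 3, GR = 1e-3)
                    else c(D = 0.03, G = 0.002),
                    links = links)
    structure(list(model = ml, ofv = ofv, npar = npar, aic = ofv + 2 * npar,
                   signature = c(m = 10, n_obs = 40, y_sum = 1)),
              class = "psa_fit")
  }
  expect_equal(mkfit(100, 5)$aic, 110)
  l <- list(cov_link("DS", "BAS", "power", ref = 8.5))
  # delta OFV 11 on one df: reject the reduced model
  r <- compare_models(mkfit(111, 9), mkfit(100, 10, links = l))
  expect_equal(r$method, "LRT")
  expect_equal(r$winner, "full")
  # delta OFV 10: retain the reduced model
  r2 <- compare_models(mkfit(110, 9), mkfit(100, 10, links = l))
  expect_equal(r2$winner, "reduced")
  # different structures: AIC decides
  r3 <- compare_models(mkfit(100, 9), mkfit(104, 5, structure = "adaptation"))
  expect_equal(r3$method, "AIC")
  expect_equal(r3$winner, "b")
  bad <- mkfit(100, 9); bad$signature <- c(m = 11, n_obs = 40, y_sum = 1)
  expect_error(compare_models(mkfit(100, 9), bad), "same cohort")
})

test_that("identical seeds give bit-identical fit traces", {
  co <- generate_cohort(cohort_design(12), seed = 31)
  ctl <- mcpem_control(stages = data.frame(isample = 100, iters = 5),
                       vcov = FALSE)
  f1 <- fit_psa_model(co, start_model(links = FALSE), ctl, seed = 77)
  f2 <- fit_psa_model(co, start_model(links = FALSE), ctl, seed = 77)
  expect_identical(f1$trace, f2$trace)
  expect_identical(f1$ofv, f2$ofv)
  f3 <- fit_psa_model(co, start_model(links = FALSE), ctl, seed = 78)
  expect_false(identical(f1$ofv, f3$ofv))
})

test_that("with no variability and tiny noise the fit recovers the typical values", {
  gen <- psa_model("clonal", theta = c(DS = 3.78e-2, GS = 1.96e-3,
                                       RP = 3.94, GR = 6.54e-4),
                   omega = c(DS = 0, GS = 0, RP = 0, GR = 0), sigma = 1e-3)
  d <- cohort_design(30, model = gen)
  co <- generate_cohort(d, seed = 17)
  ctl <- mcpem_control(stages = data.frame(isample = c(200, 400),
                                           iters = c(40, 5)), vcov = FALSE)
  fit <- fit_psa_model(co, start_model(links = FALSE), ctl, seed = 18)
  expect_equal(unname(coef(fit)[c("DS", "GS", "RP", "GR")]),
               unname(gen$theta), tolerance = 0.05)
  expect_lt(fit$sigma, 0.05)
})

test_that("nested null covariates rarely clear the 10.83 OFV threshold", {
  # type-I behaviour of the LRT rule on data with no AND effect
  gen <- psa_model("clonal", theta = c(DS = 3.78e-2, GS = 1.96e-3,
                                       RP = 3.94, GR = 6.54e-4),
                   omega = c(DS = 0.453, GS = 2.59, RP = 0.944, GR = 3.76),
                   sigma = 0.201)
  ctl <- fast_control()
  deltas <- vapply(1:5, function(r) {
    co <- generate_cohort(cohort_design(30, model = gen), seed = 100 + r)
    f0 <- fit_psa_model(co, start_model(links = FALSE), ctl, seed = 200 + r)
    withand <- start_model(links = FALSE)
    withand$links <- list("DS:AND" = cov_link("DS", "AND", "indicator"))
    f1 <- fit_psa_model(co, withand, ctl, seed = 200 + r)
    f0$ofv - f1$ofv
  }, 0)
  expect_gte(sum(deltas < 10.83), 4)
})

test_that("the generative model beats a mis-specified one on its own data", {
  co <- generate_cohort(cohort_design(100), seed = 41)
  truth <- final_psa_model()
  wrong <- truth
  wrong$theta[["DS"]] <- truth$theta[["DS"]] / 4
  ofv_of <- function(mod) {
    dat <- psaprog:::.prep_fit_data(co, mod)
    b <- psaprog:::.model_beta(mod)
    p1 <- psaprog:::.mc_pass(dat, b, mod$omega, mod$sigma, 2000, draw_seed = 5)
    pv <- 2 * p1$Bdiag + matrix(0.05 * mod$omega, dat$m, 4, byrow = TRUE)
    psaprog:::.mc_pass(dat, b, mod$omega, mod$sigma, 2000, draw_seed = 6,
                       prop_mean = p1$thetabar, prop_var = pv)$ofv
  }
  expect_lt(ofv_of(truth), ofv_of(wrong))
})

test_that("the finite-difference covariance reproduces a closed-form SE", {
  # near-linear design: resistant pool dominates late observations, so the
  # log prediction is log(BAS) - RP and SE(log theta_RP) = sigma / sqrt(n)
  n <- 50; sg <- 0.2
  subs <- lapply(seq_len(n), function(i)
    psa_subject(paste0("s", i), c(0, 50), c(10, 10 * exp(-1)), t1 = 0,
                cov = list(BAS = 10)))
  co <- psa_cohort(subs)
  m <- psa_model("clonal", theta = c(DS = 5, GS = 1e-8, RP = 1, GR = 1e-8),
                 omega = c(DS = 0, GS = 0, RP = 0, GR = 0), sigma = sg)
  vc <- estimate_covariance(m, co, isample = 50, seed = 3, free = "RP")
  expect_equal(unname(vc$se), sg / sqrt(n), tolerance = 0.05)
  # a multi-parameter covariance comes back symmetric
  co2 <- generate_cohort(cohort_design(40), seed = 51)
  vc2 <- suppressWarnings(
    estimate_covariance(final_psa_model(), co2, isample = 300, seed = 4,
                        free = c("DS", "RP")))
  expect_equal(vc2$cov, t(vc2$cov), tolerance = 1e-8)
  expect_true(all(vc2$pct_cv > 0))
})
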