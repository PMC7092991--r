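# Shared fixtures and oracles, all built in code at test time.

# Generic clinical starting model used by every fit: deliberately away
# from the generative values.
start_model <- function(links = TRUE) {
  psa_model("clonal",
            theta = c(DS = 0.02, GS = 0.005, RP = 2, GR = 0.002),
            omega = c(DS = 0.5, GS = 0.5, RP = 0.5, GR = 0.5),
            sigma = 0.3,
            links = if (links) list(
              cov_link("RP", "HGB", "power", ref = 13.6),
              cov_link("DS", "BAS", "power", ref = 8.5),
              cov_link("DS", "AND", "indicator")) else list())
}

start_model_adaptation <- function() {
  psa_model("adaptation", theta = c(D = 0.02, G = 0.002),
            omega = c(D = 0.5, G = 0.5), sigma = 0.3)
}

# Published population estimates used as generative truth.
table2_truth <- c(DS = 3.78e-2, GS = 1.96e-3, RP = 3.94, GR = 6.54e-4,
                  "RP:HGB" = 2.30, "DS:BAS" = 0.174, "DS:AND" = 0.677)

fast_control <- function(...) {
  mcpem_control(stages = data.frame(isample = c(150, 400), iters = c(30, 6)),
                vcov = FALSE, ...)
}

# A small long-format CSV fixture: 2 subjects, 3 observations each.
write_fixture_csv <- function(path, duplicate_time = FALSE) {
  rows <- c(
    "ID,TIME,DV,BLQ,TRT_START,AGE,RACE,REGION,AND,AST,ALT,SCR,ALP,ALB,HGB,BAS",
    "A,0,10,0,30,75,Caucasian,South,0,20,18,1.1,76,4.1,13.6,10",
    "A,90,4,0,30,75,Caucasian,South,0,20,18,1.1,76,4.1,13.6,10",
    sprintf("A,%d,1.5,0,30,75,Caucasian,South,0,20,18,1.1,76,4.1,13.6,10",
            if (duplicate_time) 90L else 200L),
    "B,0,6,0,10,80,Black,West,1,25,20,1.0,80,4.0,12.5,6",
    "B,100,0.1,1,10,80,Black,West,1,25,20,1.0,80,4.0,12.5,6",
    "B,250,0.4,0,10,80,Black,West,1,25,20,1.0,80,4.0,12.5,6")
  writeLines(rows, path)
  path
}

# Independent quadrature oracle for two-dimensional conditional moments:
# dense tensor-product grid over the two free random effects, posterior
# weights = likelihood x normal prior, trapezoid-equivalent Riemann sums.
quadrature_moments <- function(model, subject, free = c("DS", "RP"),
                               half_width = 6, n_grid = 161) {
  pn <- names(model$theta)
  mu <- log(drop(typical_params(model, psaprog:::.subject_cov(subject))))
  sd1 <- sqrt(model$omega[[free[1]]]); sd2 <- sqrt(model$omega[[free[2]]])
  g1 <- seq(-half_width * sd1, half_width * sd1, length.out = n_grid)
  g2 <- seq(-half_width * sd2, half_width * sd2, length.out = n_grid)
  grid <- expand.grid(e1 = g1, e2 = g2)
  eta <- matrix(0, nrow(grid), length(pn), dimnames = list(NULL, pn))
  eta[, free[1]] <- grid$e1
  eta[, free[2]] <- grid$e2
  ll <- subject_loglik(model, subject, eta)
  lp <- ll + stats::dnorm(grid$e1, 0, sd1, log = TRUE) +
    stats::dnorm(grid$e2, 0, sd2, log = TRUE)
  w <- exp(lp - max(lp)); w <- w / sum(w)
  phi <- sweep(eta, 2, mu, "+")
  tb <- colSums(w * phi)
  dev <- sweep(phi, 2, tb, "-")
  list(theta_bar = tb,
       B_diag = colSums(w * dev^2))
}
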