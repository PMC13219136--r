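# The oracle below recodes the joint density directly from its definition
# (binomial + two normal proxy terms per cell, truncated-normal hierarchy,
# hyperpriors), independently of the package's ez_moments/log_density code
# path.
oracle_log_density <- function(model, pars) {
  spec <- model$spec
  d <- model$data
  ltn <- function(x, m, s, lo)  # truncated normal, log
    dnorm(x, m, s, log = TRUE) - log(1 - pnorm((lo - m) / s))
  lp <- dnorm(pars$mu_nu, spec$mu_nu_prior[1], spec$mu_nu_prior[2], TRUE) +
    dnorm(pars$beta, spec$beta_prior[1], spec$beta_prior[2], TRUE) +
    ltn(pars$mu_alpha, spec$mu_alpha_prior[1], spec$mu_alpha_prior[2], 0) +
    ltn(pars$mu_tau, spec$mu_tau_prior[1], spec$mu_tau_prior[2], 0) +
    ltn(pars$sigma_nu, 0, spec$sigma_nu_sd, 0) +
    ltn(pars$sigma_alpha, 0, spec$sigma_alpha_sd, 0) +
    ltn(pars$sigma_tau, 0, spec$sigma_tau_sd, 0)
  for (p in seq_len(d$P)) {
    lp <- lp + ltn(pars$alpha[p], pars$mu_alpha, pars$sigma_alpha, 0) +
      ltn(pars$tau[p], pars$mu_tau, pars$sigma_tau, spec$tau_floor)
    for (k in 1:2) {
      nu <- pars$nu[p, k]
      lp <- lp + dnorm(nu, pars$mu_nu + pars$beta * d$X[k], pars$sigma_nu,
                       TRUE)
      kap <- pars$alpha[p] * nu / spec$s^2
      pc <- 1 / (1 + exp(-kap))
      mrt <- pars$tau[p] + (pars$alpha[p] / (2 * nu)) * (2 * pc - 1)
      vrt <- (pars$alpha[p] * spec$s^2 / nu^3) * (pc - 0.5 - kap * pc * (1 - pc))
      lp <- lp + dbinom(d$nc[p, k], d$ntot[p, k], pc, log = TRUE) +
        dnorm(d$loc[p, k], mrt, sqrt(vrt / d$nrt[p, k]), TRUE) +
        dnorm(d$scl[p, k], vrt, sqrt(2 * vrt^2 / (d$nrt[p, k] - 1)), TRUE)
    }
  }
  lp
}

random_point <- function(P) {
  list(mu_nu = runif(1, -1, 2), beta = runif(1, -0.5, 0.5),
       mu_alpha = runif(1, 2, 3.5), mu_tau = runif(1, 0.2, 0.4),
       sigma_nu = runif(1, 0.5, 1.2), sigma_alpha = runif(1, 0.4, 1),
       sigma_tau = runif(1, 0.1, 0.4),
       nu = matrix(runif(2 * P, 0.3, 2.5), P, 2),
       alpha = runif(P, 1.5, 3.5), tau = runif(P, 0.1, 0.5))
}

test_that("the model log density matches an independently coded oracle", {
  fx <- fixture_dataset(P = 5, T = 25)
  cells <- summarize_dataset(fx$data, "standard", rt_scope = "all")
  model <- build_model(cells, model_spec(rt_scope = "all"))
  set.seed(77)
  for (i in 1:5) {
    pars <- random_point(5)
    expect_equal(model$log_density(pars), oracle_log_density(model, pars),
                 tolerance = 1e-10)
  }
  # finite at the generating truth
  truth <- list(mu_nu = fx$ind$pop$mu_nu, beta = fx$ind$pop$beta,
                mu_alpha = fx$ind$pop$mu_alpha, mu_tau = fx$ind$pop$mu_tau,
                sigma_nu = sqrt(0.75), sigma_alpha = sqrt(0.5),
                sigma_tau = sqrt(0.1), nu = fx$ind$nu, alpha = fx$ind$alpha,
                tau = fx$ind$tau)
  expect_true(is.finite(model$log_density(truth)))
  # out-of-support points are rejected
  truth$sigma_nu <- -1
  expect_identical(model$log_density(truth), -Inf)
})

test_that("perturbing one observed location shifts the density by the normal log-ratio", {
  fx <- fixture_dataset(P = 4, T = 25, seed = 43)
  cells <- summarize_dataset(fx$data, "standard", rt_scope = "all")
  model <- build_model(cells, model_spec(rt_scope = "all"))
  cells2 <- cells
  cells2$loc[1] <- cells$loc[1] + 0.1
  model2 <- build_model(cells2, model_spec(rt_scope = "all"))
  set.seed(78)
  pars <- random_point(4)
  mom <- forward_moments(ddm_params(pars$nu[1, 1], pars$alpha[1],
                                    pars$tau[1]))
  n <- model$data$nrt[1, 1]
  expected <- dnorm(cells2$loc[1], mom$mrt, sqrt(mom$vrt / n), log = TRUE) -
    dnorm(cells$loc[1], mom$mrt, sqrt(mom$vrt / n), log = TRUE)
  expect_equal(model2$log_density(pars) - model$log_density(pars), expected,
               tolerance = 1e-10)
})

test_that("build_model enforces its preconditions", {
  fx <- fixture_dataset(P = 3, T = 20, seed = 44)
  cells <- summarize_dataset(fx$data, "standard", rt_scope = "all")
  cells$n[1] <- 3
  expect_error(build_model(cells), "at least 4")
  cells <- summarize_dataset(fx$data, "standard", rt_scope = "all")
  expect_error(build_model(cells[cells$condition == 0 | cells$participant == 1, ]),
               "both conditions")
})

test_that("decision statistics follow their closed forms", {
  ft <- fake_fit(beta_mean = 0.4, beta_sd = 0.1)
  expect_equal(decision_statistic(ft, "z_abs"), 4)
  expect_equal(decision_statistic(ft, "savage_dickey_bf10"),
               dnorm(0, 0, 1) / dnorm(0, 0.4, 0.1), tolerance = 1e-12)
  # posterior equal to the prior carries no evidence either way
  ft1 <- fake_fit(beta_mean = 0, beta_sd = 1)
  expect_equal(decision_statistic(ft1, "savage_dickey_bf10"), 1)
  expect_error(decision_statistic(fake_fit(0.4, 0)), "posterior sd")
})

test_that("MCMC recovers the effect size on clean data and is seed-deterministic", {
  set.seed(91)
  ind <- draw_individuals(fixture_pop(mu_nu = 1, beta = 0.4), 20)
  d <- generate_dataset(ind, 60)
  cells <- summarize_dataset(d, "standard", rt_scope = "all")
  model <- build_model(cells, model_spec(rt_scope = "all"))
  ft <- suppressWarnings(fit_model(model, quick_mcmc(), seed = 12))
  expect_lt(abs(ft$beta_mean - 0.4), 3 * ft$beta_sd)
  expect_equal(nrow(ft$summary), 7)
  expect_true(all(is.finite(ft$summary$rhat)))
  expect_true(all(is.finite(ft$summary$ess)))
  ft2 <- suppressWarnings(fit_model(model, quick_mcmc(), seed = 12))
  expect_identical(ft$draws, ft2$draws)
  ft3 <- suppressWarnings(fit_model(model, quick_mcmc(), seed = 13))
  expect_false(identical(ft$draws, ft3$draws))
})
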