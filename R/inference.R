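# Hierarchical Bayesian EZ-diffusion inference.
#
# The model places a proxy likelihood on the per-cell summary statistics.
# With predicted moments (pc, mrt, vrt) = forward_moments(nu[p,k], alpha[p],
# tau[p]) for each participant-by-condition cell:
#
#   n_correct[p,k] ~ Binomial(n_total[p,k], pc)
#   loc[p,k]       ~ Normal(mrt, vrt / n)
#   scale[p,k]     ~ Normal(vrt, 2 vrt^2 / (n - 1))
#
# (the large-sample sampling distributions of the sample mean and the
# unbiased sample variance of n RTs).  The robust variant plugs the median
# and the IQR variance estimate into the identical structure.  The hierarchy
# is the same meta-regression the generator uses:
#
#   nu[p,k] ~ N(mu_nu + beta * X_k, sigma_nu^2)
#   alpha[p] ~ N(mu_alpha, sigma_alpha^2) truncated to (0, Inf)
#   tau[p]   ~ N(mu_tau, sigma_tau^2) truncated to (tau_floor, Inf)
#
# Posterior sampling is delegated to JAGS (rjags); the same joint log
# density is also exposed as a plain R function for testing and diagnostics.

#' Specify priors and model variant for the hierarchical EZ-DDM
#'
#' Hyperpriors are weakly informative and cover the generating ranges of the
#' simulation studies: normals for the population means (truncated to
#' positive support for boundary separation and non-decision time) and
#' half-normals for the population standard deviations.  The `beta` prior is
#' also the reference density of the Savage--Dickey Bayes factor, so it must
#' be proper with positive density at 0.
#'
#' @param method Summary method tag: `"standard"` or `"robust"`.
#' @param rt_scope RT scope tag: `"correct_only"` or `"all"` (recorded in
#'   results; the scope itself is applied in [summarize_dataset()]).
#' @param mu_nu_prior,beta_prior,mu_alpha_prior,mu_tau_prior Length-2
#'   vectors `c(location, scale)` of normal priors.
#' @param sigma_nu_sd,sigma_alpha_sd,sigma_tau_sd Scales of the half-normal
#'   priors on the population standard deviations.
#' @param tau_floor Lower truncation of individual non-decision times
#'   (seconds); matches the generator's floor.
#' @param s Diffusion coefficient (default 1).
#' @return An object of class `model_spec`.
#' @export
model_spec <- function(method = c("standard", "robust"),
                       rt_scope = c("correct_only", "all"),
                       mu_nu_prior = c(0, 2),
                       beta_prior = c(0, 1),
                       mu_alpha_prior = c(3, 1),
                       mu_tau_prior = c(0.3, 0.25),
                       sigma_nu_sd = 1, sigma_alpha_sd = 1, sigma_tau_sd = 1,
                       tau_floor = 0.05, s = 1) {
  method <- match.arg(method)
  rt_scope <- match.arg(rt_scope)
  for (nm in c("mu_nu_prior", "beta_prior", "mu_alpha_prior",
               "mu_tau_prior")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 2L || !all(is.finite(v)) || v[2] <= 0)
      stop_robez("'", nm, "' must be c(location, scale) with scale > 0")
  }
  check_scalar(sigma_nu_sd, "sigma_nu_sd", lower = 0, strict_lower = TRUE)
  check_scalar(sigma_alpha_sd, "sigma_alpha_sd", lower = 0,
               strict_lower = TRUE)
  check_scalar(sigma_tau_sd, "sigma_tau_sd", lower = 0, strict_lower = TRUE)
  check_scalar(tau_floor, "tau_floor", lower = 0)
  check_scalar(s, "s", lower = 0, strict_lower = TRUE)
  structure(list(method = method, rt_scope = rt_scope,
                 mu_nu_prior = mu_nu_prior, beta_prior = beta_prior,
                 mu_alpha_prior = mu_alpha_prior,
                 mu_tau_prior = mu_tau_prior, sigma_nu_sd = sigma_nu_sd,
                 sigma_alpha_sd = sigma_alpha_sd, sigma_tau_sd = sigma_tau_sd,
                 tau_floor = tau_floor, s = s),
            class = "model_spec")
}

hyper_names <- function() {
  c("mu_nu", "beta", "sigma_nu", "mu_alpha", "sigma_alpha", "mu_tau",
    "sigma_tau")
}

# JAGS translation of the model.  The EZ moment expressions are guarded by
# the same |k| < 0.05 series branch as ez_moments(): without it, the vrt
# expression loses all precision to cancellation near zero drift, which the
# slice sampler does visit.  pc is clamped away from {0, 1} before entering
# the binomial.
jags_model_string <- function(spec) {
  sprintf('
model {
  mu_nu ~ dnorm(%g, %g)
  beta ~ dnorm(%g, %g)
  mu_alpha ~ dnorm(%g, %g) T(0,)
  mu_tau ~ dnorm(%g, %g) T(0,)
  sigma_nu ~ dnorm(0, %g) T(0,)
  sigma_alpha ~ dnorm(0, %g) T(0,)
  sigma_tau ~ dnorm(0, %g) T(0,)
  prec_nu <- 1 / pow(sigma_nu, 2)
  prec_alpha <- 1 / pow(sigma_alpha, 2)
  prec_tau <- 1 / pow(sigma_tau, 2)
  for (p in 1:P) {
    alpha_p[p] ~ dnorm(mu_alpha, prec_alpha) T(0,)
    tau_p[p] ~ dnorm(mu_tau, prec_tau) T(%g,)
    for (k in 1:K) {
      nu_pk[p, k] ~ dnorm(mu_nu + beta * X[k], prec_nu)
      kap[p, k] <- alpha_p[p] * nu_pk[p, k] / %g
      pc[p, k] <- 1 / (1 + exp(-kap[p, k]))
      pcb[p, k] <- max(min(pc[p, k], 1 - 1e-9), 1e-9)
      mrt[p, k] <- tau_p[p] + ifelse(abs(kap[p, k]) < 0.05,
        (pow(alpha_p[p], 2) / %g) *
          (1 - pow(kap[p, k], 2) / 12 + pow(kap[p, k], 4) / 120),
        (alpha_p[p] / (2 * nu_pk[p, k])) * (2 * pc[p, k] - 1))
      vrt[p, k] <- ifelse(abs(kap[p, k]) < 0.05,
        (pow(alpha_p[p], 4) / %g) *
          (1 - pow(kap[p, k], 2) / 5 + 17 * pow(kap[p, k], 4) / 560),
        (alpha_p[p] * %g / pow(nu_pk[p, k], 3)) *
          (pc[p, k] - 0.5 - kap[p, k] * pc[p, k] * (1 - pc[p, k])))
      nc[p, k] ~ dbin(pcb[p, k], ntot[p, k])
      loc[p, k] ~ dnorm(mrt[p, k], nrt[p, k] / vrt[p, k])
      scl[p, k] ~ dnorm(vrt[p, k], (nrt[p, k] - 1) / (2 * pow(vrt[p, k], 2)))
    }
  }
}',
    spec$mu_nu_prior[1], 1 / spec$mu_nu_prior[2]^2,
    spec$beta_prior[1], 1 / spec$beta_prior[2]^2,
    spec$mu_alpha_prior[1], 1 / spec$mu_alpha_prior[2]^2,
    spec$mu_tau_prior[1], 1 / spec$mu_tau_prior[2]^2,
    1 / spec$sigma_nu_sd^2, 1 / spec$sigma_alpha_sd^2, 1 / spec$sigma_tau_sd^2,
    spec$tau_floor, spec$s^2, 4 * spec$s^2, 24 * spec$s^4, spec$s^2)
}

# Reshape summary cells (long data.frame) into P x 2 matrices.
cells_to_matrices <- function(cells) {
  parts <- sort(unique(cells$participant))
  conds <- sort(unique(cells$condition))
  if (length(conds) != 2L)
    stop_robez("every participant must contribute exactly two conditions")
  get <- function(col) {
    m <- matrix(NA_real_, length(parts), 2L)
    for (j in 1:2) {
      sub <- cells[cells$condition == conds[j], ]
      sub <- sub[match(parts, sub$participant), ]
      m[, j] <- sub[[col]]
    }
    m
  }
  mats <- list(participants = parts, nc = get("n_correct"),
               ntot = get("n_total"), nrt = get("n"), loc = get("loc"),
               scl = get("scale"))
  if (anyNA(mats$nc) || anyNA(mats$loc) || anyNA(mats$scl))
    stop_robez("every participant must contribute both conditions")
  mats
}

dnorm_trunc_log <- function(x, mean, sd, lower) {
  ifelse(x <= lower, -Inf,
         dnorm(x, mean, sd, log = TRUE) -
           pnorm(lower, mean, sd, lower.tail = FALSE, log.p = TRUE))
}

#' Build a hierarchical EZ-DDM model from summary cells
#'
#' Assembles the proxy-likelihood model for a set of per-cell summary
#' statistics: the JAGS program, the data block, and an R function
#' evaluating the joint log density (hyperpriors + hierarchy + proxy
#' likelihood) at any point, used for testing and diagnostics.
#'
#' @param cells A [summarize_dataset()] result (or equivalent `data.frame`);
#'   every participant must contribute both conditions and every cell at
#'   least 4 RTs.
#' @param spec A [model_spec()].
#' @return An object of class `hez_model`: list with elements `spec`,
#'   `data` (JAGS data block), `jags_code`, `P`, `participants`, and
#'   `log_density(pars)` where `pars` is a list with elements `mu_nu`,
#'   `beta`, `mu_alpha`, `mu_tau`, `sigma_nu`, `sigma_alpha`, `sigma_tau`,
#'   `nu` (P x 2), `alpha`, `tau` (length P).
#' @export
build_model <- function(cells, spec = model_spec()) {
  if (!inherits(spec, "model_spec"))
    stop_robez("'spec' must be a model_spec object")
  if (any(cells$n < 4L))
    stop_robez("all cells must have at least 4 RTs")
  m <- cells_to_matrices(cells)
  P <- length(m$participants)
  data <- list(P = P, K = 2L, X = c(0, 1), nc = m$nc, ntot = m$ntot,
               nrt = m$nrt, loc = m$loc, scl = m$scl)
  s <- spec$s
  floor_tau <- spec$tau_floor

  log_density <- function(pars) {
    with(pars, {
      if (any(c(sigma_nu, sigma_alpha, sigma_tau) <= 0) ||
          mu_alpha <= 0 || mu_tau <= 0 || any(alpha <= 0) ||
          any(tau <= floor_tau))
        return(-Inf)
      lp <- dnorm(mu_nu, spec$mu_nu_prior[1], spec$mu_nu_prior[2],
                  log = TRUE) +
        dnorm(beta, spec$beta_prior[1], spec$beta_prior[2], log = TRUE) +
        dnorm_trunc_log(mu_alpha, spec$mu_alpha_prior[1],
                        spec$mu_alpha_prior[2], 0) +
        dnorm_trunc_log(mu_tau, spec$mu_tau_prior[1], spec$mu_tau_prior[2],
                        0) +
        dnorm_trunc_log(sigma_nu, 0, spec$sigma_nu_sd, 0) +
        dnorm_trunc_log(sigma_alpha, 0, spec$sigma_alpha_sd, 0) +
        dnorm_trunc_log(sigma_tau, 0, spec$sigma_tau_sd, 0)
      for (k in 1:2) {
        lp <- lp + sum(dnorm(nu[, k], mu_nu + beta * (k - 1), sigma_nu,
                             log = TRUE))
      }
      lp <- lp + sum(dnorm_trunc_log(alpha, mu_alpha, sigma_alpha, 0)) +
        sum(dnorm_trunc_log(tau, mu_tau, sigma_tau, floor_tau))
      for (k in 1:2) {
        mom <- ez_moments(nu[, k], alpha, tau, s)
        pc <- pmin(pmax(mom$pc, 1e-9), 1 - 1e-9)
        lp <- lp + sum(dbinom(m$nc[, k], m$ntot[, k], pc, log = TRUE)) +
          sum(dnorm(m$loc[, k], mom$mrt, sqrt(mom$vrt / m$nrt[, k]),
                    log = TRUE)) +
          sum(dnorm(m$scl[, k], mom$vrt,
                    sqrt(2 * mom$vrt^2 / (m$nrt[, k] - 1)), log = TRUE))
      }
      lp
    })
  }

  structure(list(spec = spec, data = data, jags_code = jags_model_string(spec),
                 P = P, participants = m$participants,
                 log_density = log_density),
            class = "hez_model")
}

#' MCMC settings
#'
#' @param chains Number of chains (>= 2 for convergence diagnostics).
#' @param adapt JAGS adaptation iterations.
#' @param warmup Burn-in iterations discarded after adaptation.
#' @param draws Retained iterations per chain.
#' @return A list of class `mcmc_control`.
#' @export
mcmc_control <- function(chains = 4, adapt = 500, warmup = 1000,
                         draws = 1000) {
  structure(list(chains = check_count(chains, "chains"),
                 adapt = check_count(adapt, "adapt", min = 100L),
                 warmup = check_count(warmup, "warmup", min = 0L),
                 draws = check_count(draws, "draws", min = 100L)),
            class = "mcmc_control")
}

# Method-of-moments starting values from edge-corrected EZ inversion,
# clamped into the support of the hierarchy.
ez_inits <- function(model) {
  d <- model$data
  spec <- model$spec
  P <- model$P
  nu0 <- matrix(0.5, P, 2)
  alpha0 <- rep(3, P)
  tau0 <- rep(max(0.25, spec$tau_floor + 0.05), P)
  for (p in seq_len(P)) {
    for (k in 1:2) {
      est <- try({
        pc <- edge_correct_pc(d$nc[p, k] / d$ntot[p, k], d$ntot[p, k])
        inverse_ez(pc, d$loc[p, k], max(d$scl[p, k], 1e-4), s = spec$s)
      }, silent = TRUE)
      if (!inherits(est, "try-error") && is.finite(est$nu)) {
        nu0[p, k] <- min(max(est$nu, -6), 6)
        if (abs(nu0[p, k]) < 0.1) nu0[p, k] <- 0.1 * sign(nu0[p, k] + 1e-9)
        if (k == 1L) {
          alpha0[p] <- min(max(est$alpha, 0.5), 6)
          tau0[p] <- min(max(est$tau, spec$tau_floor + 0.01), 1.5)
        }
      }
    }
  }
  list(nu = nu0, alpha = alpha0, tau = tau0)
}

#' Fit a hierarchical EZ-DDM model by MCMC
#'
#' Runs JAGS on the model with method-of-moments starting values, collects
#' hyperparameter draws, and computes convergence diagnostics (split chains
#' are not used; potential scale reduction is computed across chains).
#' Results are fully reproducible given `seed`: chain RNG streams and
#' starting values are derived from it.
#'
#' @param model A [build_model()] result.
#' @param mcmc An [mcmc_control()].
#' @param seed Integer seed for the sampler.
#' @param monitor_individuals If `TRUE`, also retain draws of the
#'   individual-level parameters (larger output).
#' @param quiet Suppress JAGS progress output (default `TRUE`).
#' @return An object of class `hez_fit`: list with `draws` (matrix,
#'   iterations x hyperparameters), `summary` (data.frame with posterior
#'   mean/sd/quantiles, Rhat, effective sample size per hyperparameter),
#'   `beta_mean`, `beta_sd`, `converged` (all Rhat <= 1.05), `max_rhat`,
#'   `spec`, `mcmc`, `seed`, and optionally `individual_draws`.
#' @export
fit_model <- function(model, mcmc = mcmc_control(), seed = 1,
                      monitor_individuals = FALSE, quiet = TRUE) {
  if (!inherits(model, "hez_model"))
    stop_robez("'model' must be a hez_model object")
  seed <- check_count(seed, "seed", min = 0L)
  spec <- model$spec
  base_inits <- ez_inits(model)
  inits <- lapply(seq_len(mcmc$chains), function(ch) {
    # small deterministic jitter so chains start dispersed
    set.seed(derive_seed(seed, "init", ch))
    list(mu_nu = mean(base_inits$nu) + rnorm(1, 0, 0.2),
         beta = rnorm(1, 0, 0.1),
         mu_alpha = max(mean(base_inits$alpha) + rnorm(1, 0, 0.2), 0.5),
         mu_tau = max(mean(base_inits$tau) + rnorm(1, 0, 0.02),
                      spec$tau_floor + 0.02),
         sigma_nu = runif(1, 0.5, 1.2), sigma_alpha = runif(1, 0.4, 1),
         sigma_tau = runif(1, 0.1, 0.4),
         nu_pk = base_inits$nu, alpha_p = base_inits$alpha,
         tau_p = base_inits$tau,
         .RNG.name = "base::Mersenne-Twister",
         .RNG.seed = derive_seed(seed, "chain", ch))
  })
  jm <- rjags::jags.model(textConnection(model$jags_code),
                          data = model$data, inits = inits,
                          n.chains = mcmc$chains, n.adapt = mcmc$adapt,
                          quiet = quiet)
  if (mcmc$warmup > 0)
    update(jm, mcmc$warmup, progress.bar = "none")
  monitors <- hyper_names()
  if (monitor_individuals)
    monitors <- c(monitors, "nu_pk", "alpha_p", "tau_p")
  samp <- rjags::coda.samples(jm, monitors, n.iter = mcmc$draws,
                              progress.bar = "none")

  hy <- hyper_names()
  draws_mat <- do.call(rbind, lapply(samp, function(ch) as.matrix(ch)[, hy]))
  post_mean <- colMeans(draws_mat)
  post_sd <- apply(draws_mat, 2, sd)
  qs <- t(apply(draws_mat, 2, quantile, probs = c(0.025, 0.5, 0.975)))
  rhat <- rep(NA_real_, length(hy))
  if (mcmc$chains >= 2) {
    gd <- try(coda::gelman.diag(samp[, hy, drop = FALSE],
                                multivariate = FALSE, autoburnin = FALSE),
              silent = TRUE)
    if (!inherits(gd, "try-error")) rhat <- gd$psrf[hy, 1]
  }
  ess <- as.numeric(coda::effectiveSize(samp[, hy, drop = FALSE])[hy])
  summ <- data.frame(parameter = hy, mean = post_mean, sd = post_sd,
                     q2.5 = qs[, 1], q50 = qs[, 2], q97.5 = qs[, 3],
                     rhat = rhat, ess = ess, row.names = NULL)
  max_rhat <- suppressWarnings(max(rhat, na.rm = TRUE))
  converged <- is.finite(max_rhat) && max_rhat <= 1.05
  if (!converged)
    warning("fit flagged as non-converged (max Rhat = ",
            signif(max_rhat, 4), ")", call. = FALSE)
  out <- list(draws = draws_mat, summary = summ,
              beta_mean = unname(post_mean["beta"]),
              beta_sd = unname(post_sd["beta"]),
              converged = converged, max_rhat = max_rhat, spec = spec,
              mcmc = mcmc, seed = seed)
  if (monitor_individuals)
    out$individual_draws <- do.call(rbind, lapply(samp, as.matrix))
  class(out) <- "hez_fit"
  out
}

#' @export
print.hez_fit <- function(x, ...) {
  cat(sprintf("Hierarchical EZ-DDM fit (%s summaries, %d draws, %s)\n",
              x$spec$method, nrow(x$draws),
              if (x$converged) "converged" else "NOT converged"))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Evidence statistic for the condition effect
#'
#' Computes a scalar evidence value for the test of `beta = 0`.
#' `"z_abs"` is the absolute posterior z score
#' `|mean(beta)| / sd(beta)`; `"savage_dickey_bf10"` is the Savage--Dickey
#' Bayes factor in favor of an effect, the prior density of `beta` at 0
#' divided by its posterior density at 0 (posterior density under a normal
#' approximation from the posterior mean and sd).  Both are monotone
#' orderings of the evidence, so ROC analyses are unaffected by the choice.
#'
#' @param fit A [fit_model()] result.
#' @param kind `"z_abs"` (default) or `"savage_dickey_bf10"`.
#' @return A single nonnegative number; larger = more evidence for an
#'   effect.
#' @export
decision_statistic <- function(fit, kind = c("z_abs", "savage_dickey_bf10")) {
  kind <- match.arg(kind)
  if (!inherits(fit, "hez_fit"))
    stop_robez("'fit' must be a hez_fit object")
  if (!is.finite(fit$beta_sd) || fit$beta_sd <= 0)
    stop_robez("posterior sd of beta is zero or non-finite")
  if (kind == "z_abs") {
    abs(fit$beta_mean) / fit$beta_sd
  } else {
    prior <- fit$spec$beta_prior
    dnorm(0, prior[1], prior[2]) / dnorm(0, fit$beta_mean, fit$beta_sd)
  }
}
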