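# Hierarchical two-condition data generator.  Individual drift rates follow
# a meta-regression on the condition indicator X_k in {0, 1}:
#   nu_pred[p,k] = mu_nu + beta * X_k
#   nu[p,k] ~ N(nu_pred[p,k], sigma2_nu)
#   alpha[p] ~ N(mu_alpha, sigma2_alpha),  tau[p] ~ N(mu_tau, sigma2_tau)
# and trial-level data are Wiener first-passage draws per participant and
# condition, optionally passed through a two-stage contamination procedure.

.presets <- list(
  "main"               = list(nu = c(-3, 3), alpha = c(2, 4)),
  "low-nu/low-alpha"   = list(nu = c(0, 1),  alpha = c(2, 2.5)),
  "low-nu/high-alpha"  = list(nu = c(0, 1),  alpha = c(3.5, 4)),
  "high-nu/low-alpha"  = list(nu = c(2, 3),  alpha = c(2, 2.5)),
  "high-nu/high-alpha" = list(nu = c(2, 3),  alpha = c(3.5, 4))
)

#' Population-level (hyper)parameters of the data-generating model
#'
#' @param mu_nu Population drift-rate intercept.
#' @param beta Condition effect on drift (the parameter under test).
#' @param mu_alpha,mu_tau Population means of boundary separation (> 0) and
#'   non-decision time (> 0 s).
#' @param sigma2_nu,sigma2_alpha,sigma2_tau Population variances (> 0).
#'   Defaults are the fixed values used throughout the simulation studies.
#' @return An object of class `population_params`.
#' @export
population_params <- function(mu_nu, beta, mu_alpha, mu_tau,
                              sigma2_nu = 0.75, sigma2_alpha = 0.5,
                              sigma2_tau = 0.1) {
  check_scalar(mu_nu, "mu_nu")
  check_scalar(beta, "beta")
  check_scalar(mu_alpha, "mu_alpha", lower = 0, strict_lower = TRUE)
  check_scalar(mu_tau, "mu_tau", lower = 0, strict_lower = TRUE)
  check_scalar(sigma2_nu, "sigma2_nu", lower = 0, strict_lower = TRUE)
  check_scalar(sigma2_alpha, "sigma2_alpha", lower = 0, strict_lower = TRUE)
  check_scalar(sigma2_tau, "sigma2_tau", lower = 0, strict_lower = TRUE)
  structure(list(mu_nu = mu_nu, beta = beta, mu_alpha = mu_alpha,
                 mu_tau = mu_tau, sigma2_nu = sigma2_nu,
                 sigma2_alpha = sigma2_alpha, sigma2_tau = sigma2_tau),
            class = "population_params")
}

#' List the available simulation presets
#' @return Character vector of preset names accepted by [draw_population()].
#' @export
study_presets <- function() names(.presets)

#' Draw population-level parameters for a simulation preset
#'
#' The `main` preset draws `mu_nu ~ U(-3, 3)` and `mu_alpha ~ U(2, 4)`.  The
#' four follow-up presets cross low/high drift intercepts
#' (`U(0, 1)` / `U(2, 3)`) with low/high boundary separation
#' (`U(2, 2.5)` / `U(3.5, 4)`).  All presets draw `mu_tau ~ U(0.2, 0.4)` and
#' fix the variances at `sigma2_nu = 0.75`, `sigma2_alpha = 0.5`,
#' `sigma2_tau = 0.1`.
#'
#' @param preset One of [study_presets()].
#' @param beta True condition effect on drift.
#' @return A [population_params()] object.
#' @examples
#' set.seed(1)
#' draw_population("main", beta = 0.4)
#' @export
draw_population <- function(preset = "main", beta = 0) {
  if (length(preset) != 1L || !preset %in% names(.presets))
    stop_robez("unknown preset '", preset, "'; available: ",
               paste(names(.presets), collapse = ", "))
  rg <- .presets[[preset]]
  population_params(mu_nu = runif(1, rg$nu[1], rg$nu[2]),
                    beta = beta,
                    mu_alpha = runif(1, rg$alpha[1], rg$alpha[2]),
                    mu_tau = runif(1, 0.2, 0.4))
}

# Draw from N(mean, sd) until all values exceed `lower` (strict).  This is
# exact sampling from the truncated normal; the acceptance rate is high for
# all parameter ranges used here.
rnorm_trunc <- function(n, mean, sd, lower) {
  x <- rnorm(n, mean, sd)
  bad <- which(x <= lower)
  while (length(bad)) {
    x[bad] <- rnorm(length(bad), mean, sd)
    bad <- bad[x[bad] <= lower]
  }
  x
}

#' Draw individual-level diffusion parameters
#'
#' Samples person-by-condition drift rates from the meta-regression
#' structure and person-level boundary separations and non-decision times
#' from their population normals.  Boundary separations are redrawn until
#' positive and non-decision times until at least `tau_floor`, i.e. they are
#' sampled from the corresponding truncated normals.
#'
#' @param pop A [population_params()] object.
#' @param P Number of participants (>= 1).
#' @param tau_floor Lower truncation for non-decision time (seconds,
#'   default 0.05).
#' @return An object of class `individual_params`: list with `nu` (P x 2
#'   matrix; column k for condition k-1), `alpha`, `tau` (length-P vectors),
#'   plus `pop` and `tau_floor`.
#' @export
draw_individuals <- function(pop, P, tau_floor = 0.05) {
  if (!inherits(pop, "population_params"))
    stop_robez("'pop' must be a population_params object")
  P <- check_count(P, "P")
  check_scalar(tau_floor, "tau_floor", lower = 0)
  nu <- cbind(rnorm(P, pop$mu_nu, sqrt(pop$sigma2_nu)),
              rnorm(P, pop$mu_nu + pop$beta, sqrt(pop$sigma2_nu)))
  alpha <- rnorm_trunc(P, pop$mu_alpha, sqrt(pop$sigma2_alpha), 0)
  tau <- rnorm_trunc(P, pop$mu_tau, sqrt(pop$sigma2_tau), tau_floor)
  structure(list(nu = nu, alpha = alpha, tau = tau, pop = pop,
                 tau_floor = tau_floor),
            class = "individual_params")
}

#' Generate a clean trial-level dataset
#'
#' For each participant and condition, draws `T` Wiener first-passage trials
#' with that cell's drift rate and the participant's boundary separation and
#' non-decision time.
#'
#' @param ind An [draw_individuals()] result.
#' @param T Trials per participant per condition (>= 1).
#' @param s Diffusion coefficient (default 1).
#' @param dt Euler step size for the Wiener sampler (default 1e-3 s).
#' @return A `data.frame` with columns `participant` (1..P), `condition`
#'   (0/1), `rt` (s), `accuracy` (0/1), and `contaminant`
#'   (all `"none"`).
#' @export
generate_dataset <- function(ind, T, s = 1, dt = 1e-3) {
  if (!inherits(ind, "individual_params"))
    stop_robez("'ind' must be an individual_params object")
  T <- check_count(T, "T")
  P <- length(ind$alpha)
  out <- vector("list", P * 2L)
  for (p in seq_len(P)) {
    for (k in 0:1) {
      pars <- ddm_params(nu = ind$nu[p, k + 1L], alpha = ind$alpha[p],
                         tau = ind$tau[p], s = s)
      tr <- sample_trials(pars, T, dt = dt)
      out[[(p - 1L) * 2L + k + 1L]] <-
        data.frame(participant = p, condition = k, rt = tr$rt,
                   accuracy = tr$accuracy, contaminant = "none",
                   stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Replace a fraction of trials with contaminants
#'
#' Applies the two-stage contamination procedure to a clean dataset.  In
#' every participant-by-condition cell, exactly `round(rate * T)` trials are
#' selected uniformly without replacement.  Each selected trial is,
#' independently with probability 1/2, a \emph{delayed startup} -- uniform
#' noise between 2 and 3 seconds is added to its RT, accuracy unchanged --
#' and otherwise a \emph{guess}: the trial is redrawn from the Wiener
#' process with the drift rate set to 0 (keeping the participant's boundary
#' separation and non-decision time), which yields chance-level accuracy.
#' All unselected trials are returned bit-identical to the input.
#'
#' @param data A clean dataset from [generate_dataset()] (all `contaminant`
#'   tags `"none"`).
#' @param ind The [draw_individuals()] object the data were generated from
#'   (supplies each participant's `alpha` and `tau` for guess redraws).
#' @param rate Contamination proportion per cell, in `[0, 0.5]`
#'   (default 0.05).
#' @param s,dt Passed to the Wiener sampler for guess redraws.
#' @return The dataset with contaminated rows replaced and tagged
#'   `"delayed"` or `"guess"`.
#' @export
contaminate <- function(data, ind, rate = 0.05, s = 1, dt = 1e-3) {
  if (!inherits(ind, "individual_params"))
    stop_robez("'ind' must be an individual_params object")
  check_scalar(rate, "rate", lower = 0, upper = 0.5)
  if (!all(data$contaminant == "none"))
    stop_robez("'data' already contains contaminant tags")
  if (rate == 0) return(data)
  out <- data
  cells <- split(seq_len(nrow(data)),
                 list(data$participant, data$condition), drop = TRUE)
  # deterministic cell order (participant-major) so results depend only on
  # the RNG state, not on split()'s label ordering
  ord <- order(vapply(cells, function(i) data$participant[i[1]], 0),
               vapply(cells, function(i) data$condition[i[1]], 0))
  for (idx in cells[ord]) {
    m <- round(rate * length(idx))
    if (m == 0L) next
    pick <- idx[sample.int(length(idx), m)]
    p <- data$participant[pick[1]]
    for (i in pick) {
      if (runif(1) < 0.5) {
        out$rt[i] <- out$rt[i] + runif(1, 2, 3)
        out$contaminant[i] <- "delayed"
      } else {
        g <- sample_trials(ddm_params(nu = 0, alpha = ind$alpha[p],
                                      tau = ind$tau[p], s = s), 1, dt = dt)
        out$rt[i] <- g$rt
        out$accuracy[i] <- g$accuracy
        out$contaminant[i] <- "guess"
      }
    }
  }
  out
}
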