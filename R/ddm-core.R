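# Closed-form EZ-diffusion moment equations and Wiener first-passage
# sampling.  Parameterization: drift rate nu (signed, evidence/s), boundary
# separation alpha (> 0), non-decision time tau (>= 0, seconds), diffusion
# coefficient s (evidence/sqrt(s); model-wide constant, default 1).  The
# start point is fixed at alpha/2 (unbiased process).

#' Construct a diffusion-model parameterization
#'
#' Bundles the three EZ-diffusion parameters for one participant-condition
#' cell, plus the diffusion coefficient, with validation.
#'
#' @param nu Drift rate (signed; evidence units per second).
#' @param alpha Boundary separation (> 0; evidence units).
#' @param tau Non-decision time (>= 0; seconds).
#' @param s Diffusion coefficient (> 0; default 1).
#' @return An object of class `ddm_params`.
#' @examples
#' ddm_params(nu = 1, alpha = 2, tau = 0.3)
#' @export
ddm_params <- function(nu, alpha, tau, s = 1) {
  check_scalar(nu, "nu")
  check_scalar(alpha, "alpha", lower = 0, strict_lower = TRUE)
  check_scalar(tau, "tau", lower = 0)
  check_scalar(s, "s", lower = 0, strict_lower = TRUE)
  structure(list(nu = nu, alpha = alpha, tau = tau, s = s),
            class = "ddm_params")
}

#' @export
print.ddm_params <- function(x, ...) {
  cat(sprintf("DDM parameters: nu = %g, alpha = %g, tau = %g (s = %g)\n",
              x$nu, x$alpha, x$tau, x$s))
  invisible(x)
}

# Vectorized EZ forward equations.  With k = alpha*nu/s^2:
#   pc  = logistic(k)
#   mrt = tau + (alpha / (2 nu)) * (2 pc - 1)
#   vrt = (alpha s^2 / nu^3) * (pc - 1/2 - k pc (1 - pc))
# The mrt and vrt expressions are 0/0 at nu = 0 and lose all precision to
# cancellation for small |k|, so below |k| = 0.05 we switch to Taylor
# expansions (accurate to ~1e-10 relative at the switch point):
#   mrt = tau + alpha^2/(4 s^2) * (1 - k^2/12 + k^4/120)
#   vrt = alpha^4/(24 s^4) * (1 - k^2/5 + 17 k^4/560)
ez_moments <- function(nu, alpha, tau, s = 1) {
  k <- alpha * nu / s^2
  pc <- plogis(k)
  small <- abs(k) < 0.05
  mrt <- ifelse(small,
                tau + (alpha^2 / (4 * s^2)) * (1 - k^2 / 12 + k^4 / 120),
                tau + (alpha / (2 * nu)) * (2 * pc - 1))
  vrt <- ifelse(small,
                (alpha^4 / (24 * s^4)) * (1 - k^2 / 5 + 17 * k^4 / 560),
                (alpha * s^2 / nu^3) * (pc - 0.5 - k * pc * (1 - pc)))
  list(pc = pc, mrt = mrt, vrt = vrt)
}

#' EZ-diffusion forward moment equations
#'
#' Computes the exact decision-process moments of an unbiased Wiener
#' diffusion: the probability of a correct (upper-boundary) response, the
#' mean RT, and the RT variance.  The function is continuous in the drift
#' rate across zero; at `nu = 0` it returns the series limits
#' `pc = 1/2`, `mrt = tau + alpha^2/(4 s^2)`, `vrt = alpha^4/(24 s^4)`.
#'
#' @param params A [ddm_params()] object.
#' @return A list of class `moment_triple` with elements `pc` (in (0,1)),
#'   `mrt` (seconds), `vrt` (seconds squared).
#' @examples
#' forward_moments(ddm_params(nu = 1, alpha = 2, tau = 0.3))
#' @seealso [inverse_ez()] for the inverse mapping.
#' @export
forward_moments <- function(params) {
  if (!inherits(params, "ddm_params"))
    stop_robez("'params' must be a ddm_params object")
  m <- ez_moments(params$nu, params$alpha, params$tau, params$s)
  structure(m, class = "moment_triple")
}

# Classical EZ edge correction for observed accuracy rates of exactly
# 0, 1/2, or 1, given the trial count n.  Only intended for method-of-moments
# diagnostics and MCMC starting values; never used inside the proxy
# likelihood.
edge_correct_pc <- function(pc, n) {
  n <- check_count(n, "n")
  ifelse(pc <= 0, 1 / (2 * n),
         ifelse(pc >= 1, 1 - 1 / (2 * n),
                ifelse(pc == 0.5, 0.5 + 1 / (4 * n), pc)))
}

#' EZ-diffusion inverse (method-of-moments) equations
#'
#' Maps an observed or predicted moment triple back to the diffusion
#' parameters.  With `L = log(pc / (1 - pc))`:
#' \deqn{\nu = \mathrm{sign}(pc - 1/2)\, s\, [L (pc^2 L - pc L + pc - 1/2)/vrt]^{1/4}}
#' \deqn{\alpha = s^2 L / \nu, \quad
#'       \tau = mrt - (\alpha/(2\nu)) (2 pc - 1).}
#' This is the exact inverse of [forward_moments()] on its range.
#'
#' An accuracy of exactly 0, 1/2, or 1 makes the inversion undefined.  If a
#' trial count `n` is supplied, the classical edge correction is applied
#' first (`0 -> 1/(2n)`, `1 -> 1 - 1/(2n)`, `1/2 -> 1/2 + 1/(4n)`); otherwise
#' these inputs raise an error.  Edge-corrected estimates are meant for
#' diagnostics and starting values only.
#'
#' @param pc Accuracy rate, in (0, 1).
#' @param mrt Mean (or median) RT in seconds.
#' @param vrt RT variance in seconds squared (> 0).
#' @param s Diffusion coefficient (default 1).
#' @param n Optional trial count enabling the edge correction.
#' @return A [ddm_params()] object.
#' @examples
#' m <- forward_moments(ddm_params(nu = 1, alpha = 2, tau = 0.3))
#' inverse_ez(m$pc, m$mrt, m$vrt)
#' @export
inverse_ez <- function(pc, mrt, vrt, s = 1, n = NULL) {
  check_scalar(pc, "pc", lower = 0, upper = 1)
  check_scalar(mrt, "mrt")
  check_scalar(vrt, "vrt", lower = 0, strict_lower = TRUE)
  check_scalar(s, "s", lower = 0, strict_lower = TRUE)
  if (!is.null(n)) pc <- edge_correct_pc(pc, n)
  if (pc <= 0 || pc >= 1 || pc == 0.5)
    stop_robez("pc of exactly 0, 1/2, or 1 is not invertible; ",
               "supply the trial count 'n' to enable the edge correction")
  L <- qlogis(pc)
  x <- L * (pc^2 * L - pc * L + pc - 0.5) / vrt
  nu <- sign(pc - 0.5) * s * x^(1 / 4)
  alpha <- s^2 * L / nu
  tau <- mrt - (alpha / (2 * nu)) * (2 * pc - 1)
  ddm_params(nu = nu, alpha = alpha, tau = tau, s = s)
}

#' Sample trial-level data from a Wiener diffusion process
#'
#' Draws `n` independent first-passage times of a Wiener process with
#' absorbing boundaries at 0 and `alpha`, start point `alpha/2`, drift `nu`
#' and diffusion coefficient `s`.  The response time is the decision time
#' plus the non-decision time `tau`; accuracy is 1 iff the upper boundary is
#' hit.  Simulation uses an Euler--Maruyama scheme with Brownian-bridge
#' interval-crossing correction, which removes the leading
#' \eqn{O(\sqrt{dt})} boundary-crossing bias of the plain scheme; the
#' residual discretization bias is \eqn{O(dt)}.
#'
#' Randomness is drawn from R's global random number generator, so results
#' are reproducible under [set.seed()].
#'
#' @param params A [ddm_params()] object.
#' @param n Number of trials (>= 1).
#' @param dt Euler step size in seconds (default 1e-3).
#' @return A `data.frame` with columns `rt` (seconds, all `> tau`) and
#'   `accuracy` (0/1).
#' @examples
#' set.seed(1)
#' trials <- sample_trials(ddm_params(nu = 1, alpha = 2, tau = 0.3), n = 10)
#' @export
sample_trials <- function(params, n, dt = 1e-3) {
  if (!inherits(params, "ddm_params"))
    stop_robez("'params' must be a ddm_params object")
  n <- check_count(n, "n")
  check_scalar(dt, "dt", lower = 0, strict_lower = TRUE)
  res <- wiener_sample_cpp(n, params$nu, params$alpha, params$tau, params$s,
                           dt)
  data.frame(rt = res$rt, accuracy = res$accuracy)
}
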