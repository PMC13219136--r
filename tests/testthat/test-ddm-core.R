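test_that("forward moments match hand-computed values and the zero-drift limit", {
  m <- forward_moments(ddm_params(nu = 1, alpha = 2, tau = 0.3))
  expect_equal(m$pc, plogis(2))
  expect_equal(m$mrt, 0.3 + tanh(1), tolerance = 1e-12)
  expect_equal(m$vrt, 2 * (plogis(2) - 0.5 - 2 * plogis(2) * (1 - plogis(2))),
               tolerance = 1e-12)
  # zero drift: series limits
  m0 <- forward_moments(ddm_params(nu = 0, alpha = 2, tau = 0.3))
  expect_equal(m0$pc, 0.5)
  expect_equal(m0$mrt, 1.3)
  expect_equal(m0$vrt, 16 / 24)
})

test_that("forward moments are continuous across zero drift and the series switch", {
  a <- 2.7; tau <- 0.25
  lim <- forward_moments(ddm_params(0, a, tau))
  near <- forward_moments(ddm_params(1e-7, a, tau))
  expect_equal(near$mrt, lim$mrt, tolerance = 1e-10)
  expect_equal(near$vrt, lim$vrt, tolerance = 1e-10)
  # just below / above the |k| = 0.05 branch point
  nu_lo <- 0.049 / a; nu_hi <- 0.051 / a
  lo <- forward_moments(ddm_params(nu_lo, a, tau))
  hi <- forward_moments(ddm_params(nu_hi, a, tau))
  mid <- forward_moments(ddm_params(0.05 / a, a, tau))
  expect_true(lo$vrt > mid$vrt && mid$vrt > hi$vrt)
  expect_lt(abs(lo$vrt - hi$vrt) / lo$vrt, 1e-3)
})

test_that("moments are symmetric in drift sign and monotone in the parameters", {
  pos <- forward_moments(ddm_params(1, 2, 0.3))
  neg <- forward_moments(ddm_params(-1, 2, 0.3))
  expect_equal(neg$pc, 1 - pos$pc, tolerance = 1e-14)
  expect_equal(neg$mrt, pos$mrt, tolerance = 1e-14)
  expect_equal(neg$vrt, pos$vrt, tolerance = 1e-14)
  # pc strictly increasing in nu at fixed alpha
  nus <- seq(-3, 3, by = 0.5)
  pcs <- vapply(nus, function(nu) forward_moments(ddm_params(nu, 2, 0.3))$pc, 0)
  expect_true(all(diff(pcs) > 0))
  # mrt strictly increasing in alpha at fixed nu > 0
  alphas <- seq(1, 4, by = 0.25)
  mrts <- vapply(alphas,
                 function(a) forward_moments(ddm_params(1, a, 0.3))$mrt, 0)
  expect_true(all(diff(mrts) > 0))
})

test_that("inverse_ez round-trips forward_moments over the study ranges", {
  set.seed(101)
  for (i in 1:100) {
    nu <- runif(1, -3, 3)
    if (abs(nu) < 1e-3) nu <- 1e-3  # exact inversion is undefined at nu = 0
    p <- ddm_params(nu, runif(1, 2, 4), runif(1, 0.2, 0.4))
    m <- forward_moments(p)
    inv <- inverse_ez(m$pc, m$mrt, m$vrt)
    expect_equal(inv$nu, p$nu, tolerance = 1e-8)
    expect_equal(inv$alpha, p$alpha, tolerance = 1e-8)
    expect_equal(inv$tau, p$tau, tolerance = 1e-8)
  }
})

test_that("inverse_ez rejects degenerate accuracies unless edge-corrected", {
  expect_error(inverse_ez(0.5, 1, 0.3), "edge correction")
  expect_error(inverse_ez(1, 1, 0.3, n = NULL), "edge correction")
  # with a trial count the classical correction applies
  inv <- inverse_ez(1, 0.8, 0.1, n = 40)    # pc -> 1 - 1/80
  expect_true(is.finite(inv$nu) && inv$nu > 0)
  inv0 <- inverse_ez(0, 0.8, 0.1, n = 40)   # pc -> 1/80
  expect_true(is.finite(inv0$nu) && inv0$nu < 0)
  invh <- inverse_ez(0.5, 0.8, 0.1, n = 40) # pc -> 1/2 + 1/160
  expect_true(is.finite(invh$nu))
  expect_error(forward_moments(ddm_params(NaN, 2, 0.3)))
})

test_that("sampled trials agree with the closed-form moments", {
  set.seed(7)
  n <- 20000
  for (par in list(c(1, 2, 0.3), c(-2, 3, 0.2))) {
    p <- ddm_params(par[1], par[2], par[3])
    m <- forward_moments(p)
    tr <- sample_trials(p, n)
    expect_true(all(tr$rt > p$tau))
    expect_true(all(tr$accuracy %in% 0:1))
    expect_lt(abs(mean(tr$accuracy) - m$pc),
              3.5 * sqrt(m$pc * (1 - m$pc) / n))
    expect_lt(abs(mean(tr$rt) - m$mrt), 3.5 * sqrt(m$vrt / n))
    se_v <- sd((tr$rt - mean(tr$rt))^2) / sqrt(n)
    expect_lt(abs(var(tr$rt) - m$vrt), 3.5 * se_v)
  }
})

test_that("sample_trials is deterministic under a seed and handles n = 1", {
  p <- ddm_params(0.5, 2.5, 0.3)
  set.seed(5); a <- sample_trials(p, 50)
  set.seed(5); b <- sample_trials(p, 50)
  expect_identical(a, b)
  set.seed(6)
  one <- sample_trials(p, 1)
  expect_equal(nrow(one), 1L)
  expect_gt(one$rt, p$tau)
})
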