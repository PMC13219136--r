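test_that("population draws respect the preset ranges and fixed variances", {
  set.seed(21)
  ranges <- list("main" = list(nu = c(-3, 3), alpha = c(2, 4)),
                 "high-nu/high-alpha" = list(nu = c(2, 3), alpha = c(3.5, 4)),
                 "low-nu/low-alpha" = list(nu = c(0, 1), alpha = c(2, 2.5)))
  for (preset in names(ranges)) {
    rg <- ranges[[preset]]
    for (i in 1:50) {
      pop <- draw_population(preset, beta = 0.2)
      expect_gte(pop$mu_nu, rg$nu[1]);    expect_lte(pop$mu_nu, rg$nu[2])
      expect_gte(pop$mu_alpha, rg$alpha[1])
      expect_lte(pop$mu_alpha, rg$alpha[2])
      expect_gte(pop$mu_tau, 0.2);        expect_lte(pop$mu_tau, 0.4)
      expect_identical(c(pop$sigma2_nu, pop$sigma2_alpha, pop$sigma2_tau),
                       c(0.75, 0.5, 0.1))
      expect_identical(pop$beta, 0.2)
    }
  }
  expect_error(draw_population("nope"), "unknown preset")
})

test_that("individual draws follow the drift meta-regression", {
  set.seed(22)
  P <- 10000
  ind <- draw_individuals(fixture_pop(mu_nu = 1, beta = 0.4), P)
  d <- ind$nu[, 2] - ind$nu[, 1]
  expect_lt(abs(mean(d) - 0.4), 3 * sqrt(2 * 0.75 / P))
  for (k in 1:2)
    expect_lt(abs(var(ind$nu[, k]) - 0.75), 3 * 0.75 * sqrt(2 / P))
  expect_true(all(ind$alpha > 0))
  expect_true(all(ind$tau >= 0.05))
  # null effect
  ind0 <- draw_individuals(fixture_pop(beta = 0), P)
  expect_lt(abs(mean(ind0$nu[, 2] - ind0$nu[, 1])), 3 * sqrt(2 * 0.75 / P))
})

test_that("generate_dataset produces exactly T trials per cell, reproducibly", {
  fx <- fixture_dataset(P = 2, T = 20)
  expect_equal(nrow(fx$data), 2 * 2 * 20)
  counts <- table(fx$data$participant, fx$data$condition)
  expect_true(all(counts == 20))
  expect_true(all(fx$data$contaminant == "none"))
  fx2 <- fixture_dataset(P = 2, T = 20)
  expect_identical(fx$data, fx2$data)
  # a high-drift individual responds correctly almost always
  set.seed(30)
  ind <- draw_individuals(fixture_pop(mu_nu = 3, beta = 0), 1)
  ind$nu[] <- 3; ind$alpha[] <- 3
  d <- generate_dataset(ind, 200)
  expect_gt(mean(d$accuracy), 0.98)  # forward pc = plogis(9) ~ 0.9999
})

test_that("contamination replaces exactly round(rate*T) trials per cell and nothing else", {
  set.seed(33)
  ind <- draw_individuals(fixture_pop(), 3)
  d <- generate_dataset(ind, 160)
  dc <- contaminate(d, ind, rate = 0.05)
  for (p in 1:3) {
    for (k in 0:1) {
      cell <- dc[dc$participant == p & dc$condition == k, ]
      expect_equal(sum(cell$contaminant != "none"), 8)  # 5% of 160
    }
  }
  clean_rows <- dc$contaminant == "none"
  expect_identical(dc$rt[clean_rows], d$rt[clean_rows])
  expect_identical(dc$accuracy[clean_rows], d$accuracy[clean_rows])
  # delayed startups: same accuracy, RT inflated by a value in (2, 3)
  del <- which(dc$contaminant == "delayed")
  expect_identical(dc$accuracy[del], d$accuracy[del])
  off <- dc$rt[del] - d$rt[del]
  expect_true(all(off > 2 & off < 3))
  # rate 0 is the identity
  expect_identical(contaminate(d, ind, rate = 0), d)
  expect_error(contaminate(d, ind, rate = 0.6), "rate")
  expect_error(contaminate(dc, ind), "already contains")
})

test_that("contaminant types split 50/50 and guesses are at chance", {
  set.seed(34)
  ind <- draw_individuals(fixture_pop(mu_nu = 2.5, mu_alpha = 2.2), 5)
  d <- generate_dataset(ind, 80)
  types <- character(); guess_acc <- integer()
  for (r in 1:12) {  # re-contaminate the same clean data for more coin flips
    dc <- contaminate(d, ind, rate = 0.05)
    tagged <- dc$contaminant[dc$contaminant != "none"]
    types <- c(types, tagged)
    guess_acc <- c(guess_acc, dc$accuracy[dc$contaminant == "guess"])
  }
  n <- length(types)
  expect_gt(n, 400)
  expect_lt(abs(mean(types == "delayed") - 0.5), 3 * sqrt(0.25 / n))
  expect_lt(abs(mean(guess_acc) - 0.5),
            3 * sqrt(0.25 / length(guess_acc)))
})
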