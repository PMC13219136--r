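# Shared fixtures: small generating populations and datasets built in code.

fixture_pop <- function(mu_nu = 1.5, beta = 0.4, mu_alpha = 2.5,
                        mu_tau = 0.3) {
  population_params(mu_nu = mu_nu, beta = beta, mu_alpha = mu_alpha,
                    mu_tau = mu_tau)
}

# A clean dataset plus its generating individuals, under a fixed seed.
fixture_dataset <- function(P = 4, T = 20, seed = 42, ...) {
  set.seed(seed)
  ind <- draw_individuals(fixture_pop(...), P)
  list(ind = ind, data = generate_dataset(ind, T))
}

quick_mcmc <- function() {
  mcmc_control(chains = 2, adapt = 200, warmup = 200, draws = 400)
}

# Hand-built fit object for testing statistics that only read posterior
# summaries.
fake_fit <- function(beta_mean, beta_sd, beta_prior = c(0, 1)) {
  structure(list(beta_mean = beta_mean, beta_sd = beta_sd,
                 spec = model_spec(beta_prior = beta_prior),
                 converged = TRUE),
            class = "hez_fit")
}
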