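# Shared fixtures built in code: small psychometric datasets and simulated
# observers used across test files.

# Binomial responses from an ideal cumulative-Gaussian observer.
make_curve_data <- function(pse = 40, slope = 0.1, levels = seq(0, 100, 10),
                            n_trials = 30, seed = 1) {
  set.seed(seed)
  p <- pnorm(slope * (levels - pse))
  psychometric_data(levels, n_trials, rbinom(length(levels), n_trials, p))
}

# Deterministic (noise-free) counts from a curve: k = round(n * p).
make_exact_data <- function(pse = 50, slope = 0.08, levels = seq(0, 100, 10),
                            n_trials = 1000) {
  p <- pnorm(slope * (levels - pse))
  psychometric_data(levels, n_trials, round(n_trials * p))
}

# Simulated psychometric data from a model observer, as % LI counts.
make_observer_data <- function(sigma_S, sigma_L, sigma_C = NULL,
                               variant = "M1", n_per_level = 300, seed = 1) {
  priors <- if (is.null(sigma_C)) NULL else prior_params(sigma_C = sigma_C)
  as_psychometric_data(simulate_psychometric(
    n_per_level = n_per_level, sens = sensory_params(sigma_S, sigma_L),
    priors = priors, variant = variant, settings = sim_settings(seed = seed)
  ))
}

# Brute-force binomial log-likelihood of a cumulative-Gaussian curve.
curve_loglik <- function(data, pse, slope) {
  p <- pnorm(slope * (data$levels - pse))
  p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
  sum(dbinom(data$n_coherent, data$n_trials, p, log = TRUE))
}
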