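#' Monte-Carlo simulation settings
#'
#' @param n_full Direction samples per trial for the posterior stage
#'   (default 5000).
#' @param early_fraction Fraction of `n_full` used for the early chi stage
#'   (default 0.2, i.e. 20% of 5000).
#' @param seed Integer RNG seed for the simulation.
#' @param bin_width Direction-grid resolution in degrees (default 0.5).
#' @return An object of class `sim_settings`.
#' @export
sim_settings <- function(n_full = 5000, early_fraction = 0.2, seed = 1L,
                         bin_width = 0.5) {
  stopifnot(is.numeric(n_full), n_full >= 100,
            is.numeric(early_fraction), early_fraction > 0,
            early_fraction <= 1)
  structure(
    list(n_full = as.integer(n_full), early_fraction = early_fraction,
         seed = as.integer(seed), grid = direction_grid(bin_width)),
    class = "sim_settings"
  )
}

# Deterministic substream seed derived from a base seed and integer keys.
# Linear congruential fold; always in [1, 2^31 - 2].
derive_seed <- function(seed, ...) {
  keys <- c(...)
  s <- (abs(as.numeric(seed)) %% 2147483647)
  for (k in c(keys, 0)) {
    s <- (s * 69621 + abs(as.numeric(k)) + 1) %% 2147483647
  }
  as.integer(s %% 2147483645) + 1L
}

#' Draw sensory direction measurements
#'
#' Independent draws from the three-component direction mixture: a
#' component is chosen with probabilities (A_S/2, A_S/2, A_L) for
#' (-theta_S, +theta_S, pattern), Gaussian jitter of the matching width is
#' added, and the result is wrapped to \[-180, 180).
#'
#' @param stim A [stimulus_config()].
#' @param sens A [sensory_params()].
#' @param n Number of samples (>= 1).
#' @return An object of class `measurement_samples`: list with `angles`
#'   (degrees, wrapped) and `n`.
#' @export
sample_measurements <- function(stim, sens, n) {
  stopifnot(inherits(stim, "stimulus_config"), inherits(sens, "sensory_params"),
            n >= 1)
  n <- as.integer(n)
  comp <- sample.int(3L, n, replace = TRUE,
                     prob = c(stim$A_S / 2, stim$A_S / 2, stim$A_L))
  mu <- c(-stim$theta_S, stim$theta_S, stim$theta_L)[comp]
  sd <- c(sens$sigma_S, sens$sigma_S, sens$sigma_L)[comp]
  angles <- wrap_angle(stats::rnorm(n, mu, sd))
  structure(list(angles = angles, n = n), class = "measurement_samples")
}

# Per-trial histogram argmax with the documented tie rule: among bins with
# maximal (weighted) count, the smallest |angle| wins, then the positive
# member of a +/- pair. `counts` is n_bins x n_trials; `centers` and `pref`
# describe those bins.
hist_argmax <- function(counts, centers, pref) {
  m <- t(counts[pref, , drop = FALSE])
  idx <- max.col(m, ties.method = "first")
  centers[pref][idx]
}

# Shared setup for the per-level trial simulation: active-bin restriction,
# bin probabilities, preference order and the two prior weight vectors.
# Bins whose probability is below max(p) * 1e-14 can never hold a sample at
# these counts and are dropped before drawing (truncated mass < 1e-10).
level_sim_setup <- function(A_L, stim, sens, priors, variant, settings) {
  grid <- settings$grid
  stim_l <- stimulus_config(theta_S = stim$theta_S, theta_L = stim$theta_L,
                            A_L = A_L)
  p <- likelihood_pdf(grid, stim_l, sens)$values * grid$bin_width
  active <- which(p > max(p) * 1e-14)
  p <- p[active]
  centers <- grid$centers[active]
  list(
    p = p / sum(p), centers = centers, active = active,
    pref = order(abs(centers), -centers),
    w1 = prior_weights_for(grid, variant, 1L, priors)[active],
    w2 = prior_weights_for(grid, variant, 2L, priors)[active],
    n_early = max(1L, as.integer(round(settings$early_fraction *
                                         settings$n_full)))
  )
}

# Simulation of all trials at one LI level. Histogram counts of n iid
# binned mixture draws are built by direct categorical sampling over the
# bins (exactly the distribution of the binned sample histogram); the hot
# loop lives in C++ (simulate_level_cpp). RNG state (set.seed) is the
# caller's responsibility.
simulate_level_trials <- function(A_L, n_trials, stim, sens, priors, variant,
                                  settings) {
  s <- level_sim_setup(A_L, stim, sens, priors, variant, settings)
  out <- simulate_level_cpp(s$p, as.integer(n_trials), s$n_early,
                            settings$n_full, s$w1, s$w2, s$centers,
                            s$pref - 1L, order(s$p, decreasing = TRUE) - 1L,
                            stim$theta_S / 2, stim$theta_S / 2)
  data.frame(chi = out$chi, theta_max = out$theta_max,
             theta_map = out$theta_map,
             percept = ifelse(out$coherent, "coherent", "transparent"),
             stringsAsFactors = FALSE)
}

# Pure-R reference implementation of the same two-stage protocol, drawing
# the histogram counts as multinomials (rmultinom). Distributionally
# identical to simulate_level_trials (not draw-for-draw: different sampling
# algorithm); kept as an independent cross-check for tests.
simulate_level_trials_r <- function(A_L, n_trials, stim, sens, priors,
                                    variant, settings) {
  s <- level_sim_setup(A_L, stim, sens, priors, variant, settings)
  cnt1 <- stats::rmultinom(n_trials, s$n_early, s$p)
  theta_max <- hist_argmax(cnt1, s$centers, s$pref)
  chi <- chi_decision(theta_max, stim$theta_S)
  cnt2 <- stats::rmultinom(n_trials, settings$n_full, s$p)
  theta_map <- numeric(n_trials)
  for (ch in unique(chi)) {
    cols <- chi == ch
    w <- if (ch == 1L) s$w1 else s$w2
    theta_map[cols] <- hist_argmax(cnt2[, cols, drop = FALSE] * w,
                                   s$centers, s$pref)
  }
  percept <- ifelse(abs(theta_map) < stim$theta_S / 2, "coherent",
                    "transparent")
  data.frame(chi = chi, theta_max = theta_max, theta_map = theta_map,
             percept = percept, stringsAsFactors = FALSE)
}

#' Simulate a single trial
#'
#' Two-stage protocol: (1) an early histogram of `early_fraction * n_full`
#' direction samples on the 0.5-degree grid yields theta_max and the
#' categorical commitment chi; (2) a fresh histogram of `n_full` samples is
#' multiplied bin-wise by the (variant, chi)-selected prior weights and its
#' argmax is the MAP direction theta_map, from which the categorical percept
#' is read out (coherent iff `|theta_map| < theta_S/2`; the boundary maps to
#' transparent).
#'
#' @param stim A [stimulus_config()].
#' @param sens A [sensory_params()].
#' @param priors A [prior_params()] (or `NULL` for M1).
#' @param variant Model variant tag `"M1"`..`"M4"`.
#' @param settings A [sim_settings()]; its `seed` drives the trial.
#' @return An object of class `trial_outcome`: list with `chi`, `theta_max`,
#'   `theta_map`, `percept`.
#' @export
simulate_trial <- function(stim, sens, priors = NULL, variant = "M1",
                           settings = sim_settings()) {
  check_variant_priors(variant, priors)
  set.seed(settings$seed)
  row <- simulate_level_trials(stim$A_L, 1L, stim, sens, priors, variant,
                               settings)
  structure(list(chi = row$chi, theta_max = row$theta_max,
                 theta_map = row$theta_map, percept = row$percept),
            class = "trial_outcome")
}

#' @export
print.trial_outcome <- function(x, ...) {
  cat(sprintf("<trial_outcome> chi=%d theta_max=%g theta_map=%g -> %s\n",
              x$chi, x$theta_max, x$theta_map, x$percept))
  invisible(x)
}

#' Simulate a psychometric function
#'
#' Runs `n_per_level` independent trials at each LI-proportion level and
#' returns the fraction of coherent percepts per level. Each level uses its
#' own RNG substream derived from `settings$seed` (and `condition_key`), so
#' results are reproducible independent of which levels are simulated.
#'
#' @param levels LI proportions in \[0, 1\] (default: 11 equally spaced
#'   levels from 0 to 1).
#' @param n_per_level Trials per level.
#' @param sens A [sensory_params()].
#' @param priors A [prior_params()] (or `NULL`).
#' @param variant Model variant tag.
#' @param settings A [sim_settings()].
#' @param stim A [stimulus_config()]; its `A_L` is overridden per level.
#' @param condition_key Optional integer key folded into the per-level seeds
#'   so distinct experimental conditions get distinct substreams.
#' @return An object of class `sim_psychometric`: list with `levels`,
#'   `n_per_level`, `n_coherent`, `p_coherent`, `seed`.
#' @export
simulate_psychometric <- function(levels = seq(0, 1, length.out = 11),
                                  n_per_level = 30,
                                  sens,
                                  priors = NULL,
                                  variant = "M1",
                                  settings = sim_settings(),
                                  stim = stimulus_config(),
                                  condition_key = 0L) {
  stopifnot(length(levels) > 0, all(levels >= 0 & levels <= 1))
  check_variant_priors(variant, priors)
  n_coh <- integer(length(levels))
  for (i in seq_along(levels)) {
    set.seed(derive_seed(settings$seed, condition_key, i))
    tr <- simulate_level_trials(levels[i], n_per_level, stim, sens, priors,
                                variant, settings)
    n_coh[i] <- sum(tr$percept == "coherent")
  }
  structure(
    list(levels = levels, n_per_level = n_per_level, n_coherent = n_coh,
         p_coherent = n_coh / n_per_level, seed = settings$seed),
    class = "sim_psychometric"
  )
}

#' Simulate psychometric functions for several variant/prior configurations
#' at once
#'
#' Runs the same simulated trials (identical stage-1 and stage-2 sample
#' histograms, i.e. common random numbers) through multiple prior-weight
#' readouts. Because the draws are shared, differences between the returned
#' curves reflect only the priors' effects, not independent Monte-Carlo
#' noise — which is what makes small model-evidence margins measurable.
#'
#' @param configs A list; each element a list with elements `variant`
#'   (tag `"M1"`..`"M4"`) and `priors` (a [prior_params()] or `NULL`).
#' @inheritParams simulate_psychometric
#' @return Matrix of coherent-percept fractions, `length(levels)` rows x
#'   `length(configs)` columns.
#' @export
simulate_psychometric_multi <- function(configs,
                                        levels = seq(0, 1, length.out = 11),
                                        n_per_level = 30,
                                        sens,
                                        settings = sim_settings(),
                                        stim = stimulus_config(),
                                        condition_key = 0L) {
  stopifnot(length(configs) >= 1, length(levels) > 0,
            all(levels >= 0 & levels <= 1))
  for (cf in configs) check_variant_priors(cf$variant, cf$priors)
  grid <- settings$grid
  p_coh <- matrix(NA_real_, length(levels), length(configs))
  for (i in seq_along(levels)) {
    s <- level_sim_setup(levels[i], stim, sens, NULL, "M1", settings)
    W1 <- vapply(configs, function(cf)
      prior_weights_for(grid, cf$variant, 1L, cf$priors)[s$active],
      numeric(length(s$centers)))
    W2 <- vapply(configs, function(cf)
      prior_weights_for(grid, cf$variant, 2L, cf$priors)[s$active],
      numeric(length(s$centers)))
    set.seed(derive_seed(settings$seed, condition_key, i))
    n_coh <- simulate_level_multi_cpp(
      s$p, as.integer(n_per_level), s$n_early, settings$n_full,
      W1, W2, s$centers, s$pref - 1L, order(s$p, decreasing = TRUE) - 1L,
      stim$theta_S / 2, stim$theta_S / 2
    )
    p_coh[i, ] <- n_coh / n_per_level
  }
  p_coh
}

#' @export
print.sim_psychometric <- function(x, ...) {
  cat(sprintf("<sim_psychometric> %d levels x %d trials, seed %d\n",
              length(x$levels), x$n_per_level, x$seed))
  print(round(stats::setNames(x$p_coherent, x$levels), 3))
  invisible(x)
}
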