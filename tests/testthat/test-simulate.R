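test_that("measurement samples follow the mixture and the seeded contract", {
  stim <- stimulus_config(A_L = 1)
  sens <- sensory_params(10, 1)
  set.seed(3)
  s <- sample_measurements(stim, sens, 1e5)
  expect_true(all(s$angles >= -180 & s$angles < 180))
  # circular mean of a tight centered component
  ang <- s$angles * pi / 180
  cmean <- atan2(mean(sin(ang)), mean(cos(ang))) * 180 / pi
  expect_lt(abs(cmean), 0.1)

  # mirror symmetry of the pure-component mixture: exact binomial bound
  set.seed(4)
  s0 <- sample_measurements(stimulus_config(A_L = 0), sensory_params(10, 10), 1e5)
  frac_pos <- mean(s0$angles > 0)
  expect_lt(abs(frac_pos - 0.5), 3 * sqrt(0.25 / 1e5))

  # bit-identical repetition under a fixed seed
  set.seed(99)
  a <- sample_measurements(stim, sens, 1000)
  set.seed(99)
  b <- sample_measurements(stim, sens, 1000)
  expect_identical(a$angles, b$angles)
})

test_that("single-trial outcomes satisfy the percept rule", {
  out <- simulate_trial(stimulus_config(A_L = 0.5), sensory_params(10, 10),
                        settings = sim_settings(seed = 5))
  expect_true(out$chi %in% 1:2)
  expect_identical(out$percept,
                   if (abs(out$theta_map) < 30) "coherent" else "transparent")
  # chi is consistent with its own theta_max
  expect_identical(out$chi, chi_decision(out$theta_max, 60))
  expect_error(simulate_trial(stimulus_config(), sensory_params(10, 10),
                              variant = "M3"), "sigma_C")
})

test_that("endpoint levels give near-certain percepts", {
  sens <- sensory_params(5, 5)
  sim <- simulate_psychometric(levels = c(0, 1), n_per_level = 1000,
                               sens = sens, settings = sim_settings(seed = 7))
  expect_lte(sim$p_coherent[1], 0.01)  # all separated lines -> transparent
  expect_gte(sim$p_coherent[2], 0.99)  # all intersections -> coherent
})

test_that("psychometric simulation is deterministic and uses the default design", {
  sens <- sensory_params(12, 9)
  a <- simulate_psychometric(n_per_level = 50, sens = sens,
                             settings = sim_settings(seed = 21))
  b <- simulate_psychometric(n_per_level = 50, sens = sens,
                             settings = sim_settings(seed = 21))
  expect_equal(a$levels, seq(0, 1, length.out = 11))
  expect_identical(a$p_coherent, b$p_coherent)
  # endpoint ordering
  expect_lte(a$p_coherent[1], a$p_coherent[11])
})

test_that("the segregating prior suppresses coherence under common random numbers", {
  sens <- sensory_params(10, 10)
  st <- sim_settings(seed = 31)
  m1 <- simulate_psychometric(levels = 1 / 3, n_per_level = 2000, sens = sens,
                              variant = "M1", settings = st)
  m3 <- simulate_psychometric(levels = 1 / 3, n_per_level = 2000, sens = sens,
                              priors = prior_params(sigma_C = 30),
                              variant = "M3", settings = st)
  expect_lt(m3$p_coherent, m1$p_coherent)
})

test_that("effectively flat priors reproduce M1 fractions at common seeds", {
  sens <- sensory_params(12, 8)
  st <- sim_settings(seed = 41)
  n <- 500
  m1 <- simulate_psychometric(n_per_level = n, sens = sens, settings = st)
  m2 <- simulate_psychometric(n_per_level = n, sens = sens,
                              priors = prior_params(sigma_P = 1e4),
                              variant = "M2", settings = st)
  m3 <- simulate_psychometric(n_per_level = n, sens = sens,
                              priors = prior_params(sigma_C = 0.01),
                              variant = "M3", settings = st)
  se <- sqrt(pmax(m1$p_coherent * (1 - m1$p_coherent), 0.25 / n) / n)
  expect_true(all(abs(m2$p_coherent - m1$p_coherent) <= 3 * se))
  expect_true(all(abs(m3$p_coherent - m1$p_coherent) <= 3 * se))
})

test_that("expected coherent fraction is monotone in the LI proportion", {
  sens <- sensory_params(15, 10)
  sim <- simulate_psychometric(n_per_level = 2000, sens = sens,
                               settings = sim_settings(seed = 51))
  violations <- sum(diff(sim$p_coherent) < -2 * sqrt(0.25 / 2000))
  expect_lt(violations, 2)
})

test_that("widening one likelihood shifts the PSE in the expected direction", {
  # PSE proxy: first level where the simulated fraction crosses 0.5
  pse_of <- function(sigma_S, sigma_L) {
    sim <- simulate_psychometric(levels = seq(0, 1, 0.05), n_per_level = 400,
                                 sens = sensory_params(sigma_S, sigma_L),
                                 settings = sim_settings(seed = 61))
    approx(sim$p_coherent + seq_along(sim$levels) * 1e-9, sim$levels, 0.5)$y
  }
  for (sL in c(6, 10)) {
    # larger sigma_S -> coherence easier -> smaller PSE
    expect_lt(pse_of(20, sL), pse_of(10, sL))
  }
  for (sS in c(10, 20)) {
    # larger sigma_L -> transparency easier -> larger PSE
    expect_gt(pse_of(sS, 12), pse_of(sS, 6))
  }
})

test_that("the C++ sampler agrees distributionally with the rmultinom reference", {
  stim <- stimulus_config()
  sens <- sensory_params(12, 9)
  st <- sim_settings(seed = 71)
  n <- 3000
  set.seed(1)
  a <- plaidobs:::simulate_level_trials(0.3, n, stim, sens, NULL, "M1", st)
  set.seed(1)
  b <- plaidobs:::simulate_level_trials_r(0.3, n, stim, sens, NULL, "M1", st)
  pa <- mean(a$percept == "coherent")
  pb <- mean(b$percept == "coherent")
  se <- sqrt(2 * 0.25 / n)
  expect_lt(abs(pa - pb), 4 * se)
  expect_lt(abs(mean(a$chi == 1) - mean(b$chi == 1)), 4 * se)
})

test_that("multi-readout simulation matches single-variant runs draw for draw", {
  sens <- sensory_params(12, 9)
  st <- sim_settings(seed = 81)
  configs <- list(
    list(variant = "M1", priors = NULL),
    list(variant = "M3", priors = prior_params(sigma_C = 30))
  )
  p_multi <- simulate_psychometric_multi(configs, n_per_level = 300,
                                         sens = sens, settings = st)
  m1 <- simulate_psychometric(n_per_level = 300, sens = sens, settings = st)
  # the M1 column shares draws and readout with the plain M1 simulation
  expect_identical(p_multi[, 1], m1$p_coherent)
  m3 <- simulate_psychometric(n_per_level = 300, sens = sens,
                              priors = prior_params(sigma_C = 30),
                              variant = "M3", settings = st)
  expect_identical(p_multi[, 2], m3$p_coherent)
})
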