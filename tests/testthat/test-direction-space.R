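test_that("direction grid is uniform, wraps, and rejects bad widths", {
  g <- direction_grid(0.5)
  expect_equal(g$n_bins, 720L)
  expect_equal(unique(round(diff(g$centers), 12)), 0.5)
  expect_equal(g$centers[1], -180)
  # circular wrap: the gap between the last and first bin is one bin width
  expect_equal((g$centers[1] - g$centers[g$n_bins]) %% 360, g$bin_width)
  expect_error(direction_grid(0.7), "divide 360")
  g2 <- direction_grid(1)
  expect_equal(g2$n_bins, 360L)
  expect_true(0 %in% g2$centers)
})

test_that("likelihood mixture is a normalized density with the stated weights", {
  g <- direction_grid()
  sens <- sensory_params(5, 5)
  d <- likelihood_pdf(g, stimulus_config(A_L = 0.4), sens)
  expect_lt(abs(sum(d$values) * g$bin_width - 1), 1e-9)
  # with sigma = 5 the three components are well separated: component mass
  # A_S/2 each at +/-60, pattern mass A_L at 0
  mass_near <- function(center) {
    sel <- abs(wrap_angle(g$centers - center)) < 30
    sum(d$values[sel]) * g$bin_width
  }
  expect_equal(mass_near(-60), 0.3, tolerance = 1e-6)
  expect_equal(mass_near(60), 0.3, tolerance = 1e-6)
  expect_equal(mass_near(0), 0.4, tolerance = 1e-6)

  # A_L = 1: unimodal, peak at the 0-degree bin, symmetric about 0
  d1 <- likelihood_pdf(g, stimulus_config(A_L = 1), sensory_params(5, 10))
  expect_equal(g$centers[which.max(d1$values)], 0)
  # A_L = 0: bimodal with equal peaks at the bins containing +/-60
  d0 <- likelihood_pdf(g, stimulus_config(A_L = 0), sensory_params(10, 10))
  peaks <- g$centers[order(d0$values, decreasing = TRUE)[1:2]]
  expect_setequal(peaks, c(-60, 60))
  expect_equal(d0$values[g$centers == -60], d0$values[g$centers == 60])
})

test_that("likelihood is even in theta when the pattern direction is 0", {
  g <- direction_grid()
  d <- likelihood_pdf(g, stimulus_config(A_L = 0.3), sensory_params(12, 7))
  pos <- g$centers > 0 & g$centers < 180
  mirrored <- vapply(g$centers[pos], function(th)
    d$values[g$centers == -th], numeric(1))
  expect_equal(d$values[pos], mirrored, tolerance = 1e-12)
})

test_that("integrating prior is a centered, peak-scaled, even weight", {
  g <- direction_grid()
  w <- integrate_prior(g, 30)
  expect_equal(g$centers[which.max(w$values)], 0)
  expect_equal(max(w$values), 1)
  # flat-prior limit
  wf <- integrate_prior(g, 1e4)
  expect_lt(max(wf$values) / min(wf$values), 1.01)
  # even function
  pos <- g$centers > 0 & g$centers < 180
  mirrored <- vapply(g$centers[pos], function(th)
    w$values[g$centers == -th], numeric(1))
  expect_equal(w$values[pos], mirrored, tolerance = 1e-12)
  expect_error(integrate_prior(g, 0), "positive")
  expect_error(integrate_prior(g, -3), "positive")
})

test_that("segregating prior inhibits the pattern and peaks opposite it", {
  g <- direction_grid()
  w <- segregate_prior(g, 30)
  expect_equal(g$centers[which.min(w$values)], 0)
  expect_equal(min(w$values), 0)
  expect_true(all(w$values >= 0 & w$values <= 1))
  # exhaustive scan: the bin diametrically opposite (at -180, the grid's
  # representative of +/-180) carries the maximal weight
  expect_gte(w$values[g$centers == -180], max(w$values) - 1e-12)
  # vanishing-width limit approaches a flat weight except the exact 0 bin
  w0 <- segregate_prior(g, 0.01)
  expect_true(all(w0$values[g$centers != 0] > 0.999))
  expect_equal(w0$values[g$centers == 0], 0)
  expect_error(segregate_prior(g, 0), "positive")
})

test_that("conditional posterior applies the (variant, chi) prior and renormalizes", {
  g <- direction_grid()
  hist <- likelihood_pdf(g, stimulus_config(A_L = 1 / 3), sensory_params(10, 10))
  priors <- prior_params(sigma_P = 40, sigma_C = 30)

  # M1 leaves the input untouched
  post <- conditional_posterior(hist, "M1", 1, priors)
  expect_equal(post$values, hist$values)

  # unit mass for every variant and chi
  for (v in c("M1", "M2", "M3", "M4")) {
    for (chi in 1:2) {
      p <- conditional_posterior(hist, v, chi, priors)
      expect_lt(abs(sum(p$values) * g$bin_width - 1), 1e-9)
    }
  }

  # independent bin-wise oracle for M3, chi = 2
  w <- segregate_prior(g, 30)$values
  expected <- hist$values * w
  expected <- expected / (sum(expected) * g$bin_width)
  got <- conditional_posterior(hist, "M3", 2, priors)
  expect_equal(got$values, expected, tolerance = 1e-12)
  # the segregating prior suppresses the pattern bin relative to M1
  m1_at0 <- conditional_posterior(hist, "M1", 2, priors)$values[g$centers == 0]
  expect_lt(got$values[g$centers == 0], m1_at0)

  # variant/prior mismatch is a configuration error
  expect_error(conditional_posterior(hist, "M3", 2, prior_params(sigma_P = 40)),
               "sigma_C")
  expect_error(conditional_posterior(hist, "M2", 1, NULL), "sigma_P")
})

test_that("effectively flat priors reproduce the M1 posterior bin-wise", {
  g <- direction_grid()
  hist <- likelihood_pdf(g, stimulus_config(A_L = 0.5), sensory_params(15, 8))
  m1 <- conditional_posterior(hist, "M1", 1)
  m2_flat <- conditional_posterior(hist, "M2", 1, prior_params(sigma_P = 1e4))
  m3_flat <- conditional_posterior(hist, "M3", 2, prior_params(sigma_C = 0.01))
  expect_lt(max(abs(m2_flat$values - m1$values)), 1e-3)
  # the 0.01-degree segregating prior only empties the exact 0 bin
  off0 <- g$centers != 0
  expect_lt(max(abs(m3_flat$values[off0] - m1$values[off0])), 1e-3)
})

test_that("chi decision matches the circular-distance oracle with the tie rule", {
  g <- direction_grid()
  theta_S <- 60
  # brute-force oracle: nearest of {0, -60, +60} in circular distance;
  # the exact tie |theta| = 30 goes to the components (chi = 2)
  circ_dist <- function(a, b) abs(wrap_angle(a - b))
  oracle <- vapply(g$centers, function(th) {
    d_pattern <- circ_dist(th, 0)
    d_comp <- min(circ_dist(th, 60), circ_dist(th, -60))
    if (d_pattern < d_comp) 1L else 2L
  }, integer(1))
  got <- chi_decision(g$centers, theta_S)
  expect_equal(got, oracle)
  # printed examples
  expect_identical(chi_decision(0, 60), 1L)
  expect_identical(chi_decision(-60, 60), 2L)
  expect_identical(chi_decision(30, 60), 2L)   # documented boundary rule
  expect_identical(chi_decision(-30, 60), 2L)
})

test_that("parameter constructors validate their domains", {
  expect_error(sensory_params(0, 10), "positive")
  expect_error(sensory_params(10, Inf), "positive")
  expect_error(prior_params(sigma_P = -1), "positive")
  expect_error(stimulus_config(A_L = 1.2), "0, 1")
  expect_error(stimulus_config(theta_S = -60), "positive")
  s <- stimulus_config(A_L = 0.4)
  expect_equal(s$A_S, 0.6)
})

test_that("normalization holds across randomized posterior chains", {
  g <- direction_grid()
  set.seed(11)
  for (i in 1:25) {
    sens <- sensory_params(runif(1, 2, 40), runif(1, 2, 40))
    stim <- stimulus_config(A_L = runif(1))
    priors <- prior_params(sigma_P = runif(1, 5, 120),
                           sigma_C = runif(1, 5, 120))
    hist <- likelihood_pdf(g, stim, sens)
    v <- sample(c("M1", "M2", "M3", "M4"), 1)
    chi <- sample(1:2, 1)
    post <- conditional_posterior(hist, v, chi, priors)
    expect_lt(abs(sum(post$values) * g$bin_width - 1), 1e-9)
    # chaining: posterior of a posterior still normalized
    post2 <- conditional_posterior(post, v, 3L - chi, priors)
    expect_lt(abs(sum(post2$values) * g$bin_width - 1), 1e-9)
  }
})
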