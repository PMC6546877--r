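#' Per-level binomial response data
#'
#' @param levels Stimulus levels in % LI (0-100), strictly increasing.
#' @param n_trials Trials per level (recycled if scalar).
#' @param n_coherent Coherent responses per level.
#' @return An object of class `psychometric_data`.
#' @export
psychometric_data <- function(levels, n_trials, n_coherent) {
  n_trials <- rep_len(as.integer(n_trials), length(levels))
  n_coherent <- as.integer(n_coherent)
  stopifnot(length(levels) == length(n_coherent),
            all(diff(levels) > 0),
            all(n_coherent >= 0), all(n_coherent <= n_trials))
  structure(list(levels = as.numeric(levels), n_trials = n_trials,
                 n_coherent = n_coherent),
            class = "psychometric_data")
}

#' @export
print.psychometric_data <- function(x, ...) {
  cat(sprintf("<psychometric_data> %d levels, %d trials total\n",
              length(x$levels), sum(x$n_trials)))
  invisible(x)
}

#' Convert a simulated psychometric function to response data
#'
#' @param sim A `sim_psychometric` from [simulate_psychometric()].
#' @return A [psychometric_data()] with levels on the % LI scale.
#' @export
as_psychometric_data <- function(sim) {
  stopifnot(inherits(sim, "sim_psychometric"))
  psychometric_data(sim$levels * 100, sim$n_per_level, sim$n_coherent)
}

stop_degenerate <- function(direction) {
  cond <- structure(
    class = c("plaidobs_degenerate_fit", "error", "condition"),
    list(message = sprintf(
      "all responses are %s; the psychometric curve is not identifiable",
      if (direction > 0) "coherent" else "transparent"),
      call = NULL, direction = direction)
  )
  stop(cond)
}

#' Fit a two-parameter psychometric function
#'
#' Binomial maximum-likelihood fit of a cumulative Gaussian
#' `P(coherent | level) = Phi(slope * (level - pse))` via a probit GLM.
#' No lapse or guess parameters are estimated. By construction the
#' predicted probability at the fitted PSE is exactly 0.5.
#'
#' @param data A [psychometric_data()] with at least 3 informative levels.
#' @return An object of class `psychometric_fit` with elements `pse`
#'   (% LI at P = 0.5), `slope` (probit slope per % LI), `sigma`
#'   (= 1/slope, the cumulative-Gaussian width), `loglik`, `family`.
#' @export
fit_psychometric <- function(data) {
  stopifnot(inherits(data, "psychometric_data"))
  keep <- data$n_trials > 0
  lv <- data$levels[keep]
  k <- data$n_coherent[keep]
  n <- data$n_trials[keep]
  if (length(lv) < 3) stop("need >= 3 levels with trials", call. = FALSE)
  if (all(k == 0)) stop_degenerate(-1)
  if (all(k == n)) stop_degenerate(+1)
  fit <- suppressWarnings(
    stats::glm(cbind(k, n - k) ~ lv, family = stats::binomial(link = "probit"))
  )
  b <- unname(stats::coef(fit))
  if (!all(is.finite(b)) || b[2] == 0) {
    stop("psychometric fit did not converge to a finite slope", call. = FALSE)
  }
  p_hat <- stats::pnorm(b[1] + b[2] * lv)
  p_hat <- pmin(pmax(p_hat, 1e-12), 1 - 1e-12)
  structure(
    list(pse = -b[1] / b[2], slope = b[2], sigma = 1 / b[2],
         loglik = sum(stats::dbinom(k, n, p_hat, log = TRUE)),
         family = "cumulative-gaussian", data = data),
    class = "psychometric_fit"
  )
}

#' Construct a psychometric curve directly from parameters
#'
#' Useful for evaluating stability indices on idealized curves (e.g. a flat
#' curve with `slope = 0`, or sweeps of slope at fixed PSE) without fitting.
#'
#' @param pse PSE in % LI.
#' @param slope Probit slope per % LI (0 gives the flat curve P = 0.5).
#' @return An object of class `psychometric_fit`.
#' @export
psychometric_curve <- function(pse, slope) {
  structure(list(pse = pse, slope = slope,
                 sigma = if (slope != 0) 1 / slope else Inf,
                 loglik = NA_real_, family = "cumulative-gaussian",
                 data = NULL),
            class = "psychometric_fit")
}

#' @export
predict.psychometric_fit <- function(object, levels = NULL, ...) {
  if (is.null(levels)) levels <- object$data$levels
  stats::pnorm(object$slope * (levels - object$pse))
}

#' @export
print.psychometric_fit <- function(x, ...) {
  cat(sprintf("<psychometric_fit> PSE = %.2f %% LI, slope = %.4f /%%, loglik = %.2f\n",
              x$pse, x$slope, x$loglik))
  invisible(x)
}

#' Bootstrap a psychometric fit
#'
#' Per-level binomial resampling with replacement of the observed responses
#' (equivalently, resampling each level's Bernoulli responses), refitting
#' each replicate. Degenerate replicates (all-coherent or all-transparent)
#' are dropped and counted.
#'
#' @param data A [psychometric_data()].
#' @param n_resamples Number of bootstrap replicates (default 400).
#' @param seed RNG seed.
#' @param probs Percentile interval probabilities.
#' @return An object of class `psychometric_boot`: `pse` and `slope`
#'   replicate vectors, `ci_pse`, `ci_slope`, `n_failed`, `seed`.
#' @export
bootstrap_fit <- function(data, n_resamples = 400, seed = 1L,
                          probs = c(0.025, 0.975)) {
  stopifnot(inherits(data, "psychometric_data"))
  set.seed(seed)
  p_hat <- ifelse(data$n_trials > 0, data$n_coherent / data$n_trials, 0)
  pse <- slope <- numeric(0)
  n_failed <- 0L
  for (r in seq_len(n_resamples)) {
    k_star <- stats::rbinom(length(p_hat), data$n_trials, p_hat)
    f <- tryCatch(
      fit_psychometric(psychometric_data(data$levels, data$n_trials, k_star)),
      error = function(e) NULL
    )
    if (is.null(f)) {
      n_failed <- n_failed + 1L
    } else {
      pse <- c(pse, f$pse)
      slope <- c(slope, f$slope)
    }
  }
  structure(
    list(pse = pse, slope = slope,
         ci_pse = stats::quantile(pse, probs, names = FALSE),
         ci_slope = stats::quantile(slope, probs, names = FALSE),
         n_resamples = n_resamples, n_failed = n_failed, seed = seed),
    class = "psychometric_boot"
  )
}

#' @export
print.psychometric_boot <- function(x, ...) {
  cat(sprintf(
    "<psychometric_boot> %d replicates (%d failed); PSE %.2f [%.2f, %.2f]\n",
    x$n_resamples, x$n_failed, stats::median(x$pse), x$ci_pse[1], x$ci_pse[2]))
  invisible(x)
}

#' Perceptual bias relative to a reference curve
#'
#' The bias is the subject's 50% coherence threshold (PSE) minus the
#' reference PSE (conventionally the pooled low-density population fit),
#' in % LI. Positive values mean the subject needs more LI apertures to see
#' coherence, i.e. is shifted toward the transparent percept.
#'
#' @param fit Subject [fit_psychometric()] result.
#' @param reference Reference `psychometric_fit`.
#' @return An object of class `bias_estimate` with `value` (% LI) and
#'   `direction` (`"transparent"`, `"coherent"`, or `"none"`).
#' @export
estimate_bias <- function(fit, reference) {
  stopifnot(inherits(fit, "psychometric_fit"),
            inherits(reference, "psychometric_fit"))
  value <- fit$pse - reference$pse
  structure(
    list(value = value,
         direction = if (value > 0) "transparent"
                     else if (value < 0) "coherent" else "none"),
    class = "bias_estimate"
  )
}

#' @export
print.bias_estimate <- function(x, ...) {
  cat(sprintf("<bias_estimate> %+.2f %% LI (%s)\n", x$value, x$direction))
  invisible(x)
}

#' Perceptual stability index (PSI)
#'
#' Evaluates the fitted curve at the stimulus levels; a level is
#' confident-coherent if P(coherent) > `threshold` and
#' confident-transparent if P(coherent) < 1 - `threshold` (default 75%
#' confidence areas). The dominant percept is the side with more confident
#' levels (ties broken by the sign of `bias` if given, else coherent), and
#' the PSI is the fraction of all levels that are confident on the dominant
#' side.
#'
#' @param fit A `psychometric_fit`.
#' @param levels Stimulus levels (% LI) at which to evaluate the curve.
#' @param threshold Confidence cutoff probability (default 0.75).
#' @param bias Optional signed bias value used only to break ties.
#' @return An object of class `psi_result`: `psi` in \[0, 1\], `dominant`,
#'   `threshold`, and the per-side confident counts.
#' @export
compute_psi <- function(fit, levels, threshold = 0.75, bias = NULL) {
  stopifnot(inherits(fit, "psychometric_fit"), length(levels) > 0,
            threshold > 0.5, threshold < 1)
  p <- predict(fit, levels)
  n_coh <- sum(p > threshold)
  n_tra <- sum(p < 1 - threshold)
  dominant <- if (n_coh > n_tra) {
    "coherent"
  } else if (n_tra > n_coh) {
    "transparent"
  } else if (!is.null(bias) && is.numeric(bias) && bias < 0) {
    "coherent"
  } else if (!is.null(bias) && is.numeric(bias) && bias > 0) {
    "transparent"
  } else {
    "coherent"
  }
  psi <- (if (dominant == "coherent") n_coh else n_tra) / length(levels)
  structure(
    list(psi = psi, dominant = dominant, threshold = threshold,
         n_confident_coherent = n_coh, n_confident_transparent = n_tra,
         n_levels = length(levels)),
    class = "psi_result"
  )
}

#' @export
print.psi_result <- function(x, ...) {
  cat(sprintf("<psi_result> PSI = %.3f (dominant: %s, threshold %.2f)\n",
              x$psi, x$dominant, x$threshold))
  invisible(x)
}
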