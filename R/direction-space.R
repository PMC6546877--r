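#' Discretized circular direction space
#'
#' All densities in the observer model live on a uniform grid of direction
#' bins covering \[-180, 180) degrees. Bins are half-open intervals
#' \[c - w/2, c + w/2) around each center c, with 0 degrees (the pattern
#' direction) always an exact bin center.
#'
#' @param bin_width Bin resolution in degrees; must divide 360 exactly.
#'   Default 0.5.
#' @return An object of class `direction_grid` with elements `bin_width`,
#'   `centers` (ordered bin centers from -180 to 180 - bin_width), `n_bins`,
#'   and `pref` (the bin preference order used to break histogram-argmax
#'   ties: smallest absolute angle first, positive before negative).
#' @examples
#' g <- direction_grid()
#' g$n_bins # 720
#' @export
direction_grid <- function(bin_width = 0.5) {
  stopifnot(is.numeric(bin_width), length(bin_width) == 1L, bin_width > 0)
  n <- 360 / bin_width
  if (abs(n - round(n)) > 1e-9) {
    stop("`bin_width` must divide 360 exactly", call. = FALSE)
  }
  n <- as.integer(round(n))
  centers <- seq(-180, by = bin_width, length.out = n)
  # argmax tie rule: smallest |angle| wins, positive member of a +/- pair first
  pref <- order(abs(centers), -centers)
  structure(
    list(bin_width = bin_width, centers = centers, n_bins = n, pref = pref),
    class = "direction_grid"
  )
}

#' @export
print.direction_grid <- function(x, ...) {
  cat(sprintf(
    "<direction_grid> %d bins of %.3g deg covering [-180, 180)\n",
    x$n_bins, x$bin_width
  ))
  invisible(x)
}

#' Wrap angles into [-180, 180)
#'
#' @param theta Numeric vector of angles in degrees.
#' @return Angles wrapped to the circular interval \[-180, 180).
#' @export
wrap_angle <- function(theta) {
  ((theta + 180) %% 360) - 180
}

# Wrapped Gaussian density on the circle, evaluated at `theta` (degrees).
# Sums enough 360-degree replicates for the tails at the given sigma.
wrapped_gaussian <- function(theta, mu, sigma) {
  n_wrap <- max(1L, ceiling(4 * sigma / 360))
  out <- 0
  for (k in -n_wrap:n_wrap) {
    out <- out + stats::dnorm(theta - mu + 360 * k, sd = sigma)
  }
  out
}

#' Stimulus configuration
#'
#' The plaid stimulus is summarized by the component direction magnitude
#' `theta_S` (components at +/- theta_S), the pattern direction `theta_L`
#' (fixed at 0 in the default design), and the pattern mixture weight `A_L`,
#' identified with the proportion of line-intersection (LI) apertures.
#' The component weight is always `A_S = 1 - A_L`.
#'
#' @param theta_S Component direction magnitude in degrees (> 0); default 60.
#' @param theta_L Pattern direction in degrees; default 0.
#' @param A_L Pattern mixture weight in \[0, 1\] (LI-aperture proportion).
#' @return An object of class `stimulus_config`.
#' @export
stimulus_config <- function(theta_S = 60, theta_L = 0, A_L = 0.5) {
  stopifnot(is.numeric(theta_S), length(theta_S) == 1L, is.finite(theta_S))
  if (theta_S <= 0) stop("`theta_S` must be strictly positive", call. = FALSE)
  stopifnot(is.numeric(A_L), length(A_L) == 1L, is.finite(A_L))
  if (A_L < 0 || A_L > 1) stop("`A_L` must lie in [0, 1]", call. = FALSE)
  structure(
    list(theta_S = theta_S, theta_L = theta_L, A_L = A_L, A_S = 1 - A_L),
    class = "stimulus_config"
  )
}

#' Sensory likelihood widths
#'
#' @param sigma_S Width (degrees) of each component likelihood term.
#' @param sigma_L Width (degrees) of the pattern likelihood term.
#' @return An object of class `sensory_params`.
#' @export
sensory_params <- function(sigma_S, sigma_L) {
  for (s in c(sigma_S, sigma_L)) {
    if (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0) {
      stop("sensory sigmas must be strictly positive and finite", call. = FALSE)
    }
  }
  structure(list(sigma_S = sigma_S, sigma_L = sigma_L), class = "sensory_params")
}

#' Conditional prior widths
#'
#' Widths of the two conditional hypothesis priors: `sigma_P` for the
#' integrating (pattern-enhancing) prior and `sigma_C` for the segregating
#' (pattern-inhibiting) prior. Either may be absent (`NULL`) when the model
#' variant does not use it.
#'
#' @param sigma_P Integrating prior width in degrees, or `NULL`.
#' @param sigma_C Segregating prior width in degrees, or `NULL`.
#' @return An object of class `prior_params`.
#' @export
prior_params <- function(sigma_P = NULL, sigma_C = NULL) {
  for (s in list(sigma_P, sigma_C)) {
    if (!is.null(s) &&
        (!is.numeric(s) || length(s) != 1L || !is.finite(s) || s <= 0)) {
      stop("prior sigmas must be strictly positive when present", call. = FALSE)
    }
  }
  structure(list(sigma_P = sigma_P, sigma_C = sigma_C), class = "prior_params")
}

#' Model variants
#'
#' @description
#' Four observer architectures differing in conditional prior use:
#' * M1 — no prior (flat in direction space);
#' * M2 — integrating prior applied on trials where the early decision
#'   chooses the pattern hypothesis (chi = 1);
#' * M3 — segregating prior applied on trials where the early decision
#'   chooses the component hypothesis (chi = 2);
#' * M4 — control using both conditional priors.
#'
#' @param variant One of `"M1"`, `"M2"`, `"M3"`, `"M4"`.
#' @param priors A [prior_params()] object (or `NULL` for M1).
#' @return `check_variant_priors()` invisibly returns `TRUE` or throws a
#'   configuration error naming the missing prior width.
#' @export
check_variant_priors <- function(variant, priors = NULL) {
  variant <- match.arg(variant, c("M1", "M2", "M3", "M4"))
  need_p <- variant %in% c("M2", "M4")
  need_c <- variant %in% c("M3", "M4")
  if (need_p && is.null(priors$sigma_P)) {
    stop(sprintf("variant %s requires `sigma_P` in its prior_params", variant),
         call. = FALSE)
  }
  if (need_c && is.null(priors$sigma_C)) {
    stop(sprintf("variant %s requires `sigma_C` in its prior_params", variant),
         call. = FALSE)
  }
  invisible(TRUE)
}

#' Direction-space likelihood mixture
#'
#' The sensory likelihood over perceived direction is a normalized
#' three-component mixture of wrapped Gaussians: weight `A_S/2` at each
#' component direction (+/- theta_S, width sigma_S) and weight `A_L` at the
#' pattern direction (theta_L = 0, width sigma_L).
#'
#' @param grid A [direction_grid()].
#' @param stim A [stimulus_config()].
#' @param sens A [sensory_params()].
#' @return A `density_on_grid` object: list with `grid`, `values`
#'   (per-bin density), and `normalized = TRUE`
#'   (`sum(values) * bin_width == 1`).
#' @export
likelihood_pdf <- function(grid, stim, sens) {
  stopifnot(inherits(grid, "direction_grid"), inherits(stim, "stimulus_config"),
            inherits(sens, "sensory_params"))
  th <- grid$centers
  v <- stim$A_S / 2 * wrapped_gaussian(th, -stim$theta_S, sens$sigma_S) +
    stim$A_S / 2 * wrapped_gaussian(th, +stim$theta_S, sens$sigma_S) +
    stim$A_L * wrapped_gaussian(th, stim$theta_L, sens$sigma_L)
  v <- v / (sum(v) * grid$bin_width)
  structure(list(grid = grid, values = v, normalized = TRUE),
            class = "density_on_grid")
}

#' @export
print.density_on_grid <- function(x, ...) {
  cat(sprintf(
    "<density_on_grid> %d bins, %s, peak %.4g at %g deg\n",
    x$grid$n_bins, if (isTRUE(x$normalized)) "normalized" else "weights",
    max(x$values), x$grid$centers[which.max(x$values)]
  ))
  invisible(x)
}

#' Integrating (pattern-enhancing) prior weights
#'
#' A wrapped Gaussian centered on the pattern / vector-average direction
#' (0 degrees), returned as an unnormalized multiplicative weight function
#' with its maximum scaled to 1. Multiplying a posterior by this weight
#' enhances the pattern direction and supports integration.
#'
#' @param grid A [direction_grid()].
#' @param sigma_P Prior width in degrees (> 0).
#' @return A `density_on_grid` with `normalized = FALSE`; values in (0, 1\].
#' @export
integrate_prior <- function(grid, sigma_P) {
  stopifnot(inherits(grid, "direction_grid"))
  if (!is.numeric(sigma_P) || length(sigma_P) != 1L || !is.finite(sigma_P) ||
      sigma_P <= 0) {
    stop("`sigma_P` must be strictly positive", call. = FALSE)
  }
  w <- wrapped_gaussian(grid$centers, 0, sigma_P)
  structure(list(grid = grid, values = w / max(w), normalized = FALSE),
            class = "density_on_grid")
}

#' Segregating (pattern-inhibiting) prior weights
#'
#' The complement `1 - g(theta)` of a peak-scaled wrapped Gaussian `g` of
#' width `sigma_C` centered on 0 degrees: a weight function with its minimum
#' (exactly 0) at the pattern direction and its maximum near +/-180 degrees,
#' i.e. a prior centered diametrically opposite the average stimulus
#' direction in circular direction space. Multiplying by it inhibits the
#' pattern direction and supports segregation into components.
#'
#' @param grid A [direction_grid()].
#' @param sigma_C Prior width in degrees (> 0).
#' @return A `density_on_grid` with `normalized = FALSE`; values in \[0, 1\].
#' @export
segregate_prior <- function(grid, sigma_C) {
  stopifnot(inherits(grid, "direction_grid"))
  if (!is.numeric(sigma_C) || length(sigma_C) != 1L || !is.finite(sigma_C) ||
      sigma_C <= 0) {
    stop("`sigma_C` must be strictly positive", call. = FALSE)
  }
  g <- wrapped_gaussian(grid$centers, 0, sigma_C)
  structure(list(grid = grid, values = 1 - g / max(g), normalized = FALSE),
            class = "density_on_grid")
}

# Prior weight vector selected by (variant, chi). Flat (all ones) unless the
# variant applies a conditional prior for this chi.
prior_weights_for <- function(grid, variant, chi, priors = NULL) {
  variant <- match.arg(variant, c("M1", "M2", "M3", "M4"))
  stopifnot(chi %in% c(1L, 2L))
  if (chi == 1L && variant %in% c("M2", "M4")) {
    integrate_prior(grid, priors$sigma_P)$values
  } else if (chi == 2L && variant %in% c("M3", "M4")) {
    segregate_prior(grid, priors$sigma_C)$values
  } else {
    rep(1, grid$n_bins)
  }
}

#' Conditional posterior after the early categorical decision
#'
#' Multiplies a normalized direction histogram bin-wise by the prior weight
#' selected by the model variant and the early decision chi, then
#' renormalizes to total mass 1. Under M1 (or whenever the variant applies
#' no prior for this chi) the input is returned unchanged.
#'
#' @param hist A normalized `density_on_grid` (e.g. from [likelihood_pdf()]
#'   or a binned sample histogram scaled to a density).
#' @param variant Model variant tag, `"M1"`..`"M4"`.
#' @param chi Early categorical decision, 1 (integrate) or 2 (segregate).
#' @param priors A [prior_params()] supplying the widths the variant needs.
#' @return A normalized `density_on_grid`.
#' @export
conditional_posterior <- function(hist, variant, chi, priors = NULL) {
  stopifnot(inherits(hist, "density_on_grid"), isTRUE(hist$normalized))
  chi <- as.integer(chi)
  check_variant_priors(variant, priors)
  w <- prior_weights_for(hist$grid, variant, chi, priors)
  v <- hist$values * w
  total <- sum(v) * hist$grid$bin_width
  if (total <= 0) {
    stop("posterior has zero mass after prior weighting", call. = FALSE)
  }
  structure(list(grid = hist$grid, values = v / total, normalized = TRUE),
            class = "density_on_grid")
}

#' Early categorical decision (chi heuristic)
#'
#' Commits to the pattern hypothesis (chi = 1) when the early direction
#' estimate `theta_max` is closer to the pattern direction (0 degrees) than
#' to the component directions (+/- theta_S), i.e. when
#' `|theta_max| < theta_S / 2`; otherwise to the component hypothesis
#' (chi = 2). The boundary `|theta_max| == theta_S / 2` maps to chi = 2
#' (documented tie rule).
#'
#' @param theta_max Early-stage histogram argmax, degrees in \[-180, 180).
#' @param theta_S Component direction magnitude in degrees.
#' @return Integer vector of 1s and 2s.
#' @export
chi_decision <- function(theta_max, theta_S = 60) {
  ifelse(abs(theta_max) < theta_S / 2, 1L, 2L)
}
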