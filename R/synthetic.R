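#' Factorial experiment design
#'
#' The psychophysics design: 2 regularity experiments x 3 aperture
#' densities x 11 equally spaced LI proportions (0-100%) x 30 trials per
#' point, per subject.
#'
#' @param experiments Experiment labels.
#' @param densities Aperture counts.
#' @param n_levels Number of LI-proportion levels (equally spaced, both
#'   endpoints included).
#' @param trials_per_level Trials per psychometric point.
#' @param n_subjects Cohort size.
#' @return An object of class `experiment_design` (with a `levels_pct`
#'   element).
#' @export
experiment_design <- function(experiments = c("regular", "irregular"),
                              densities = c(180, 340, 680),
                              n_levels = 11, trials_per_level = 30,
                              n_subjects = 5) {
  stopifnot(n_levels >= 2, trials_per_level >= 1, n_subjects >= 1,
            length(densities) >= 1)
  structure(
    list(experiments = experiments, densities = densities,
         n_levels = as.integer(n_levels),
         trials_per_level = as.integer(trials_per_level),
         n_subjects = as.integer(n_subjects),
         levels_pct = seq(0, 100, length.out = n_levels)),
    class = "experiment_design"
  )
}

#' Construct a ground-truth synthetic observer
#'
#' Builds per-(experiment, density) observer parameters whose behavioural
#' consequence mimics the density/regularity signature: one sensory width
#' shrinks with aperture density as a power law
#' `sigma(d) = sigma_base * (d / d0)^(-gamma)` with `gamma = strength` in
#' the regular experiment and `gamma = strength * irregular_attenuation`
#' in the irregular one. Because a sharper (taller) likelihood peak wins
#' the MAP competition, shrinking the component width `sigma_S` drives the
#' observer toward transparency and shrinking the pattern width `sigma_L`
#' toward coherence; `bias_direction` names the percept toward which the
#' observer's bias grows with density.
#'
#' @param bias_direction `"transparent"` (density shrinks sigma_S) or
#'   `"coherent"` (density shrinks sigma_L).
#' @param strength Power-law exponent gamma (>= 0; 0 = no density effect).
#' @param seed Integer seed; adds a small deterministic log-normal jitter
#'   to the base widths so cohort members differ.
#' @param subject_id Subject label.
#' @param base_sigma_S,base_sigma_L Base sensory widths (degrees) at the
#'   lowest density.
#' @param sigma_C,sigma_P Prior widths (degrees) for the generating variant.
#' @param variant Generating model variant (default `"M3"`).
#' @param irregular_attenuation Multiplier on `strength` in the irregular
#'   experiment (default 0.25).
#' @param jitter_sd Log-scale SD of the per-observer jitter (default 0.1).
#' @param design An [experiment_design()].
#' @return An object of class `synthetic_observer`: subject id, variant,
#'   bias direction, strength, seed, and `params[[experiment]][[density]]`
#'   each holding `sens` and `priors`.
#' @export
make_observer <- function(bias_direction = c("transparent", "coherent"),
                          strength = 0.3, seed = 1L, subject_id = "s1",
                          base_sigma_S = 15, base_sigma_L = 10,
                          sigma_C = 30, sigma_P = 60, variant = "M3",
                          irregular_attenuation = 0.25, jitter_sd = 0.1,
                          design = experiment_design()) {
  bias_direction <- match.arg(bias_direction)
  if (!is.numeric(strength) || strength < 0) {
    stop("`strength` must be >= 0", call. = FALSE)
  }
  variant <- match.arg(variant, c("M1", "M2", "M3", "M4"))
  check_variant_priors(variant, prior_params(sigma_P = sigma_P,
                                             sigma_C = sigma_C))
  set.seed(derive_seed(seed, 104729L))
  jit <- exp(stats::rnorm(2, 0, jitter_sd))
  s_S <- base_sigma_S * jit[1]
  s_L <- base_sigma_L * jit[2]
  d0 <- min(design$densities)
  params <- list()
  for (e in design$experiments) {
    gamma <- if (e == "regular") strength else strength * irregular_attenuation
    params[[e]] <- list()
    for (d in design$densities) {
      scale <- (d / d0)^(-gamma)
      sens <- if (bias_direction == "transparent") {
        sensory_params(sigma_S = s_S * scale, sigma_L = s_L)
      } else {
        sensory_params(sigma_S = s_S, sigma_L = s_L * scale)
      }
      params[[e]][[as.character(d)]] <- list(
        sens = sens,
        priors = prior_params(
          sigma_P = if (variant %in% c("M2", "M4")) sigma_P else NULL,
          sigma_C = if (variant %in% c("M3", "M4")) sigma_C else NULL
        )
      )
    }
  }
  structure(
    list(subject_id = subject_id, variant = variant,
         bias_direction = bias_direction, strength = strength,
         seed = as.integer(seed), params = params,
         irregular_attenuation = irregular_attenuation),
    class = "synthetic_observer"
  )
}

#' @export
print.synthetic_observer <- function(x, ...) {
  p0 <- x$params[[1]][[1]]$sens
  cat(sprintf(
    "<synthetic_observer> %s: %s, %s-biased (strength %.2f), base sigma_S=%.1f sigma_L=%.1f\n",
    x$subject_id, x$variant, x$bias_direction, x$strength,
    p0$sigma_S, p0$sigma_L))
  invisible(x)
}

#' Simulate a full synthetic experiment for one observer
#'
#' Runs the method-of-constant-stimuli design through the trial simulator:
#' for every (experiment, density, level) cell, `trials_per_level` trials
#' with the observer's condition-specific parameters. Each cell gets its
#' own RNG substream, so the table is reproducible cell-by-cell.
#'
#' @param spec A [make_observer()] result.
#' @param design An [experiment_design()].
#' @param settings A [sim_settings()]; its seed combines with the
#'   observer's seed.
#' @return A `trial_table` data.frame with columns `subject`, `experiment`,
#'   `density`, `level_pct`, `trial`, `response`.
#' @export
generate_experiment <- function(spec, design = experiment_design(),
                                settings = sim_settings()) {
  stopifnot(inherits(spec, "synthetic_observer"),
            inherits(design, "experiment_design"))
  for (e in design$experiments) {
    if (is.null(spec$params[[e]])) {
      stop(sprintf("observer has no parameters for experiment '%s'", e),
           call. = FALSE)
    }
    for (d in design$densities) {
      if (is.null(spec$params[[e]][[as.character(d)]])) {
        stop(sprintf("observer has no parameters for density %s", d),
             call. = FALSE)
      }
    }
  }
  stim <- stimulus_config()
  rows <- list()
  for (ei in seq_along(design$experiments)) {
    e <- design$experiments[ei]
    for (di in seq_along(design$densities)) {
      d <- design$densities[di]
      cell <- spec$params[[e]][[as.character(d)]]
      for (li in seq_along(design$levels_pct)) {
        lev <- design$levels_pct[li]
        set.seed(derive_seed(settings$seed, spec$seed, ei, di, li))
        tr <- simulate_level_trials(lev / 100, design$trials_per_level,
                                    stim, cell$sens, cell$priors,
                                    spec$variant, settings)
        rows[[length(rows) + 1L]] <- data.frame(
          subject = spec$subject_id, experiment = e, density = d,
          level_pct = lev, trial = seq_len(design$trials_per_level),
          response = tr$percept, stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("trial_table", "data.frame")
  out
}

#' Build a cohort of synthetic observers
#'
#' @param n_subjects Cohort size (default 5).
#' @param bias_mix Named proportions for the bias directions, summing to 1
#'   (default 3:2 coherent:transparent, mirroring a small mixed cohort).
#' @param strength Shared density-effect strength.
#' @param seed Base seed; per-subject seeds are derived from it unless
#'   `seeds` is given.
#' @param seeds Optional explicit integer seed per subject.
#' @param ... Further arguments passed to [make_observer()].
#' @return List of `synthetic_observer` objects.
#' @export
make_cohort <- function(n_subjects = 5,
                        bias_mix = c(coherent = 0.6, transparent = 0.4),
                        strength = 0.3, seed = 1L, seeds = NULL, ...) {
  stopifnot(n_subjects >= 1)
  if (is.null(names(bias_mix)) ||
      !all(names(bias_mix) %in% c("coherent", "transparent")) ||
      abs(sum(bias_mix) - 1) > 1e-9 || any(bias_mix < 0)) {
    stop("`bias_mix` must be named proportions over coherent/transparent summing to 1",
         call. = FALSE)
  }
  if (is.null(seeds)) {
    seeds <- vapply(seq_len(n_subjects), function(i) derive_seed(seed, i),
                    integer(1))
  }
  stopifnot(length(seeds) == n_subjects)
  n_coh <- round(n_subjects * bias_mix[["coherent"]])
  dirs <- c(rep("coherent", n_coh), rep("transparent", n_subjects - n_coh))
  lapply(seq_len(n_subjects), function(i) {
    make_observer(bias_direction = dirs[i], strength = strength,
                  seed = seeds[i], subject_id = sprintf("s%d", i), ...)
  })
}

#' Write / read a trial table as CSV
#'
#' Plain CSV with header `subject,experiment,density,level_pct,trial,response`.
#'
#' @param table A `trial_table` data.frame.
#' @param path File path.
#' @return `read_trial_table()` returns a validated `trial_table`.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(is.data.frame(table))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_table
#' @export
read_trial_table <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject", "experiment", "density", "level_pct", "trial", "response")
  if (!all(need %in% names(tab))) {
    stop("trial table must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (!all(tab$response %in% c("coherent", "transparent"))) {
    stop("responses must be 'coherent' or 'transparent'", call. = FALSE)
  }
  tab$subject <- as.character(tab$subject)
  class(tab) <- c("trial_table", "data.frame")
  tab
}

#' Aggregate a trial table into per-condition psychometric data
#'
#' @param table A `trial_table`.
#' @return A named list of [psychometric_data()], keyed
#'   `subject|experiment|density`, with a `keys` data.frame attribute.
#' @export
trials_to_psychometric <- function(table) {
  stopifnot(is.data.frame(table))
  keys <- unique(table[, c("subject", "experiment", "density")])
  keys <- keys[order(keys$subject, keys$experiment, keys$density), ,
               drop = FALSE]
  rownames(keys) <- NULL
  out <- vector("list", nrow(keys))
  names(out) <- paste(keys$subject, keys$experiment, keys$density, sep = "|")
  for (i in seq_len(nrow(keys))) {
    sub <- table[table$subject == keys$subject[i] &
                 table$experiment == keys$experiment[i] &
                 table$density == keys$density[i], ]
    lv <- sort(unique(sub$level_pct))
    f <- factor(sub$level_pct, levels = lv)
    n <- as.integer(table(f))
    k <- as.integer(tapply(sub$response == "coherent", f, sum))
    out[[i]] <- psychometric_data(lv, n, k)
  }
  attr(out, "keys") <- keys
  out
}
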