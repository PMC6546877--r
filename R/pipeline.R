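#' Group-level linear trend of a statistic on density
#'
#' Ordinary least-squares regression of a per-(subject, density) statistic
#' (bias magnitude or PSI) on aperture density, reporting slope, intercept,
#' r-squared and the two-sided p-value for the slope.
#'
#' @param values Numeric statistic, one per (subject, density) pair.
#' @param densities Matching densities.
#' @param label Optional condition label carried in the result.
#' @return An object of class `group_trend`: `slope`, `intercept`,
#'   `r_squared`, `p_value`, `n`, `label`.
#' @export
density_trend <- function(values, densities, label = "") {
  stopifnot(length(values) == length(densities), length(values) >= 3)
  if (length(unique(densities)) < 2) {
    stop("constant predictor: need at least two distinct densities",
         call. = FALSE)
  }
  if (stats::var(values) == 0) {
    # flat input: no trend by definition
    return(structure(
      list(slope = 0, intercept = values[1], r_squared = 0,
           p_value = NA_real_, n = length(values), label = label),
      class = "group_trend"
    ))
  }
  fit <- stats::lm(values ~ densities)
  # summary.lm warns on an exactly collinear fit; the r^2/p are still valid
  sm <- suppressWarnings(summary(fit))
  co <- stats::coef(sm)
  p <- if (nrow(co) >= 2 && !is.na(co[2, 4])) co[2, 4] else NA_real_
  structure(
    list(slope = unname(stats::coef(fit)[2]),
         intercept = unname(stats::coef(fit)[1]),
         r_squared = sm$r.squared, p_value = p,
         n = length(values), label = label),
    class = "group_trend"
  )
}

#' @export
print.group_trend <- function(x, ...) {
  cat(sprintf(
    "<group_trend>%s slope = %.4g, r^2 = %.3f, p = %.4g (n = %d)\n",
    if (nzchar(x$label)) paste0(" [", x$label, "]") else "",
    x$slope, x$r_squared, x$p_value, x$n))
  invisible(x)
}

#' Correlate fitted sensory width with perceptual bias
#'
#' Joins fitted observer parameters and bias estimates on
#' (subject, experiment, density) and regresses the bias (positive =
#' transparent-shifted) on the fitted component width `sigma_S`, per
#' experiment, collapsing across densities.
#'
#' @param fits data.frame with columns `subject`, `experiment`, `density`,
#'   `sigma_S`.
#' @param biases data.frame with columns `subject`, `experiment`, `density`,
#'   `bias`.
#' @return Named list (one `group_trend` per experiment).
#' @export
sigma_bias_correlation <- function(fits, biases) {
  need_f <- c("subject", "experiment", "density", "sigma_S")
  need_b <- c("subject", "experiment", "density", "bias")
  stopifnot(all(need_f %in% names(fits)), all(need_b %in% names(biases)))
  merged <- merge(fits[, need_f], biases[, need_b],
                  by = c("subject", "experiment", "density"))
  if (nrow(merged) < nrow(fits) || nrow(merged) < nrow(biases)) {
    stop("key mismatch: fits and biases do not share all (subject, experiment, density) keys",
         call. = FALSE)
  }
  out <- list()
  for (e in unique(merged$experiment)) {
    sub <- merged[merged$experiment == e, ]
    out[[e]] <- density_trend(sub$bias, sub$sigma_S,
                              label = paste0("bias~sigma_S|", e))
  }
  out
}

#' Run configuration for the end-to-end pipeline
#'
#' @param out_dir Output directory for JSON results and the trial CSV.
#' @param seed Master seed; all stage seeds derive from it.
#' @param design An [experiment_design()].
#' @param settings A [sim_settings()].
#' @param cohort_args List of arguments for [make_cohort()].
#' @param n_bootstrap Bootstrap replicates per psychometric fit (0 skips
#'   the bootstrap).
#' @param variants Model variants to fit and compare (empty vector skips
#'   model fitting).
#' @param search_cfg A [fit_search_config()] for model fitting.
#' @param trial_csv Optional path to an existing trial-table CSV; when
#'   given, the synthesis stage is skipped and the CSV is analyzed instead.
#' @return An object of class `run_config`.
#' @export
run_config <- function(out_dir, seed = 1L, design = experiment_design(),
                       settings = NULL, cohort_args = list(),
                       n_bootstrap = 400, variants = character(0),
                       search_cfg = fit_search_config(), trial_csv = NULL) {
  if (is.null(settings)) settings <- sim_settings(seed = seed)
  if (length(variants) > 0) {
    variants <- match.arg(variants, c("M1", "M2", "M3", "M4"),
                          several.ok = TRUE)
  }
  structure(
    list(out_dir = out_dir, seed = as.integer(seed), design = design,
         settings = settings, cohort_args = cohort_args,
         n_bootstrap = n_bootstrap, variants = variants,
         search_cfg = search_cfg, trial_csv = trial_csv),
    class = "run_config"
  )
}

#' Analyze a trial table: fits, bias, PSI per subject and condition
#'
#' Fits a psychometric function per (subject, experiment, density), builds
#' the per-experiment reference by pooling every subject's lowest-density
#' trials and fitting once, and derives the bias (PSE minus reference PSE)
#' and the 75%-confidence perceptual stability index for each condition.
#'
#' @param table A `trial_table`.
#' @param n_bootstrap Bootstrap replicates per fit (0 to skip).
#' @param seed Seed for the bootstrap resampling.
#' @param psi_threshold Confidence cutoff for the PSI.
#' @return List with `results` (data.frame: subject, experiment, density,
#'   pse, slope, bias, psi, dominant, plus bootstrap SE columns when
#'   requested), `reference` (per-experiment reference PSEs), and `fits`
#'   (named list of `psychometric_fit`).
#' @export
analyze_trials <- function(table, n_bootstrap = 400, seed = 1L,
                           psi_threshold = 0.75) {
  pdata <- trials_to_psychometric(table)
  keys <- attr(pdata, "keys")
  low_density <- min(keys$density)

  reference <- list()
  for (e in unique(keys$experiment)) {
    pooled <- table[table$experiment == e & table$density == low_density, ]
    pooled$subject <- "pooled"
    pooled_pd <- trials_to_psychometric(pooled)[[1]]
    reference[[e]] <- fit_psychometric(pooled_pd)
  }

  fits <- list()
  rows <- list()
  for (i in seq_len(nrow(keys))) {
    key <- names(pdata)[i]
    fit <- fit_psychometric(pdata[[i]])
    fits[[key]] <- fit
    ref <- reference[[keys$experiment[i]]]
    bias <- estimate_bias(fit, ref)
    psi <- compute_psi(fit, pdata[[i]]$levels, threshold = psi_threshold,
                       bias = bias$value)
    row <- data.frame(
      subject = keys$subject[i], experiment = keys$experiment[i],
      density = keys$density[i], pse = fit$pse, slope = fit$slope,
      bias = bias$value, psi = psi$psi, dominant = psi$dominant,
      stringsAsFactors = FALSE
    )
    if (n_bootstrap > 0) {
      bt <- bootstrap_fit(pdata[[i]], n_resamples = n_bootstrap,
                          seed = derive_seed(seed, i))
      row$pse_se <- stats::sd(bt$pse)
      row$boot_failed <- bt$n_failed
    }
    rows[[i]] <- row
  }
  results <- do.call(rbind, rows)
  rownames(results) <- NULL
  list(results = results,
       reference = lapply(reference, function(f) f$pse),
       fits = fits)
}

#' Run the full analysis pipeline
#'
#' Synthesize (or load) a trial table, fit psychometric functions with
#' bootstrap, derive bias and PSI per subject and condition, optionally fit
#' and compare observer-model variants, compute the group-level density
#' trends, and write all results as JSON under `config$out_dir`.
#'
#' @param config A [run_config()].
#' @return Invisibly, a list with `table`, `analysis`, `trends`,
#'   `model_comparisons` (or `NULL`), and the output file paths.
#' @export
run_end_to_end <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  # stage 1: data
  if (!is.null(config$trial_csv)) {
    table <- read_trial_table(config$trial_csv)
  } else {
    cohort <- do.call(make_cohort,
                      c(list(seed = config$seed, design = config$design),
                        config$cohort_args))
    tabs <- lapply(cohort, generate_experiment, design = config$design,
                   settings = config$settings)
    table <- do.call(rbind, tabs)
    class(table) <- c("trial_table", "data.frame")
    write_trial_table(table, file.path(config$out_dir, "trials.csv"))
  }

  # stage 2: psychometrics, bias, PSI
  analysis <- withCallingHandlers(
    analyze_trials(table, n_bootstrap = config$n_bootstrap,
                   seed = derive_seed(config$seed, 2L)),
    error = function(e) {
      stop("stage 'psychometrics' failed: ", conditionMessage(e),
           call. = FALSE)
    }
  )
  res <- analysis$results

  # stage 3: optional model fitting and AIC comparison per subject
  model_comparisons <- NULL
  if (length(config$variants) > 0) {
    pdata <- trials_to_psychometric(table)
    keys <- attr(pdata, "keys")
    model_comparisons <- list()
    for (s in unique(keys$subject)) {
      conds <- pdata[keys$subject == s]
      model_comparisons[[s]] <- compare_models(
        conds, variants = config$variants, search_cfg = config$search_cfg,
        settings = config$settings
      )
    }
  }

  # stage 4: group trends (|bias| and PSI on density, per experiment)
  trends <- list()
  for (e in unique(res$experiment)) {
    sub <- res[res$experiment == e, ]
    trends[[paste0("bias_", e)]] <-
      density_trend(abs(sub$bias), sub$density, label = paste0("abs-bias|", e))
    trends[[paste0("psi_", e)]] <-
      density_trend(sub$psi, sub$density, label = paste0("psi|", e))
  }

  paths <- list(
    results = file.path(config$out_dir, "results.json"),
    trends = file.path(config$out_dir, "trends.json"),
    log = file.path(config$out_dir, "run_log.json")
  )
  jsonlite::write_json(res, paths$results, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  jsonlite::write_json(lapply(trends, unclass), paths$trends,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(model_comparisons)) {
    paths$models <- file.path(config$out_dir, "model_comparison.json")
    jsonlite::write_json(
      lapply(model_comparisons, function(mc) {
        list(aic = as.list(mc$aic), delta_aic = as.list(mc$delta_aic),
             best = mc$best)
      }),
      paths$models, auto_unbox = TRUE, digits = NA, pretty = TRUE
    )
  }
  jsonlite::write_json(
    list(seed = config$seed, n_bootstrap = config$n_bootstrap,
         variants = as.list(config$variants),
         n_full = config$settings$n_full,
         early_fraction = config$settings$early_fraction,
         bin_width = config$settings$grid$bin_width,
         reference_pse = analysis$reference,
         package_version = as.character(utils::packageVersion("plaidobs"))),
    paths$log, auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  invisible(list(table = table, analysis = analysis, trends = trends,
                 model_comparisons = model_comparisons, paths = paths))
}
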