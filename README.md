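# plaidobs

Bayesian causal-inference observer models for bistable plaid-motion
perception, with the psychophysics statistics to go with them.

A moving line-plaid built from local 1D elements (separated lines, SL) and
2D elements (line intersections, LI) is bistable: observers report either
one **coherent** pattern moving in the vector-average direction (0°) or two
**transparent** surfaces sliding along the component directions (±60°). The
LI proportion parametrically controls which percept wins, and individual
observers differ in their bias toward one interpretation — a bias that
grows with stimulus element density when the scene geometry is regular.

`plaidobs` is for modellers and psychophysicists who want to simulate and
fit this class of hierarchical observer models end to end:

* **Probabilistic core** — the direction-space likelihood
  `P(θm|θ) = (A_S/2) N(−θ_S, σ_S) + (A_S/2) N(+θ_S, σ_S) + A_L N(0, σ_L)`
  on a 0.5°-binned circular space, conditional priors that enhance
  (integrating, width σ_P) or inhibit (segregating, width σ_C) the pattern
  direction, the early categorical commitment χ (integrate iff the early
  direction estimate falls within θ_S/2 = 30° of the pattern), and the
  prior-conditioned MAP readout. Model variants: M1 (no prior), M2
  (integrating prior on χ=1 trials), M3 (segregating prior on χ=2 trials),
  M4 (both; control).
* **Trial simulator** — the two-stage Monte-Carlo protocol (20% of 5000
  samples for χ, fresh 5000 for the MAP stage), vectorized and compiled,
  with per-condition RNG substreams and common-random-number multi-variant
  readouts.
* **Psychometrics** — binomial cumulative-Gaussian fits (PSE, slope),
  400-resample bootstrap, perceptual bias relative to a pooled low-density
  reference, and the 75%-confidence perceptual stability index (PSI).
* **Model fitting** — Kullback–Leibler minimization over simulated
  psychometric functions with a deterministic staged search, and AIC-based
  comparison of M1–M4 (binomial-likelihood AIC by default; the
  Gaussian-residual form `n·ln(rss/n) + 2k` via `residual_aic()`).
* **Synthetic cohorts** — ground-truth observers whose sensory widths
  follow a density power law (amplified under regular geometry, attenuated
  0.25× under irregular), a full method-of-constant-stimuli trial-table
  generator (2 experiments × 3 densities × 11 levels × 30 trials), CSV
  round-tripping, and an end-to-end pipeline with JSON outputs.

## Worked example

```r
library(plaidobs)

# one synthetic observer, full factorial design
obs <- make_observer("transparent", strength = 0.3, seed = 42)
#> <synthetic_observer> s1: M3, transparent-biased (strength 0.30),
#>                      base sigma_S=14.0 sigma_L=10.2
trials <- generate_experiment(obs, settings = sim_settings(seed = 42))
nrow(trials)
#> [1] 1980

# psychometric fits, bias and stability per condition
analysis <- analyze_trials(trials, n_bootstrap = 100)
round(subset(analysis$results, experiment == "regular",
             select = c(density, pse, bias, psi, pse_se)), 3)
#>   density    pse  bias   psi pse_se
#> 4     180 29.747 0.000 0.636  0.343
#> 5     340 34.606 4.859 0.636  1.539
#> 6     680 39.501 9.754 0.545  0.379

# group-level density trend of the bias magnitude (regular experiment)
reg <- subset(analysis$results, experiment == "regular")
density_trend(abs(reg$bias), reg$density, label = "abs bias ~ density")
#> <group_trend> [abs bias ~ density] slope = 0.01871, r^2 = 0.959,
#>               p = 0.1291 (n = 3)
```

Reading the numbers: this transparent-biased observer's 50% coherence
threshold (PSE) climbs from 29.7% LI at 180 apertures to 39.5% at 680 —
it needs ever more intersection elements to see coherence, a bias of
+9.8% LI at the highest density relative to the low-density reference
(here the observer's own 180-aperture fit, hence bias = 0 there). `pse_se`
is the bootstrap standard error of the PSE; `psi` is the fraction of the
11 stimulus levels at which the fitted curve is confidently (>75%) on the
dominant percept's side. The density trend of |bias| is strongly positive
(r² = 0.96 over the three densities of this single observer; group
analyses use 5 subjects × 3 densities per experiment).

Model fitting and comparison, on the same observer's high-density regular
condition:

```r
pdata <- trials_to_psychometric(trials)
mc <- compare_models(pdata[["s1|regular|680"]])
mc$best       # which of M1..M4 minimizes the summed AIC
mc$delta_aic  # AIC differences to the best variant
```

## Acceptance script

`scripts/acceptance.R` regenerates a synthetic psychometric experiment at
the default design scale from the seed you pass, fits the psychometric
curve, and recomputes the reported quantity from scratch (for target `t1`,
the predicted response probability evaluated exactly at the fitted PSE):

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

The methods vignette (`vignettes/observer-models.Rmd`) documents the model
assumptions, the numerical choices (binning, truncations, tie rules,
clipping), what the synthetic generator does and does not emulate, and the
known identifiability limits of the fitting problem.
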