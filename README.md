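# picosocial

Growth-strategy analysis for picoplankton co-culture experiments: do
lineages (strains) of a single species modulate their maximum growth rate in
response to the mere presence of non-self conspecifics, and is that
capacity predicted by how much photosynthetically fixed carbon a lineage
has to spare?

The package is aimed at microbial ecologists and experimental-evolution
researchers working with batch-culture growth assays and flow-cytometric
counting. It provides the full analysis chain together with a
synthetic-experiment generator, so every stage is testable against a known
ground truth without any external data.

## The quantities at the core

* **Specific growth rate** from exponential, density-independent batch
  growth: `mu = (ln N_t − ln N_0) / t` (day⁻¹), two-point by default, with
  an optional log-linear fit over all daily counts.
* **Response ratio** of a focal lineage to a social cue:
  `R = mu_treatment / mu_alone`. `R = 1` means no reaction; `R > 1` faster
  growth with conspecifics present; `R < 1` slower.
* **Surplus net photosynthesis**: oxygen-based NP converted to
  biomass-specific carbon fixation, `NP_C = (NP_O2 / PQ) · 12.011 / Q_C`
  (h⁻¹, with PQ the photosynthetic quotient and `Q_C` the cellular carbon
  quota), compared with the carbon demand of growth `mu / 24`. The ratio of
  the two, and the surplus percentage `(ratio − 1) × 100`, say whether a
  lineage fixes more carbon than its growth requires. Surplus ≤ 0 flags
  storage/external carbon use, not negative photosynthesis.
* **Regression-to-the-mean null model**: drawing monoculture and
  mixed-culture rates independently from one truncated normal
  (0.45–1.1 day⁻¹) and forming the ratio produces an L-shaped
  mono-growth/response relationship with no interaction at all — the null
  against which any empirical L-shape must be read.
* **Mixed-model inference**: lineage effects on absolute growth rates
  tested by likelihood ratio between ML `lme4` fits with biological
  replicate populations as random groups; model selection by AICc;
  reactiveness regressed on surplus NP per scenario.

Modules: `simulate_experiment()` / `simulate_events()` (generator),
`gate_config()` / `gate_events()` / `classify_gfp()` (cytometry gating),
`estimate_growth*()` (kinetics), `compute_response()` /
`pair_treatment_with_monoculture()` / `variance_components()` (social
responses), `o2_to_specific_carbon()` / `carbon_budget()` (carbon budgets),
`simulate_null()` / `binned_null_expectation()` / `fit_null_curve()` (null
model), `fit_growth_model()` / `lrt_fixed_effect()` / `aicc()` /
`fit_reactiveness_model()` (inference), `run_pipeline()` (everything under
one seed). A thin command-line front end with subcommands (`all`,
`nullmodel`, `gate`, `growth`, `respond`, `carbon`) lives at
`inst/cli/picosocial.R`.

## Worked example

```r
library(picosocial)

estimate_growth_two_point(100, 1e5, 7)
#> [1] 0.9868222
compute_response(1.2, 0.6)
#> [1] 2

res <- run_pipeline(seed = 1, n_lineages = 6, null_draws = 1000)

res$variance
#> # A tibble: 2 × 4
#>   env      within_lineage_var between_lineage_var n_lineages
#> 1 ambient             0.00631              0.0119          6
#> 2 elevated            0.00490              0.0534          6
#> fold (elevated/ambient): between 4.49, within 0.78

res$null
#> Regression-to-the-mean null: 1000 draws, Spearman rho = -0.705, mean response = 1.025

dplyr::filter(res$lineage_lrt, scenario == "monoculture")
#> # A tibble: 2 × 5
#>   scenario    env       chi2 delta_df             p
#> 1 monoculture ambient   21.8        5 0.000578
#> 2 monoculture elevated  48.3        5 0.00000000311

res$reactiveness[, c("scenario", "env", "slope", "best_model")]
#> # A tibble: 6 × 4
#>   scenario env         slope best_model
#> 1 direct   ambient  0.00100  with_predictor
#> 2 direct   elevated 0.00191  with_predictor
#> 3 spike    ambient  0.000430 with_predictor
#> 4 spike    elevated 0.000738 with_predictor
#> 5 thincert ambient  0.000684 with_predictor
#> 6 thincert elevated 0.00135  with_predictor
```

Reading the output: the first call is the growth rate of the standard
culture regime (100 → 10⁵ cells ml⁻¹ in 7 days, ≈ 0.99 day⁻¹). In the
pipeline run, lineages differ significantly in growth rate in both
environments (the likelihood-ratio χ² against the no-lineage model), the
elevated-pCO2 panel shows a several-fold larger between-lineage variance,
the null model's strongly negative Spearman ρ shows how much L-shape comes
for free from regression to the mean, and the reactiveness fits recover a
positive association between a lineage's surplus photosynthate and how much
it speeds up near conspecifics — AICc prefers the surplus model over the
intercept-only model in every scenario here.

The same run from the shell, with byte-identical outputs for a given seed:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli", "picosocial.R", package = "picosocial"))')" \
  all --seed 1 --out results/run1
```

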