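# spatmet

Spatial-metabolic profiling of the tumor microenvironment from multiplexed
immunofluorescence (mIF) tissue-microarray cohorts, with survival
modelling.

## What it does

Given per-cell marker tables (coordinates in µm plus per-marker positivity
probabilities or binary calls) and a patient-level clinical table, the
package runs the full analysis chain used in spatial proteomics studies of
immunotherapy response:

1. **Phenotyping** — cohort-level binary thresholds at the minimum of the
   per-marker probability density (searched in [0.02, 0.75], capped at
   0.5), exact rule-table typing into 14 mutually exclusive cell types
   with a 5-nearest-neighbour fallback in marker-probability space, and
   functional/metabolic state annotation.
2. **Neighbourhoods** — k-means on each cell's K-nearest-neighbour
   composition histogram: tumor/stroma (window 50, K = 2),
   tumor/interface/stroma (window 30, K = 3), and metabolic
   neighbourhoods from 7 pathway-proxy counts (window 30, K = 4:
   minimal / low / medium-regulatory / high activity), with an inertia
   elbow diagnostic.
3. **Spatial metrics** — G-cross nearest-neighbour distance CDF summarized
   by its exact AUC up to 150 µm,

   `AUC = (1/r_max) * mean_i max(0, r_max − d_i)`,

   Jensen-Shannon distance between 2D kernel-density intensities
   (base-2, square root of the divergence, bounded [0, 1]), alpha-shape
   (concave hull) edge cells for cross-region boundary features, and a
   100 µm permutation interaction z-score.
4. **Feature engineering** — compartment proportions (base / functional /
   metabolic phenotype levels), count ratios, and the spatial metrics per
   compartment, assembled into a patient × feature matrix with the
   pipeline's imputation rules (JSD nulls → 1, others → 0), a
   25-unique-value sparsity filter, and standard scaling.
5. **Stability selection with decoy injection** — repeated l1-penalized
   fits (logistic Lasso on clinical benefit, penalized Cox on PFS) on 50%
   subsamples of a matrix where every feature is paired with a permutation
   or Gaussian-knockoff decoy; the decoys calibrate a selection-frequency
   threshold via the estimated false-discovery proportion
   `(1 + #decoys ≥ t) / max(1, #reals ≥ t)`.
6. **Survival analysis** — Mann-Whitney/Benjamini-Hochberg screens,
   univariate Cox, median-split Kaplan-Meier log-rank tests, repeated
   75/25 penalized-Cox splits evaluated by IPCW time-dependent AUC to 24
   months, and logHR-weighted prognosis scores with resistance
   (logHR > 0) / response (logHR < 0) signatures.

A synthetic TMA generator (`synthetic_config()`, `generate_cohort()`)
produces cores with Gaussian tumor nests, spatially structured metabolic
marker gradients, and survival outcomes from an exponential-baseline Cox
model with planted effects — so the whole pipeline is testable without any
data download.

## Worked example

```r
library(spatmet)

cfg <- list(
  out_dir = "run", seed = 42,
  synthetic = list(n_patients = 60, cells_per_core = c(1200, 1800),
                   censor_rate = 0.25,
                   planted_effects = list(list(
                     feature = "gzmb_macrophage_fraction", beta = 1.2))),
  metrics = list(views = c("cn2", "cn3", "mbn"),
                 levels = c("base", "functional"),
                 top_types = 5, families = c("gcross", "jsd", "gxedge")),
  selection = list(endpoint = "cox", n_subsamples = 50))

res <- run_pipeline(cfg)
#> [simulate] done in 8.5s
#> [phenotype] done in 5.6s
#> [neighborhoods] done in 19.3s
#> [metrics] done in 33.3s
#> [features] done in 0.2s
#> [select] done in 4.5s
#> [survive] done in 0.3s

res$features
#> Feature matrix: 60 patients x 1497 features (447 dropped by unique-value filter)

grep("GranzymeB", res$selection$selected, value = TRUE)
#> [1] "prop|cn3|stroma|functional|macrophage:GranzymeB+"
#> [2] "prop|cn3|tumor|functional|macrophage:GranzymeB+"
#> [3] "prop|mbn|medium_regulatory|functional|macrophage:GranzymeB+"
#> [4] "prop|mbn|minimal|functional|macrophage:GranzymeB+"

res$survival$cv
#> Penalized Cox, 10 random splits
#>   mean time-dependent AUC over months 1-24: 0.812
```

The cohort above plants a hazard effect on the granzyme-B⁺ macrophage
fraction (log-hazard 1.2 per SD). The selection stage recovers exactly the
engineered features that express that quantity — granzyme-B⁺ macrophage
proportions across tissue compartments — and the cross-validated
time-dependent AUC (~0.8) quantifies how well the selected spatial
features predict progression-free survival on held-out patients.

A thin CLI wraps the same pipeline
(`inst/scripts/spatmet run-all --config cfg.yaml --seed 42 --out run`),
with stage subcommands resuming from cached artifacts.

## Vignette

`vignettes/spatmet-methods.Rmd` documents the models, the parameter
choices and their defaults, what the synthetic generator does and does not
emulate, and the package's known limitations.
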