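# eosmap

Label-free scoring of eosinophil activation state from dark-field
(side-scatter) images, for imaging flow cytometry data.

Eosinophil activation reorganises and progressively empties the cell's
cytoplasmic granules. Counting eosinophils — the routine clinical
read-out — misses this: two samples with identical counts can differ
sharply in activation. Because the granules dominate the cell's optical
scattering, activation changes the *spatial structure* of each cell's
dark-field image much more than its total brightness (which rises only
~10%). `eosmap` turns that structure into a per-cell score:

1. **gate** eosinophils on integrated autofluorescence × side-scatter
   (granule-rich cells sit in the upper-right quadrant);
2. **extract** an 85-feature spatial profile of each gated dark-field
   image — intensity statistics, radial intensity distribution, a
   morphological granularity spectrum, and Haralick texture
   (gray-level co-occurrence) statistics;
3. **embed** the pooled, standardized feature matrix with a diffusion
   map: `K_ij = exp(−‖x_i−x_j‖²/2σ²)`, density-normalised (α = 1),
   row-normalised to a Markov matrix whose leading non-trivial
   eigenvectors `λ_k ψ_k` coordinate the low-dimensional map;
4. **score** each cell by its signed arc-length position along the
   fitted diffusion path, measured from the path's zero point (the
   vertex at DC1 = 0) — the *activation index*;
5. **compare** populations: Kolmogorov–Smirnov tests, Gaussian histogram
   fits, control-normalized means ± s.e.m., Pearson correlations, and
   the Fisher discriminant ratio
   `r_d = (μ₁ − μ₂)² / (σ₁² + σ₂²)`
   of the index versus plain integrated side-scatter.

Because no per-cell image data ship with the package, a seeded
synthetic-image generator (`simulate_cell()`, `simulate_cohort()`)
produces benchmark cohorts in which a latent activation level drives
granule dispersion, fragmentation and a calibrated ~10% integrated
intensity gain — so the whole pipeline is testable end to end against
known ground truth.

## Worked example

```r
library(eosmap)

# one synthetic cell, moderately activated
p    <- cell_sim_params()
cell <- simulate_cell(p, activation = 0.6, seed = 42)
f    <- extract_features(cell)
round(f[c("Int_Integrated", "Rad_FracAtD_b1", "Gran_02", "Tex_Contrast_d1")], 3)
#>  Int_Integrated  Rad_FracAtD_b1         Gran_02 Tex_Contrast_d1
#>         432.853           0.384           5.737           0.433

# full pipeline on the default five-sample cohort (two arms: eotaxin
# exposure at activation 0/0.3/0.6, elevated-count donors at 0.2/0.5)
res <- run_pipeline(run_config("run", seed = 1L))
res$stats
#> Population statistics
#>   Fisher ratio (activation index, control vs eotaxin_5h): 7.303
#>   Fisher ratio (integrated side-scatter):     0.122
#>   ...
#>   KS vs control (activation index):
#>     eotaxin_2h     D = 0.695, p = 0
#>     eotaxin_5h     D = 0.958, p = 0
#>     donor_3.1pct   D = 0.544, p = 0
#>     donor_9.0pct   D = 0.912, p = 0

round(tapply(res$scores$activation_index, res$scores$sample, mean), 3)
#>      control donor_3.1pct donor_9.0pct   eotaxin_2h   eotaxin_5h
#>       -0.317       -0.121        0.206       -0.034        0.299
```

The group means of the activation index increase strictly with the
generator's activation level within each arm, every treated sample
differs from control at vanishing KS p, and the multivariate index
separates control from the 5-h exposure far better (`r_d = 7.3`) than
integrated side-scatter does (`r_d = 0.12`) — the point of the method:
the activation signal lives in granule *redistribution*, which
whole-cell intensity barely sees. `run_pipeline()` also writes every
stage's CSV (`events.csv`, `features.csv`, `embedding.csv`, `path.csv`,
`scores.csv`, `stats_report.csv`) plus `run_metadata.yaml` into the
output directory.

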