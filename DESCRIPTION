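Package: eosmap
Title: Label-Free Eosinophil Activation Scoring from Dark-Field Images
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Quantifies the activation state of granular leukocytes
    (eosinophils) from label-free imaging flow cytometry data. Per-cell
    dark-field (side-scatter) images are segmented and summarised by an
    85-feature spatial profile (intensity statistics, radial intensity
    distribution, morphological granularity spectrum, Haralick texture),
    the pooled feature matrix is embedded with a density-normalised
    diffusion map, and each cell is scored by its signed arc-length
    position along the fitted diffusion path (the "activation index").
    Population-level comparisons (Fisher discriminant ratio, two-sample
    Kolmogorov-Smirnov tests, Pearson correlation, Gaussian histogram
    fits) contrast the multivariate index with integrated side-scatter
    intensity. A seeded synthetic-image generator emulating granule
    redistribution during activation provides reproducible benchmark
    cohorts.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    minpack.lm,
    stats,
    tiff,
    tools,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
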