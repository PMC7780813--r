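Package: cardiomap
Title: Optical Mapping Analysis of Cardiomyocyte Monolayers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for dual-dye (voltage and calcium) optical
    mapping recordings of cardiomyocyte monolayers. Conditions raw
    fluorescence movies or traces (baseline drift removal, polarity,
    normalization, smoothing), segments beats under fixed-rate, ramp, or
    spontaneous pacing, and quantifies per-beat action-potential and
    calcium-transient metrics (APD and CaTD at several repolarization
    levels, time to peak, exponential decay time constant, maximal
    upstroke derivative). Builds electrical restitution curves (APD80
    versus diastolic interval) with a monoexponential fit and maximum
    slope estimate, and implements sequential-dose drug-response
    statistics: percent change from predrug baseline, Welch two-group
    comparisons, and one-way ANOVA with Dunnett many-to-one contrasts
    using equicorrelated multivariate-t critical values. A synthetic-data
    generator emulates atrial-like and ventricular-like recordings with
    per-beat ground-truth manifests so every stage is testable without
    instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    graphics,
    signal,
    minpack.lm,
    mvtnorm,
    zoo,
    tiff,
    yaml
Suggests:
    testthat (>= 3.0.0),
    multcomp,
    jsonlite
Config/testthat/edition: 3
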