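Package: sersclass
Title: PLS-DA Classification of Serum SERS Spectra with Patient-Wise
    Bootstrap Resampling
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for binary classification of surface-enhanced Raman
    scattering (SERS) spectra of blood serum.  Implements the full
    chemometric chain: a synthetic cohort generator with Lorentzian peak
    models, patient-level random effects and fluorescence-like baselines;
    spectral preprocessing (Savitzky-Golay smoothing, iterative
    modified-polynomial background removal, standard normal variate
    normalisation); partial least squares discriminant analysis (PLS-DA)
    via NIPALS with variable importance in projection (VIP) scores and
    patient-grouped cross-validation for latent-variable selection; and a
    bootstrap class-balancing resampling protocol with patient-wise
    train/test splits, confusion-matrix metrics and ROC/AUC, aggregated
    over repeated folds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
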