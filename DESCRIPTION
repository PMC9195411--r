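Package: methylnet
Title: Hybrid Variational-Autoencoder Classification of DNA Methylation Profiles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for pan-cancer tissue-of-origin classification from
    Illumina 450K-style methylation beta values. Implements CpG-island probe
    clustering and leakage-safe per-sample feature construction, a hybrid
    variational-autoencoder/classifier neural network trained with a joint
    weighted loss (Adam, early stopping on validation accuracy), per-class
    and support-weighted F-measure evaluation, latent-space embedding with
    2-D projection and cross-validated linear-SVM separability analysis, and
    a synthetic-data generator that emulates class-specific methylation
    signatures, patient-matched samples, metastasis-like dispersion and
    age-related hypomethylation drift.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    jsonlite,
    withr
Suggests:
    testthat (>= 3.0.0),
    cluster,
    optparse,
    yaml
Config/testthat/edition: 3
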