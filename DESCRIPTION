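Package: neopredict
Title: Multimodal Prediction of Neurodevelopmental Outcomes in Very Preterm Infants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end multimodal prediction of Bayley-III neurodevelopmental
    outcomes in very preterm infants from term-equivalent-age MRI and clinical
    data. Quantifies diffuse white matter abnormality (DWMA) from segmented
    T2-weighted volumes by a threshold sweep, builds functional (Pearson
    correlation) and structural (mean fractional anisotropy) brain connectomes,
    harmonizes features across acquisition sites with ComBat, balances and
    augments training data by bin-wise convex combination of nearest
    neighbours, and trains a four-channel fusion network (fixed convolutional
    extractors for the connectome channels, stacked sparse autoencoder
    pretraining, supervised fine-tuning) for risk classification and score
    regression. Includes gradient-based interpretability (partial-derivative
    feature ranking and Grad-CAM on adjacency matrices), a nested
    cross-validation harness with the full metric suite, and a synthetic
    cohort generator with planted ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    RNifti
Suggests:
    testthat (>= 3.0.0),
    pROC,
    sva,
    withr,
    optparse
Config/testthat/edition: 3
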