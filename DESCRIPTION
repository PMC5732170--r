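Package: nodulect
Title: Quantitative CT Texture Analysis of Lung Adenocarcinoma Nodules
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Exemplar-based texture classification of lung adenocarcinoma
    nodules on computed tomography, together with parenchymal scoring of the
    tumor-free peritumoral lung and the cohort-level statistics used to
    relate both to EGFR and KRAS mutation status. Provides seeded
    region-growing nodule segmentation, affinity-propagation learning of
    nine color-coded texture exemplars, per-voxel nearest-exemplar labeling
    summarized as glyphs and composite features, rule-based classification
    of a 10 mm peritumoral shell into normal, low-attenuation, ground-glass,
    reticular and honeycomb parenchyma, and a statistics layer (exact and
    asymptotic contingency tests, stepwise logistic regression, ROC cutoffs
    at a target sensitivity, Kaplan-Meier and Cox survival). A synthetic CT
    phantom and feature-cohort generator makes every stage testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    cluster,
    graphics,
    jsonlite,
    stats,
    survival,
    utils
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
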