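Package: cryomil
Title: Transformer Multiple-Instance Learning for Cryosection Molecular Diagnosis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Slide-level prediction of glioma molecular status (ATRX, H3K27M,
    TP53, pilocytic astrocytoma) from bags of cryosection patch features using
    a single-block self-attention Transformer classifier with attention-based
    patch explanation. Includes whole-slide tissue segmentation, grid patching
    and patch quality filtering; a synthetic-cohort generator emulating
    multi-centre biopsy series with Pass/No-Pass verdicts; evaluation
    statistics (ROC/AUC, balanced and F1 operating thresholds, DeLong
    confidence intervals, permutation significance, patient-level stratified
    cross-validation, probability-level ensemble voting); and a retrospective
    biopsy re-checking simulation quantifying the re-biopsies an
    any-mutant-detection policy would save.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    EBImage,
    pROC,
    jsonlite,
    png,
    grDevices,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
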