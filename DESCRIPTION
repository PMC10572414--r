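Package: autoaugseg
Title: Automatic Data-Augmentation Policy Search for Binary Medical Image
    Segmentation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Searches a discretized space of paired image transformations for
    an augmentation policy that maximizes the validation performance of a
    segmentation network, using a recurrent (LSTM) policy controller trained
    by proximal policy optimization. Ships the U-Net family of encoder-decoder
    segmentation models (U-Net, U-Net++, Attention U-Net, Residual U-Net) on a
    compact reverse-mode autodiff engine, a hybrid Dice/cross-entropy training
    loss, a six-metric evaluation suite with patient-level k-fold
    cross-validation, and a synthetic OCT phantom generator that emulates a
    retinal B-scan cohort (layered bands, hypo-reflective cavities with
    cross-scan coherence, speckle noise, vessel shadows) so the full pipeline
    is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    png,
    stats,
    tools,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    tiff
Config/testthat/edition: 3
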