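Package: vfecm
Title: Quantitative Microanatomy of the Vocal-Fold Extracellular Matrix
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Windowed image analysis of the vocal-fold lamina propria from
    label-free optical imaging. Implements structure-tensor estimation of
    collagen fiber orientation and anisotropy on second-harmonic-generation
    (SHG) images, gray-level co-occurrence matrix (Haralick) texture features
    (contrast, entropy, inverse difference moment), single-scattering
    Beer-Lambert attenuation-coefficient fitting and changepoint layer
    segmentation on optical coherence tomography (OCT) B-scans, fibrillar
    morphometrics (fenestration fraction, fiber diameter, waviness, layer
    thickness), and region-level ANOVA/Tukey statistics. Ships seeded
    synthetic fiber and speckled B-scan phantom generators with attached
    ground truth for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tiff,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite
Config/testthat/edition: 3
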