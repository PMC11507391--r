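Package: oleospec
Title: Hyperspectral Chemometrics for Edible-Oil Acid Value Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A chemometrics pipeline for predicting the acid value (mg KOH/g)
    of edible oils from near-infrared hyperspectral images. Covers ENVI cube
    input/output and reflectance calibration, region-of-interest segmentation
    and mean-spectrum extraction, the standard spectral pretreatments
    (Savitzky-Golay smoothing and derivatives, SNV, min-max normalization,
    linear baseline correction), Kennard-Stone calibration/prediction
    partitioning with principal-component outlier screening, characteristic
    wavelength selection by the successive projections algorithm (SPA) and
    competitive adaptive reweighted sampling (CARS), gray-level co-occurrence
    matrix (GLCM) texture features at selected wavelengths, and PCR/PLSR
    calibration models evaluated by Rc2/RMSEC and Rp2/RMSEP. A synthetic-scene
    generator emulates an oil-sample cohort so the full three-tier modelling
    study (full wavelengths, selected wavelengths, fused spectral + texture
    features) can be run and validated end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    EBImage,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    optparse
Config/testthat/edition: 3
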