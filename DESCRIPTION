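Package: elfdose
Title: Stroke Lesion Volumetry and Magnetostatic Dosimetry for Pulsed
    ELF Magnetic Field Stimulation
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the computational chain of a pulsed extremely low
    frequency magnetic field (ELF-MF) stroke stimulation study: synthetic
    MRI phantom pairs with known ground truth, seeded section-by-section
    region-growing lesion segmentation with a relative-intensity inclusion
    band, voxel volumetry and FLAIR-DWI mismatch/rate endpoints, clinical
    score tracking, finite-segment Biot-Savart modelling of a single-turn
    rectangular stimulation coil (flat or cylinder-warped to the head),
    and per-lesion magnetic dose summaries against a biological threshold.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    oro.nifti,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
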