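Package: petmatch
Title: Spatial Concordance of SUVmax and ADCmin in PET/MRI Lesion Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for analysing the spatial relationship between the
    hottest FDG-PET voxel (SUVmax) and the most diffusion-restricted MRI
    voxel (ADCmin) of a lesion imaged with sequential or simultaneous
    PET/MRI. Provides axis-aligned 3D image volumes with NIfTI input and
    output, adaptive-threshold PET VOI segmentation, ADC region-of-interest
    transfer with histogram-based outlier refinement, rigid translation
    estimation and registration-accuracy thresholding, inter-extremum
    distance measurement with match/mismatch classification, fixed-volume
    sphere neighbourhood statistics, stratified correlation and
    Bland-Altman interobserver analysis, and a synthetic phantom-cohort
    generator with known ground truth for validating the pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
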