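Package: lesionquant
Title: Dual-Modality Quantitative Imaging of Breast Lesions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantitative analysis of co-registered PET and diffusion-weighted
    MR studies of breast-cancer lesions. Computes apparent diffusion
    coefficient (ADC) maps from two-point DWI acquisitions, segments the
    high-cellularity ADC functional volume (V_ADC) by a semi-automated
    k-means compartment-exclusion procedure seeded from the DCE enhanced-tissue
    mask, quantifies PET uptake (SUV, metabolic tumor volume, partial-volume
    corrected SUV_mean, total lesion glycolysis), defines the total lesion
    diffusion (TLD) index as the MR analogue of TLG, extracts a fixed
    22-feature vector (macroscopic, first-order histogram, shape/size) per
    modality, and screens features against histopathological labels and
    therapy response with uncorrected univariate tests. Includes a synthetic
    multimodal phantom generator with ground-truth compartment masks so the
    whole pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
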