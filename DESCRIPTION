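Package: fltseg
Title: Reference-Tissue Relative Thresholds for FLT PET/CT Lesion Segmentation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Implements a reference-tissue-normalized thresholding pipeline for
    segmenting proliferative lesions in [18F]fluorothymidine (FLT) PET/CT of
    diffuse large B-cell lymphoma. Quantifies liver and bone-marrow uptake in
    volumes of interest (PERCIST-style liver spheres, Hounsfield-unit-delineated
    vertebrae), derives cohort normal uptake ranges and per-stage minimum
    relative thresholds from manually reported lesions, reformulates the
    standard-deviation-based criteria into single relative multipliers, and
    applies the resulting per-patient absolute SUV thresholds to label lesions,
    count detections and compute metabolic tumour volume. Ships a synthetic
    PET/CT phantom cohort generator so the whole analysis is reproducible
    without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
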