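Package: lcnm
Title: Locus Coeruleus Neuromelanin MRI Quantification and Permutation
    Inference
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for quantifying sub-regional (rostral, middle, caudal)
    locus coeruleus neuromelanin contrast from neuromelanin-sensitive MRI
    volumes, computing FDG-PET standardized uptake value ratio (SUVR)
    images, and running the accompanying inference chain: permutation-based
    ANCOVA-type group comparisons with Freedman-Lane residual permutation,
    family-wise-error-corrected one-tailed post hoc contrasts, Spearman
    rank correlations with cognition, and voxel-wise association mapping
    with cluster-extent family-wise error correction.  A seeded synthetic
    phantom generator produces cohorts with known ground truth so that the
    whole pipeline can be validated end to end without participant data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse,
    car
Config/testthat/edition: 3
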