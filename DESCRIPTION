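Package: mtlnet
Title: Seed-Based Medial Temporal Lobe Network Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Derives anterior-temporal (AT) and posterior-medial (PM)
    network masks from perirhinal and parahippocampal seed connectivity
    using sign-flip permutation tests with threshold-free cluster
    enhancement (TFCE) and max-statistic family-wise error correction,
    extracts per-participant positive-voxel connectivity indexes, and
    relates them to age, Alzheimer's stage, biomarkers and time to
    dementia onset with linear mixed models, ranked-group smooths and
    ANCOVA.  Includes a synthetic-data generator with known ground truth
    (planted networks and planted linear effects) for end-to-end
    validation of the pipeline, plus fMRI preprocessing primitives
    (bandpass filtering, nuisance regression, framewise displacement,
    motion quality control).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    lme4,
    lmerTest,
    mgcv,
    emmeans,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
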