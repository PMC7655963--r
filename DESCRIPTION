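Package: icchub
Title: Voxel-Wise Intrinsic Connectivity Contrast Mapping for Resting-State fMRI
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Computes voxel-wise intrinsic connectivity contrast (ICC) maps --
    whole-brain, short-range, and long-range -- from denoised resting-state
    BOLD series within a gray-matter mask, using a memory-bounded chunked
    correlation engine. Implements the surrounding analysis pipeline:
    nuisance-confound construction (24 motion terms, tissue and global
    signals), confound regression, zero-phase band-pass filtering,
    frame-wise-displacement screening, permutation-based voxel- and
    cluster-level family-wise-error inference for one-sample and regression
    designs, and seed-based connectivity mapping with resting-state-network
    template overlap ratios. Ships a synthetic multi-subject BOLD cohort
    generator with planted latent networks, connector-hub voxels, and a
    covariate-modulated coupling effect so the full pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    Rcpp,
    signal,
    igraph,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
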