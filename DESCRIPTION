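Package: nhfmri
Title: Network Homogeneity Analysis of Longitudinal Resting-State fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for network-homogeneity (NH) analysis of resting-state
    fMRI in longitudinal two-arm treatment studies: temporal preprocessing
    (volume dropping, motion quality control, detrending, band-pass
    filtering, nuisance regression, framewise-displacement scrubbing),
    group independent component analysis to derive a network mask,
    per-voxel network homogeneity, voxel-wise group and time inference
    with Gaussian-random-field cluster correction and a permutation
    oracle, and leave-one-out support-vector classification and
    regression of cluster-mean NH features against clinical reduction
    ratios.  A seeded synthetic BOLD cohort generator with planted
    network structure, group effects, treatment response, head motion,
    and coupled clinical scores makes every stage testable end to end
    without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    RNifti,
    e1071,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    kernlab,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
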