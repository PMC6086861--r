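Package: rsfcnet
Title: Resting-State Functional Connectome Construction and Group-by-Time
    Network Inference
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds region-of-interest functional connectivity matrices from
    resting-state fMRI time series (band-pass filtering, polynomial
    detrending, framewise-displacement and DVARS motion scrubbing, Pearson
    correlation with Fisher r-to-z transform), summarizes connectivity within
    and between intrinsic connectivity networks, derives density-thresholded
    weighted graph topology (strength, Onnela clustering, harmonic closeness,
    global efficiency, characteristic path length, and small-worldness
    against degree-preserving rewired null models) integrated across a
    proportional density grid, and tests group-by-time interaction effects in
    two-group longitudinal designs with covariate-adjusted Freedman-Lane
    permutation inference and covariate-residualized brain-behavior
    correlation. Includes a synthetic-cohort generator with controllable
    block-covariance structure, planted interaction effects, motion spikes,
    and behavior coupling, so the full pipeline is testable end to end
    without imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    jsonlite,
    yaml,
    stats,
    tools,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
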