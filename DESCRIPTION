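Package: nodalcausal
Title: Causal Inference for Zebrafish Nodal Gene Regulation from
    Per-Embryo Fluorescence Intensities
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable pipeline identifying which upstream factors
    (maternal Eomesa, Hwa/beta-catenin dorsal signaling, Nodal/Smad2
    autoregulation, developmental time) cause the expression of the
    zebrafish nodal genes ndr1 and ndr2 from per-embryo fluorescence
    intensity measurements. Implements multiple linear regression with
    coefficient t-tests, variable screening, backdoor-criterion causal
    effect estimation with a linear estimator, three refutation tests
    (random common cause, placebo treatment, data subset), per-timepoint
    coefficient trajectories and relative contribution profiles,
    ChIP-qPCR percent-input quantification, and fluorescence-image
    region-of-interest intensity measurement with blank-minimum
    background subtraction. Includes a linear structural causal model
    generator producing synthetic embryo datasets, images and Ct tables
    with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    tiff,
    tools,
    utils,
    yaml
Suggests:
    mgcv,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
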