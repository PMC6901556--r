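Package: lnmapr
Title: Lesion Network Mapping with Normative Functional Connectomes
Version: 0.1.0
Authors@R:
    person("lnmapr", "maintainers", email = "maintainers@example.org",
           role = c("aut", "cre"))
Description: Seed binary lesion (ablation) masks in a normative cohort of
    resting-state fMRI time series to obtain per-lesion connectivity maps,
    convert them to whole-brain t-maps, threshold and binarize them, sum the
    binarized maps per outcome group, contrast the groups with voxelwise
    odds-ratio (VOR) maps, and summarize VORs over anatomical and
    resting-state-network parcellations. Includes a minimal NIfTI-1
    reader/writer, Dice overlap statistics with a label-permutation group
    test, a synthetic-connectome generator with planted ground truth so the
    whole pipeline is testable at desk scale, and a config-driven
    command-line pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
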