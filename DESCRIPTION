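Package: edmapr
Title: Absolute-Scale Interpretation of Crystallographic Electron Density Maps
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Interprets x-ray crystallographic electron density maps in
    absolute electron units. Reads CCP4-format 2Fo-Fc and Fo-Fc maps and
    PDB-format models, derives a per-structure conversion factor from
    sigma-scaled density units to electrons via the median chain density
    ratio, corrects per-atom density statistics for voxel discretization
    and B-factor dispersion, quantifies difference-map discrepancies as
    connected blobs measured in electrons, estimates the F000 offset, and
    optimizes per-atom-type radii so the metric is consistent within and
    across structures. Includes a synthetic fixture generator (Gaussian-atom
    forward model) so the full pipeline is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    data.table,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    bio3d,
    withr,
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
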