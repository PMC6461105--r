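Package: smeq
Title: Two-State Conformational Equilibrium Analysis of Single-Molecule
    Fluorescence Traces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Analysis of single-molecule fluorescence intensity traces from
    a two-state conformational reporter, as used to monitor the activation
    loop of Aurora-A kinase. Simulates telegraph-process traces with
    log-normal emission noise and frame integration, fits pooled intensity
    histograms to a sum of two log-normal components to extract
    conformational populations, extracts dwell times and fits exponential
    kinetics, converts populations into equilibrium constants and free
    energies with error propagation, performs thermodynamic-cycle
    bookkeeping for ligand and phosphorylation effects, and implements the
    conformational-selection binding model: ligand discrimination, required
    discrimination for target populations, and the overall dissociation
    constant surface with contour, equidistant-line and plateau analysis.
    Includes Forster-efficiency calculations for reporter design.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    grDevices,
    jsonlite,
    minpack.lm,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
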