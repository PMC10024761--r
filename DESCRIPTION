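Package: hippophys
Title: Hippocampal Electrophysiology and Morphometry Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for hippocampal electrophysiology and
    morphometry: brain-state segmentation from the theta/delta power ratio of
    laminar local field potentials and layer-resolved theta/gamma band power
    over mobility periods; detection and classification of epileptiform
    discharges (bursts vs seizure-like events) on multi-electrode-array grids
    with seizure initiation and propagation mapping; threshold-based detection
    of spontaneous post-synaptic currents and intrinsic membrane properties;
    Sholl profiles, dendritic tree metrics and cell-density normalisations;
    plus the associated non-parametric and contingency statistics. Includes
    seeded synthetic-data generators that emulate each recording modality with
    ground-truth labels, so every stage of the pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    signal,
    mclust,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
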