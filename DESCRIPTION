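Package: arborsim
Title: Context-Aware Simulation of Neuronal Morphologies in a Shared Substrate
Version: 0.1.0
Authors@R:
    person("Arborsim", "Developers", email = "arborsim@example.org",
           role = c("aut", "cre"))
Description: Grows populations of virtual neuronal morphologies
    simultaneously inside a shared, spatially decomposed brain substrate.
    Phenomenological growth cones ("fronts") extend, branch, and terminate
    under local attraction and repulsion cues; structural overlaps between
    neurites are detected with a capsule test and resolved on the fly by
    perturbation or termination, and putative synapses are recorded as a
    by-product of collision testing. Ships exemplar growth-rule sets for
    spinal motor neurons, dentate granule cells, and layer 5 cortical
    pyramidal neurons in a laminar substrate, plus morphometric validation
    tools (branch points, tip distances, centrifugal order, Sholl-like
    profiles, total length) summarized by median, median absolute
    deviation, and interquartile range. Morphologies are read and written
    in the SWC format.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
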