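Package: BicelleNMR
Title: Binding, Topology and Dynamics Analysis of Membrane-Protein NMR
    Titrations in Bicelles
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Quantitative analysis of solution-NMR and fluorescence
    studies of membrane-protein domains reconstituted in bicelles.
    Implements global 1:1 ligand-depletion binding fits of NMR-monitored
    titrations in both the slow-exchange (peak-intensity decay) and
    fast-exchange (hybrid chemical-shift perturbation) regimes,
    steady-state fluorescence anisotropy binding fits, paramagnetic-probe
    accessibility profiling with transmembrane-boundary calling,
    chemical-shift-index secondary-structure analysis, CLEANEX hydrogen
    exchange ratios, and per-residue CPMG R2 relaxation fits. A seeded
    synthetic-data generator produces every input class with known
    ground truth so the full pipeline is testable without spectrometer
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    minpack.lm,
    jsonlite,
    S4Vectors,
    IRanges,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
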