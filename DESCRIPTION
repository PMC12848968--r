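Package: redoxgnn
Title: Multi-Solvent Reduction-Potential Prediction with Message-Passing
    Graph Neural Networks and Evolutionary Inverse Design
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Predicts one-electron reduction potentials of organic
    redox-active molecules across solvents. Molecules enter as SMILES and
    are featurized into molecular graphs; a residual message-passing
    neural network with an attention-based (Set Transformer) readout
    predicts either a fixed vector of per-solvent potentials or a single
    potential conditioned on two solvent descriptors (dielectric constant
    and refractive index), the latter splitting the prediction into a
    solvent-independent electron-affinity term and a solvent-dependent
    term. Includes the reduction thermodynamic-cycle arithmetic,
    data-set curation filters (bond-length change, spin contamination,
    imaginary frequencies, bulk-electrostatics range), molecule-level
    train/validation/test splitting with a leave-one-solvent-out
    protocol, a synthetic data generator with a known ground truth, and
    an evolutionary inverse-design loop driven by a windowed sigmoid
    objective over a model ensemble.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ChemmineOB,
    ChemmineR,
    bio3d,
    igraph,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
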