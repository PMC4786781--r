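Package: pifeflow
Title: Single-Molecule PIFE Analysis of Protein Binding on Flow-Stretched DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and analysis of single-molecule protein-induced
    fluorescence enhancement (PIFE) experiments on flow-stretched,
    sparsely dye-labelled DNA. Generates synthetic image stacks, intensity
    and length trajectories and quantum-dot tracks with known ground
    truth; extracts integrated-intensity trajectories, kymographs,
    DNA lengths and sub-pixel quantum-dot positions from image stacks;
    fits Langmuir association/dissociation kinetics, Hill isotherms,
    compaction lag/rate changepoint models and a sequential two-site
    equilibrium binding model; and estimates tension profiles along
    flow-stretched DNA via a worm-like-chain model.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    tiff,
    yaml,
    jsonlite,
    withr
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
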