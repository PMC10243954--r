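Package: netpharm
Title: Network Pharmacology Screening, Diffusion and Proximity Analysis
Version: 0.9.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: A reusable pipeline for network-pharmacology studies of
    multi-compound herbal formulas: rule-based ADMET screening of candidate
    compounds (oral bioavailability, Lipinski's rule of five, Caco-2
    permeability, drug-likeness, half-life), assembly of drug and disease
    target sets, protein-protein interaction network topology with a
    two-times-median key-target screen, MCODE molecular complex detection,
    random walk with restart diffusion for gene prioritisation, the
    closest-distance network proximity index with a random-group null,
    hypergeometric over-representation analysis with Benjamini-Hochberg
    correction, correlation-based gene clustering, and post-processing of
    molecular docking records including the binding-energy to
    inhibition-constant conversion. A synthetic-data generator with planted
    network structure provides ground-truthed inputs for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'io.R'
    'synthetic.R'
    'screen.R'
    'targets.R'
    'network.R'
    'mcode.R'
    'diffusion.R'
    'proximity.R'
    'enrichment.R'
    'docking.R'
    'pipeline.R'
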