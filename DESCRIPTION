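Package: signalsim
Title: Nonparametric Simulation of Signal Transduction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Topology-only simulation of signal transduction networks.
    Signed directed graphs of activating and inhibiting molecular
    interactions are weighted by the Normalized Similarity Index (NSI),
    a shared-neighbourhood measure of signal-transmission efficiency,
    and node activity levels (proportion of molecules in active form,
    in [0,1]) are propagated from ligand source nodes by a
    semi-synchronized stochastic update over breadth-first-search
    layers. Includes in silico perturbation (complementary inhibitor
    nodes, gain-of-function clamps), validation statistics (Pearson
    agreement with experimental activity tables, paired Wilcoxon
    signed-rank trend calls), synthetic network generators for
    testing, and a command-line front end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllGenerics.R'
    'AllClasses.R'
    'graph-io.R'
    'nsi-weighting.R'
    'dynamics.R'
    'perturbation.R'
    'stats-validation.R'
    'fixtures.R'
    'cli.R'
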