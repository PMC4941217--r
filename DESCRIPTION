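Package: carbonylNCI
Title: Inventory of Noncovalent Interactions Made by Protein Backbone Carbonyl Oxygens
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Geometric classification of the noncovalent interactions (NCIs)
    accepted or donated by protein backbone-carbonyl oxygen atoms: hydrogen
    bonds from backbone and side-chain NH, side-chain OH, alpha-carbon and
    side-chain CH donors and water, plus n->pi* carbonyl-carbonyl
    interactions. Provides secondary-structure-resolved inventories over
    static structures and snapshot ensembles, modal-occupancy statistics,
    mining of under- and over-satisfied carbonyl motifs (including bifurcated
    hydrogen bonds and helix-capping clusters), and a generator of
    ideal-geometry peptide structures and perturbed pseudo-ensembles for
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
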