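Package: depull
Title: Differential-Evolution Guided Multidirectional Steered Pulling for
    Ligand Egress
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Finds multidirectional ("zigzag") ligand egress pathways from a
    receptor binding site by alternating differential-evolution searches over
    rigid ligand translations, scored by the change in ligand-receptor
    Coulomb and Lennard-Jones interaction energy, with short steered-pulling
    intervals in which a harmonic spring attached to a moving dummy atom
    drags the ligand along the chosen direction. Ships a desk-scale
    overdamped Langevin pulling engine, a generator of synthetic
    receptor-ligand systems with known ground-truth channels, and analysis
    of the resulting force profiles: pulling work, rupture force, Pearson
    correlation with ln(IC50), pathway classification and bootstrap pathway
    populations.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    bio3d,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    yaml
Config/testthat/edition: 3
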