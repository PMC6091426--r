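Package: pocketrank
Title: Ligand Binding Site Prediction from Protein Structure via
    Surface Point Ligandability
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts ligand binding sites (pockets) on protein
    structures by classifying points sampled on the solvent accessible
    surface. Each surface point is described by a feature vector built
    from distance-weighted physico-chemical properties of nearby atoms
    and direct geometric descriptors (protrusion first among them),
    scored for ligandability by a trainable Random Forest, and
    high-scoring points are clustered into ranked pockets. Includes a
    ligand-centric evaluation protocol based on the
    distance-from-center-to-closest-ligand-atom (DCC) criterion with
    Top-n / Top-(n+2) rank cutoffs, a synthetic structure generator so
    that training, prediction and evaluation are fully testable
    offline, and command-line entry points for single-command
    prediction, training and evaluation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    parallel,
    ranger,
    stats,
    tools,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
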