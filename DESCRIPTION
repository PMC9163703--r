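Package: cleavedock
Title: Docking-Based Prediction of Serine-Protease Cleavage Sites
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts trypsin-like protease cleavage sites in a substrate from
    docked peptide pose ensembles. Enumerates candidate P1 arginine/lysine
    positions under Schechter-Berger specificity rules, evaluates each docked
    binding mode against two geometric selection criteria (a P1/S1-pocket
    salt-bridge distance and a scissile-carbonyl to catalytic-serine distance),
    contrasts selected versus discarded modes by pairwise RMSD, scores sites by
    S1-pocket occupancy, and maps predicted cleavage events to proteolytic
    fragments. Ships a synthetic pose-ensemble generator with ground-truth
    labels so the whole pipeline is testable without a docking engine, plus an
    adapter that prepares and ingests AutoDock-Vina-style docking campaigns.
    Developed for the TMPRSS2 / gamma-ENaC (epithelial sodium channel) system
    but parameterised for any trypsin-like protease with an acidic S1 pocket.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
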