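Package: npcquant
Title: Quantification Pipeline for NPC1 Pharmacological-Chaperone Screens
Version: 1.0.0
Authors@R: person("npcquant", "maintainers", email = "npcquant@example.org",
    role = c("aut", "cre"))
Description: Reusable quantification chain for cell-based screens of
    pharmacological chaperones targeting the lysosomal cholesterol
    transporter NPC1.  Covers docking-score triage with per-heavy-atom
    ligand (binding) efficiency and reference-anchored hit calling,
    AutoDock Vina result parsing, the filipin 'LSO compartment ratio'
    image statistic, Pearson pixel-intensity colocalization, Western-blot
    densitometry with beta-actin normalization and Endo H glycoform
    fractions, and normality-gated group statistics (ANOVA/Dunnett,
    Kruskal-Wallis/Dunn, t-test) with significance-star annotation.
    A seeded synthetic-data module generates filipin-like fields,
    correlated channel pairs, densitometry tables and score tables so the
    whole pipeline runs and is testable without any external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    statmod
Suggests:
    testthat (>= 3.0.0),
    mvtnorm,
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
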