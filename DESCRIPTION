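Package: andis
Title: Angle- and Distance-Dependent Statistical Potential for Protein Model Quality Assessment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives and applies an atomic angle- and distance-dependent
    knowledge-based statistical potential (ANDIS) for assessing the quality of
    protein structure models. The potential combines orientation-dependent
    atom-pair energies over 167 residue-specific heavy-atom types with a
    distance-dependent pair potential built on a random-walk chain reference
    state, with the distance cutoff exposed as a tunable parameter: short
    cutoffs with shielding-weighted effective interactions favour native
    recognition, long cutoffs with the combined potential favour decoy
    discrimination. Includes decoy-set evaluation metrics (native recognition,
    Z-score, Pearson correlation with quality scores, 20% enrichment) and a
    deterministic synthetic-structure generator so derivation, scoring and
    evaluation are testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
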