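Package: mrcgbsa
Title: Ligand Binding Affinity Scoring with Multiple Random Conformations
    and MM-GBSA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Estimates relative protein-ligand binding affinities by the
    multiple-random-conformation MM-GBSA (MRC-MMGBSA) approach: ensembles
    of rigid-body ligand placements are generated at increasing
    protein-ligand distances, energy-minimized in a generalized-Born/
    surface-area implicit solvent model, and aggregated into a binding
    score through the Jarzynski exponential-work identity.  Includes the
    single-structure MM-GBSA comparator, docking-pose rescoring against a
    reference complex, linear scaling of scores to binding free-energy
    differences, a deterministic toy force field with minimizer and
    Langevin sampler, and synthetic receptor/ligand fixture generators so
    the whole pipeline runs without external structures or force fields.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    bio3d,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
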