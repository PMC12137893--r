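Package: nsalign
Title: Non-Sequential Protein Structure Alignment via Entropy-Regularized
    Partial Assignment
Version: 0.1.0
Authors@R:
    person("nsalign", "developers", email = "nsalign@example.org",
           role = c("aut", "cre"))
Description: Non-sequential (topology-independent) pairwise protein structure
    alignment. Residue correspondence between two superposed C-alpha traces is
    formulated as a partial linear sum assignment problem with explicit gap
    states, relaxed with an entropy regularizer and solved by a log-domain
    semi-relaxed Sinkhorn iteration. Includes SP-score similarity matrices,
    Kabsch superposition with a fragment-seeded alternating refinement loop,
    an exact assignment oracle, reference-independent (Nali, RMSD, structure
    overlap) and reference-dependent (EQR, agreement) quality metrics,
    ground-truthed synthetic structure generators (circular permutations,
    segment swaps), PDB and rotation-matrix I/O, and command-line drivers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    optparse,
    Rcpp,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
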