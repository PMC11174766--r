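Package: foldclust
Title: Structure-Based Clustering of Predicted Protein Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Confidence-aware clustering of predicted single-chain protein
    structures. Reads C-alpha models in PDB format with per-residue pLDDT in
    the temperature-factor field, filters by mean confidence, computes
    pairwise TM-score and RMSD by sequence-independent iterative structural
    alignment (Kabsch superposition plus dynamic programming), fuses them
    into a weighted combined similarity, clusters with UPGMA, exports Newick
    trees, and quantifies concordance between structure- and sequence-derived
    groupings (Robinson-Foulds distance, adjusted Rand index, cophenetic
    correlation). Includes a synthetic fold-family generator with tunable
    coordinate noise, terminal indels, simulated confidence profiles, and
    deliberately discordant sequences, so every pipeline stage can be tested
    against planted ground truth.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    ape,
    phangorn,
    mclust,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
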