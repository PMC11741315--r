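Package: eslpsc
Title: Evolutionary Sparse Learning with Paired Species Contrasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds sparse logistic genetic models of convergent traits from
    per-locus multiple sequence alignments and a rooted species phylogeny using
    a paired species contrast (PSC) training design. Alignments are one-hot
    encoded and fitted with bilevel (site plus locus) sparse-group lasso
    logistic regression over a grid of inclusion penalties; models are scored
    with a Model Fit Score, combined into predictive ensembles, and candidate
    loci are ranked by Group Sparsity Scores within and across species
    combinations. Includes two null-model constructions (response-flipped
    configurations and pair-randomized alignments), a fourfold-degenerate-site
    control for codon alignments, and a phylogenetic simulator that implants
    convergent and clade-confounded sites for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    seqinr,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
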