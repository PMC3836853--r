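Package: genechar
Title: Genes as Characters: Step-Matrix Parsimony Phylogenomics from Gene Trees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Summarizes collections of per-gene phylogenetic trees into species
    trees by treating each gene as a single ordered multi-state character.
    Haplotypes are character states, patristic distances on the gene tree
    (rescaled so the maximum step is ten) are the transformation costs, and
    species trees are scored by generalized (Sankoff) parsimony with equal
    gene weights. Includes gene-tree quality filtering by maximum branch
    length, exhaustive and heuristic (NNI/SPR/TBR) tree search, nonparametric
    character bootstrap over genes, PAUP-compatible NEXUS step-matrix export,
    gene-support tallies for competing clade hypotheses, chi-square tests of
    association between gene categories and supported hypotheses, and a
    seeded simulator of discordant gene-tree sets for validation.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    ape,
    phangorn,
    Rcpp,
    stats,
    utils,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
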