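# shared fixtures: all built in code, nothing read from disk

# the worked 4-taxon gene tree used throughout: patristic distances
# d(A,B)=3, d(A,C)=d(A,D)=5, d(B,C)=d(B,D)=6, d(C,D)=2
worked_tree <- function() parse_newick("((A:1,B:2):1,(C:1,D:1):2);", "g1")

worked_character <- function() build_character(worked_tree())

quartet <- function(newick) ape::read.tree(text = newick)

# random gene character over n taxa (random topology + exponential lengths)
random_character <- function(n_taxa, gene_id = "g") {
  tr <- ape::rtree(n_taxa, rooted = FALSE,
                   tip.label = sprintf("t%d", seq_len(n_taxa)))
  tr$edge.length <- rexp(nrow(tr$edge), rate = 10)
  tr$gene_id <- gene_id
  build_character(tr)
}

# a rooted clade query matching every non-trivial cluster of `tree` when
# rooted on `outgroup` (i.e. "this exact topology")
topology_query <- function(name, tree, outgroup) {
  rooted <- root_on_outgroup(tree, outgroup)
  labels <- rooted$tip.label
  clusters <- genechar:::tree_clusters(rooted)
  keep <- Filter(function(cl)
    length(cl) >= 2 && length(cl) <= length(labels) - 2 &&
      !outgroup %in% cl, clusters)
  clade_query(name, unique(keep), rooted = TRUE)
}
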