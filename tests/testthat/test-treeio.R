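test_that("parse_newick builds validated trees and preserves polytomies", {
  t2 <- parse_newick("(A:1,B:1);")
  expect_equal(sort(t2$tip.label), c("A", "B"))
  expect_equal(sort(t2$edge.length), c(1, 1))

  t4 <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);")
  expect_equal(ape::Ntip(t4), 4L)
  expect_setequal(t4$edge.length, c(1, 2))

  star <- parse_newick("(A:1,B:1,C:1);")
  expect_equal(star$Nnode, 1L) # polytomy kept, not arbitrarily resolved
})

test_that("malformed Newick fails with a character offset; duplicates fail", {
  expect_error(parse_newick("((A:1,B:1):1;"), "offset")
  expect_error(parse_newick("(A:1,B:1)):1;"), "offset")
  expect_error(parse_newick("(A:1,B:1)"), "offset")
  expect_error(parse_newick("((A:1,A:1):1,B:1);"), "duplicate")
})

test_that("missing branch lengths default to zero with a warning", {
  expect_warning(tr <- parse_newick("(A,B,C);"), "branch length")
  expect_equal(tr$edge.length, c(0, 0, 0))
})

test_that("max_branch_length is the maximum edge and root-invariant", {
  expect_equal(max_branch_length(parse_newick("((A:1,B:2):1,(C:1,D:1):2);")), 2)
  expect_equal(max_branch_length(parse_newick("(A:0,B:0);")), 0)
  tr <- parse_newick("((A:0.1,B:1.6):0.2,(C:0.3,D:0.1):0.2);")
  expect_equal(max_branch_length(tr), 1.6)
  rooted <- root_on_outgroup(tr, "A")
  expect_equal(max_branch_length(rooted), 1.6)
})

test_that("filter_long_branch is strict at the threshold and conserves counts", {
  mk <- function(x) parse_newick(sprintf("((A:0.1,B:%s):0.1,(C:0.1,D:0.1):0.1);", x))
  trees <- list(mk(1.6), mk(1.5), mk(0.3))
  fl <- filter_long_branch(trees, threshold = 1.5)
  expect_length(fl$kept, 2L)    # a branch of exactly 1.5 is kept
  expect_length(fl$removed, 1L)
  expect_equal(fl$report$removed, c(TRUE, FALSE, FALSE))
  expect_equal(length(fl$kept) + length(fl$removed), length(trees))

  empty <- filter_long_branch(list())
  expect_length(empty$kept, 0L)
  expect_length(empty$removed, 0L)
})

test_that("simulated long-branch artifacts are exactly the removed genes", {
  s <- simulate_species_tree(7, seed = 11)
  g <- simulate_gene_trees(s, sim_config(107, discordance = 0.1,
                                         artifact_fraction = 0.07,
                                         seed = 21))
  truth <- attr(g, "truth")
  fl <- filter_long_branch(g, threshold = 1.5)
  expect_identical(sort(genechar:::gene_ids(fl$removed)),
                   sort(truth$gene_id[truth$class == "artifact"]))
})

test_that("patristic distances are path sums, root-invariant, tree-like", {
  d <- patristic_matrix(worked_tree())
  expect_equal(d["A", "B"], 3)
  expect_equal(d["A", "C"], 5)
  expect_equal(d["A", "D"], 5)
  expect_equal(d["B", "C"], 6)
  expect_equal(d["B", "D"], 6)
  expect_equal(d["C", "D"], 2)
  expect_equal(patristic_matrix(parse_newick("(A:1,B:1);"))["A", "B"], 2)

  # root invariance and the four-point condition on simulated trees
  set.seed(42)
  for (i in 1:20) {
    tr <- ape::rtree(6)
    d <- patristic_matrix(tr)
    re <- root_on_outgroup(ape::unroot(tr), tr$tip.label[1])
    expect_equal(patristic_matrix(re)[rownames(d), colnames(d)], d,
                 tolerance = 1e-12)
    labs <- rownames(d)
    for (q in utils::combn(labs, 4, simplify = FALSE)) {
      sums <- sort(c(d[q[1], q[2]] + d[q[3], q[4]],
                     d[q[1], q[3]] + d[q[2], q[4]],
                     d[q[1], q[4]] + d[q[2], q[3]]))
      expect_lt(sums[3] - sums[2], 1e-9) # two largest sums equal
    }
  }
})

test_that("root_on_outgroup conserves length and recovers clusters", {
  tr <- parse_newick("((A:1,B:1):1,(C:1,O:1):1);")
  rooted <- root_on_outgroup(tr, "O")
  expect_equal(sum(rooted$edge.length), sum(tr$edge.length))
  keys <- vapply(genechar:::tree_clusters(rooted), paste, character(1),
                 collapse = ",")
  expect_true("A,B" %in% keys)
  expect_true("A,B,C" %in% keys)
  expect_error(root_on_outgroup(tr, "Z"), "Z")
})

test_that("bipartitions returns canonical non-trivial splits only", {
  sp <- bipartitions(parse_newick("((A:1,B:1):1,(C:1,D:1):1);"))
  expect_equal(names(sp), "C,D") # canonical side avoids the reference taxon A
  expect_length(bipartitions(parse_newick("(A:1,B:1,C:1,D:1);")), 0L)
  sp5 <- bipartitions(parse_newick("(((A:1,B:1):1,C:1):1,(D:1,E:1):1);"))
  expect_length(sp5, 2L)
  expect_setequal(names(sp5), c("D,E", "C,D,E"))
})

test_that("reading a one-per-line file and a directory both work", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines(c("(A:1,B:1,C:1);", "((A:1,B:1):1,C:1);"), f)
  trees <- read_gene_trees(f)
  expect_length(trees, 2L)
  expect_equal(names(trees), c("gene0001", "gene0002"))

  d <- withr::local_tempdir()
  writeLines("(A:1,B:2);", file.path(d, "geneX.nwk"))
  trees2 <- read_gene_trees(d)
  expect_equal(names(trees2), "geneX")
  expect_equal(trees2[[1]]$gene_id, "geneX")
})
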