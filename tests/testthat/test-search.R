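test_that("a single clean gene's topology wins the exhaustive search", {
  m <- build_matrix(list(worked_tree()), c("A", "B", "C", "D"))
  res <- exhaustive_search(m)
  expect_equal(res$score, 16.66)
  expect_equal(res$evaluated, 3L)
  expect_length(res$best_trees, 1L)
  expect_identical(topology_key(res$best_trees[[1]]),
                   topology_key(quartet("((A,B),(C,D));")))
})

test_that("mirror-image conflicting genes tie and all ties are reported", {
  g1 <- parse_newick("((A:1,B:1):1,(C:1,D:1):1);", "g1")
  g2 <- parse_newick("((A:1,C:1):1,(B:1,D:1):1);", "g2")
  m <- build_matrix(list(g1, g2), c("A", "B", "C", "D"))
  res <- exhaustive_search(m)
  expect_length(res$best_trees, 2L)
  keys <- vapply(res$best_trees, topology_key, character(1))
  expect_setequal(keys, c(topology_key(quartet("((A,B),(C,D));")),
                          topology_key(quartet("((A,C),(B,D));"))))
})

test_that("exhaustive search over 7 taxa scores all 945 topologies", {
  s <- simulate_species_tree(7, seed = 17)
  g <- simulate_gene_trees(s, sim_config(60, discordance = 0.1, seed = 19))
  m <- build_matrix(g, s$tip.label)
  res <- exhaustive_search(m)
  expect_equal(res$evaluated, 945L)
  expect_identical(topology_key(res$best_trees[[1]]), topology_key(s))
})

test_that("heuristic search matches the exhaustive optimum and is seeded", {
  s <- simulate_species_tree(6, seed = 23)
  g <- simulate_gene_trees(s, sim_config(40, discordance = 0.2, seed = 29))
  m <- build_matrix(g, s$tip.label)
  exact <- exhaustive_search(m)
  for (swap in c("NNI", "SPR", "TBR")) {
    h <- heuristic_search(m, n_starts = 5, swap = swap, seed = 31)
    expect_gte(h$score, exact$score - 1e-9)
    expect_equal(h$score, exact$score, tolerance = 1e-9)
  }
  h1 <- heuristic_search(m, n_starts = 3, seed = 7)
  h2 <- heuristic_search(m, n_starts = 3, seed = 7)
  expect_identical(h1$score, h2$score)
  expect_identical(vapply(h1$best_trees, topology_key, character(1)),
                   vapply(h2$best_trees, topology_key, character(1)))
})

test_that("identical characters recover their common topology from any seed", {
  tr <- parse_newick("(((A:0.13,B:0.27):0.19,C:0.31):0.23,(D:0.41,E:0.11):0.17);", "g")
  m <- build_matrix(list(tr, tr, tr), c("A", "B", "C", "D", "E"))
  for (seed in c(1, 2, 99)) {
    h <- heuristic_search(m, n_starts = 2, seed = seed)
    expect_identical(topology_key(h$best_trees[[1]]),
                     topology_key(tr))
  }
})

test_that("bootstrap support is 100 for unanimous genes and seeded", {
  tr <- parse_newick("(((A:0.13,B:0.27):0.19,C:0.31):0.23,(D:0.41,E:0.11):0.17);", "g")
  m <- build_matrix(list(tr, tr, tr, tr), c("A", "B", "C", "D", "E"))
  bs <- bootstrap(m, replicates = 10, seed = 3,
                  search = list(method = "exhaustive"))
  expect_true(all(bs$support == 100))
  expect_setequal(names(bs$support), names(bipartitions(tr)))
  bs2 <- bootstrap(m, replicates = 10, seed = 3,
                   search = list(method = "exhaustive"))
  expect_identical(bs$support, bs2$support)
})

test_that("a single bootstrap replicate gives all-or-nothing support", {
  s <- simulate_species_tree(5, seed = 41)
  g <- simulate_gene_trees(s, sim_config(20, discordance = 0.3, seed = 43))
  m <- build_matrix(g, s$tip.label)
  bs <- bootstrap(m, replicates = 1, seed = 5,
                  search = list(method = "exhaustive"))
  expect_true(all(bs$support <= 100 & bs$support > 0))
  # with no ties the values are exactly 0 or 100; fractional only under ties
  expect_true(all(bs$support %in% c(100) |
                    (bs$support > 0 & bs$support < 100)))
})

test_that("high discordance drags focal support well below 100", {
  s <- simulate_species_tree(7, seed = 53)
  g <- simulate_gene_trees(s, sim_config(60, discordance = 0.9,
                                         topo_moves = 3, seed = 59))
  m <- build_matrix(g, s$tip.label)
  bs <- bootstrap(m, replicates = 30, seed = 61,
                  search = list(method = "heuristic", n_starts = 1))
  expect_true(min(bs$support) < 95)
})

test_that("strict and majority consensus follow their split rules", {
  t1 <- ape::read.tree(text = "(((A,B),C),(D,E));")
  t2 <- ape::read.tree(text = "(((A,B),D),(C,E));")
  strict <- consensus_tree(list(t1, t2), "strict")
  expect_equal(length(bipartitions(strict)), 1L) # only {A,B} is shared
  expect_identical(names(bipartitions(strict)), "C,D,E")

  same <- consensus_tree(list(t1, t1), "strict")
  expect_identical(topology_key(same), topology_key(t1))

  maj <- consensus_tree(list(t1, t1, t2), "majority")
  expect_identical(topology_key(maj), topology_key(t1))
  # a split in exactly half the trees is not a majority
  half <- consensus_tree(list(t1, t2), "majority")
  expect_equal(length(bipartitions(half)), 1L)

  expect_error(consensus_tree(list()), "zero trees")
})
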