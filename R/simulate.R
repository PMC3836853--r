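#' Simulation settings for synthetic gene-tree sets
#'
#' The generator emulates the statistical structure the genes-as-characters
#' analysis assumes: a majority of gene trees concordant with one species
#' tree, a conflicting minority (topological discordance via random NNI
#' rearrangements), multiplicative branch-length noise, and a small share
#' of artifact trees carrying one grossly over-long branch of the kind
#' produced by poor alignments, paralogy, or assembly error.
#'
#' @param n_genes number of gene trees.
#' @param discordance probability a gene's topology is perturbed
#'   (default 0.1).
#' @param topo_moves random NNI moves applied to a perturbed gene
#'   (default 1).
#' @param length_noise_sd sd of the lognormal multiplier applied to every
#'   branch (default 0.3).
#' @param artifact_fraction probability a gene receives one artifact
#'   branch (default 0).
#' @param artifact_scale artifact branch length as a multiple of the gene
#'   tree's diameter; at least 10 (default 10).
#' @param seed integer seed.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_genes, discordance = 0.1, topo_moves = 1,
                       length_noise_sd = 0.3, artifact_fraction = 0,
                       artifact_scale = 10, seed = 1) {
  stopifnot(n_genes >= 1, discordance >= 0, discordance <= 1,
            artifact_fraction >= 0, artifact_fraction <= 1,
            length_noise_sd >= 0, topo_moves >= 0, artifact_scale >= 10)
  structure(list(n_genes = as.integer(n_genes), discordance = discordance,
                 topo_moves = as.integer(topo_moves),
                 length_noise_sd = length_noise_sd,
                 artifact_fraction = artifact_fraction,
                 artifact_scale = artifact_scale, seed = as.integer(seed)),
            class = "sim_config")
}

# stable per-gene sub-seed derived from the run seed and gene index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 1000003) %% 2147483562) + 1L
}

#' Simulate a species tree
#'
#' Random binary unrooted topology, uniform over labeled topologies
#' (sequential taxon insertion onto a uniformly chosen edge), with
#' exponential branch lengths of mean 0.1 substitutions/site.
#'
#' @param n_taxa number of taxa (at least 4).
#' @param seed integer seed.
#' @param taxa optional taxon names (default `t1..tn`).
#' @param mean_branch mean branch length (default 0.1).
#' @return an unrooted binary `phylo` with branch lengths.
#' @export
simulate_species_tree <- function(n_taxa, seed = 1, taxa = NULL,
                                  mean_branch = 0.1) {
  stopifnot(n_taxa >= 4)
  if (is.null(taxa)) taxa <- sprintf("t%d", seq_len(n_taxa))
  stopifnot(length(taxa) == n_taxa, !anyDuplicated(taxa))
  set.seed(seed)
  E <- star3_edges(1:3, n_taxa + 1L)
  for (tip in seq(4L, n_taxa)) {
    cands <- attach_tip_everywhere(E, tip)
    E <- cands[[sample.int(length(cands), 1L)]]
  }
  tree <- edges_to_phylo(E, n_taxa, taxa)
  tree$edge.length <- rexp(nrow(tree$edge), rate = 1 / mean_branch)
  tree
}

#' Simulate a set of gene trees around a species tree
#'
#' Each gene starts from the species tree.  With probability
#' `cfg$discordance` its topology is perturbed by `cfg$topo_moves` random
#' NNI moves; every branch is then multiplied by an independent
#' lognormal(0, `length_noise_sd`) factor; artifact genes get one
#' uniformly chosen branch inflated to `artifact_scale` times the gene
#' tree's diameter (maximum patristic distance).  Per-gene randomness uses
#' sub-seeds derived deterministically from the run seed and gene index,
#' so outputs are reproducible bit for bit.
#'
#' @param species_tree a `phylo` with branch lengths.
#' @param cfg a `sim_config`.
#' @return a `multiPhylo` of gene trees with a `truth` attribute: data
#'   frame (`gene_id`, `class` in concordant/discordant/artifact).
#' @export
simulate_gene_trees <- function(species_tree, cfg) {
  stopifnot(inherits(cfg, "sim_config"),
            !is.null(species_tree$edge.length))
  trees <- vector("list", cfg$n_genes)
  classes <- character(cfg$n_genes)
  for (i in seq_len(cfg$n_genes)) {
    set.seed(derive_seed(cfg$seed, i))
    g <- species_tree
    discordant <- runif(1) < cfg$discordance
    artifact <- runif(1) < cfg$artifact_fraction
    if (discordant && cfg$topo_moves > 0)
      g <- phangorn::rNNI(g, moves = cfg$topo_moves)
    if (cfg$length_noise_sd > 0)
      g$edge.length <- g$edge.length *
        rlnorm(length(g$edge.length), 0, cfg$length_noise_sd)
    if (artifact) {
      diameter <- max(patristic_matrix(g))
      target <- sample.int(length(g$edge.length), 1L)
      g$edge.length[target] <- cfg$artifact_scale * diameter
    }
    g$gene_id <- sprintf("gene%04d", i)
    trees[[i]] <- g
    classes[i] <- if (artifact) "artifact"
                  else if (discordant) "discordant" else "concordant"
  }
  names(trees) <- vapply(trees, `[[`, character(1), "gene_id")
  class(trees) <- "multiPhylo"
  attr(trees, "truth") <- data.frame(gene_id = names(trees),
                                     class = classes, row.names = NULL)
  trees
}

#' Plant category enrichments over hypothesis labels
#'
#' Draws gene-category memberships with a baseline rate, raising the odds
#' of membership for genes carrying a specified hypothesis label by the
#' given odds ratio.  Used to validate the association scan: an empty
#' `enriched` list gives a pure null.
#'
#' @param gene_labels named character vector, gene id -> hypothesis.
#' @param n_categories number of categories (`cat0001`...).
#' @param enriched list of `list(category=, hypothesis=, odds_ratio=)`.
#' @param baseline baseline membership probability (default 0.1).
#' @param seed integer seed.
#' @return data frame (`gene_id`, `category`), long format.
#' @export
plant_enrichment <- function(gene_labels, n_categories, enriched = list(),
                             baseline = 0.1, seed = 1) {
  stopifnot(n_categories >= 1, baseline > 0, baseline < 1)
  for (e in enriched) stopifnot(e$odds_ratio > 0)
  genes <- names(gene_labels)
  cats <- sprintf("cat%04d", seq_len(n_categories))
  enr <- setNames(vector("list", length(cats)), cats)
  for (e in enriched) enr[[e$category]] <- e
  base_odds <- baseline / (1 - baseline)
  set.seed(seed)
  rows <- vector("list", length(cats))
  for (ci in seq_along(cats)) {
    p <- rep(baseline, length(genes))
    e <- enr[[cats[ci]]]
    if (!is.null(e)) {
      odds <- base_odds * e$odds_ratio
      p[gene_labels == e$hypothesis] <- odds / (1 + odds)
    }
    member <- runif(length(genes)) < p
    if (any(member))
      rows[[ci]] <- data.frame(gene_id = genes[member],
                               category = cats[ci])
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  rownames(out) <- NULL
  out
}
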