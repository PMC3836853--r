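#' Parsimony length of one step-matrix character on a species tree
#'
#' Minimum total transformation cost of the character on the tree, taken
#' over all assignments of observed states to internal nodes, computed by
#' bottom-up (Sankoff) dynamic programming on an arbitrary rooting.  The
#' pairwise patristic distance between two haplotypes on the gene tree is
#' the cost of the corresponding transformation on the species tree.
#' Internal nodes range over the character's observed states only (PAUP
#' step-matrix semantics); taxa missing from the gene contribute an
#' all-zero leaf cost vector, i.e. standard missing data.  Because the cost
#' matrix is symmetric the result does not depend on the rooting.
#'
#' @param tree species tree (`phylo`) whose tips include all the
#'   character's states.
#' @param ch a `gene_character` from [build_character()].
#' @return the minimum cost (scaled steps).
#' @export
character_length <- function(tree, ch) {
  if (!length(ch$states)) {
    warning("character has no observed states; length is 0")
    return(0)
  }
  missing_states <- setdiff(ch$states, tree$tip.label)
  if (length(missing_states))
    stop("species tree lacks taxa required by gene '", ch$gene_id, "': ",
         paste(missing_states, collapse = ", "), call. = FALSE)
  tree <- ape::reorder.phylo(safe_unroot(tree), "postorder")
  tip_state <- match(tree$tip.label, ch$states)
  tip_state[is.na(tip_state)] <- 0L
  sankoff_char_cpp(tree$edge, length(tree$tip.label), as.integer(tip_state),
                   ch$cost)
}

#' Weighted parsimony length of a character matrix on a species tree
#'
#' Sum over genes of `weight * character_length`; additive in characters.
#'
#' @param tree species tree (`phylo`) over the matrix's taxon set.
#' @param matrix a `character_matrix`.
#' @param weights optional per-character weights overriding
#'   `matrix$weights` (used by the bootstrap).
#' @return total tree length in scaled steps.
#' @export
tree_length <- function(tree, matrix, weights = NULL) {
  if (!length(matrix$characters)) return(0)
  if (is.null(weights)) weights <- matrix$weights
  tree <- ape::reorder.phylo(safe_unroot(tree), "postorder")
  ts <- tip_state_matrix(matrix, tree$tip.label)
  costs <- lapply(matrix$characters, `[[`, "cost")
  sankoff_matrix_cpp(tree$edge, length(tree$tip.label), ts, costs,
                     as.numeric(weights))
}

#' Exact character length by exhaustive state enumeration
#'
#' Independent test oracle: enumerates every assignment of observed states
#' to the free nodes (internal nodes and missing-taxon leaves) and takes
#' the minimum edge-cost sum.  Refuses problems whose assignment space is
#' too large to enumerate.
#'
#' @inheritParams character_length
#' @param max_assignments enumeration cap (default 5e6).
#' @return the exact minimum cost.
#' @export
brute_force_length <- function(tree, ch, max_assignments = 5e6) {
  if (!length(ch$states)) return(0)
  tree <- ape::reorder.phylo(safe_unroot(tree), "postorder")
  n_tip <- length(tree$tip.label)
  n_node <- max(tree$edge)
  k <- length(ch$states)
  tip_state <- match(tree$tip.label, ch$states)
  free <- c(which(is.na(tip_state)), (n_tip + 1L):n_node)
  if (k^length(free) > max_assignments)
    stop("too many taxa for brute-force enumeration (",
         k, "^", length(free), " assignments); use character_length()",
         call. = FALSE)
  combos <- as.matrix(expand.grid(rep(list(seq_len(k)), length(free))))
  state <- integer(n_node)
  state[seq_len(n_tip)] <- ifelse(is.na(tip_state), 0L, tip_state)
  best <- Inf
  for (r in seq_len(nrow(combos))) {
    state[free] <- combos[r, ]
    cost <- sum(ch$cost[cbind(state[tree$edge[, 1L]],
                              state[tree$edge[, 2L]])])
    if (cost < best) best <- cost
  }
  best
}

new_parsimony_result <- function(score, best_trees, evaluated, method) {
  class(best_trees) <- "multiPhylo"
  structure(list(score = score, best_trees = best_trees,
                 evaluated = evaluated, method = method),
            class = "parsimony_result")
}

#' @export
print.parsimony_result <- function(x, ...) {
  cat("Parsimony", x$method, "search: best score", format(x$score),
      "(", length(x$best_trees), "tied tree(s),", x$evaluated,
      "topologies evaluated )\n")
  invisible(x)
}

#' Exhaustive parsimony search over all unrooted topologies
#'
#' Scores every unrooted binary topology on the matrix's taxon set and
#' returns the global optimum with all ties (absolute tolerance 1e-9).
#' Limited to nine taxa (135,135 topologies).
#'
#' @param matrix a `character_matrix`.
#' @param weights optional per-character weights.
#' @return a `parsimony_result`.
#' @export
exhaustive_search <- function(matrix, weights = NULL) {
  taxa <- matrix$taxa
  if (length(taxa) > 9L)
    stop("exhaustive search supports at most 9 taxa; use heuristic_search()",
         call. = FALSE)
  if (is.null(weights)) weights <- matrix$weights
  topos <- phangorn::allTrees(length(taxa), rooted = FALSE, tip.label = taxa)
  costs <- lapply(matrix$characters, `[[`, "cost")
  scores <- vapply(topos, function(tr) {
    tr <- ape::reorder.phylo(tr, "postorder")
    ts <- tip_state_matrix(matrix, tr$tip.label)
    sankoff_matrix_cpp(tr$edge, length(taxa), ts, costs,
                       as.numeric(weights))
  }, numeric(1))
  best <- min(scores)
  ties <- which(scores <= best + 1e-9)
  # [[ materializes tip labels from the compressed multiPhylo
  new_parsimony_result(best, lapply(ties, function(i) topos[[i]]),
                       length(topos), "exhaustive")
}

# postorder edge matrix (1..m tip renumbering) for an edge-list tree over a
# subset of tips; returns the sorted original tip ids alongside
edges_postorder <- function(E, tip_ids) {
  tip_ids <- sort(tip_ids)
  m <- length(tip_ids)
  n_max <- max(E)
  adj <- build_adj(E)
  newid <- integer(n_max)
  newid[tip_ids] <- seq_len(m)
  is_tip <- rep(FALSE, n_max); is_tip[tip_ids] <- TRUE
  root <- E[which(!is_tip[E])[1L]]
  next_internal <- m + 1L
  n_edge <- nrow(E)
  edge_pre <- matrix(0L, n_edge, 2L)
  k <- 0L
  stack_node <- integer(n_max); stack_parent <- integer(n_max)
  top <- 1L; stack_node[1L] <- root; stack_parent[1L] <- 0L
  while (top > 0L) {
    v <- stack_node[top]; p <- stack_parent[top]; top <- top - 1L
    if (!is_tip[v]) { newid[v] <- next_internal; next_internal <- next_internal + 1L }
    if (p > 0L) { k <- k + 1L; edge_pre[k, ] <- c(newid[p], newid[v]) }
    for (w in adj[[v]]) if (w != p) {
      top <- top + 1L; stack_node[top] <- w; stack_parent[top] <- v
    }
  }
  list(edge = edge_pre[n_edge:1L, , drop = FALSE], n_tip = m,
       tip_ids = tip_ids)
}

score_edge_tree <- function(E, tip_ids, full_ts, costs, weights) {
  po <- edges_postorder(E, tip_ids)
  sankoff_matrix_cpp(po$edge, po$n_tip,
                     full_ts[po$tip_ids, , drop = FALSE], costs, weights)
}

nni_edge_neighbors <- function(E, n_tip) {
  adj <- build_adj(E)
  out <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1L]; v <- E[i, 2L]
    if (u <= n_tip || v <= n_tip) next
    a <- setdiff(adj[[u]], v)[1L]
    for (c_ in setdiff(adj[[v]], u)) {
      E2 <- drop_edge(drop_edge(E, u, a), v, c_)
      out[[length(out) + 1L]] <- rbind(E2, c(v, a), c(u, c_))
    }
  }
  out
}

#' Heuristic parsimony search (random addition + branch swapping)
#'
#' For each start, taxa are added in a seeded random order by greedy
#' stepwise insertion (each new taxon goes to the edge minimizing the
#' partial tree score), then the tree is improved by steepest-descent
#' branch swapping (NNI, SPR, or TBR neighborhoods) until no neighbor
#' improves the score.  The best score over all starts is returned with all
#' tied endpoint topologies.  Deterministic given `seed`.
#'
#' @param matrix a `character_matrix`.
#' @param n_starts number of random-addition replicates (default 10).
#' @param swap branch-swapping neighborhood: `"SPR"` (default), `"TBR"`,
#'   or `"NNI"`.
#' @param seed integer seed.
#' @param weights optional per-character weights.
#' @return a `parsimony_result`.
#' @export
heuristic_search <- function(matrix, n_starts = 10,
                             swap = c("SPR", "TBR", "NNI"), seed = 1,
                             weights = NULL) {
  swap <- match.arg(swap)
  stopifnot(n_starts >= 1)
  taxa <- matrix$taxa
  n <- length(taxa)
  if (is.null(weights)) weights <- matrix$weights
  weights <- as.numeric(weights)
  full_ts <- tip_state_matrix(matrix, taxa)
  costs <- lapply(matrix$characters, `[[`, "cost")
  neighbor_fun <- switch(swap,
    NNI = function(E) nni_edge_neighbors(E, n),
    SPR = function(E) spr_edge_neighbors(E, n),
    TBR = function(E) c(spr_edge_neighbors(E, n),
                        tbr_internal_neighbors(E, n)))
  evaluated <- 0L
  endpoints <- list(); end_scores <- numeric(0)
  set.seed(seed)
  start_orders <- replicate(n_starts, sample.int(n), simplify = FALSE)
  for (s in seq_len(n_starts)) {
    ord <- start_orders[[s]]
    E <- star3_edges(ord[1:3], n + 1L)
    present <- ord[1:3]
    for (t in ord[-(1:3)]) {
      cands <- attach_tip_everywhere(E, t)
      sc <- vapply(cands, score_edge_tree, numeric(1),
                   tip_ids = c(present, t), full_ts = full_ts,
                   costs = costs, weights = weights)
      evaluated <- evaluated + length(cands)
      E <- cands[[which.min(sc)]]
      present <- c(present, t)
    }
    cur_score <- score_edge_tree(E, present, full_ts, costs, weights)
    repeat {
      neigh <- neighbor_fun(E)
      sc <- vapply(neigh, score_edge_tree, numeric(1),
                   tip_ids = present, full_ts = full_ts,
                   costs = costs, weights = weights)
      evaluated <- evaluated + length(neigh)
      if (!length(sc) || min(sc) >= cur_score - 1e-9) break
      E <- neigh[[which.min(sc)]]
      cur_score <- min(sc)
    }
    endpoints[[s]] <- E
    end_scores[s] <- cur_score
  }
  best <- min(end_scores)
  tied <- which(end_scores <= best + 1e-9)
  trees <- lapply(endpoints[tied], edges_to_phylo, n_tip = n, labels = taxa)
  keys <- vapply(trees, topology_key, character(1))
  trees <- trees[!duplicated(keys)]
  new_parsimony_result(best, trees, evaluated, paste0("heuristic-", swap))
}

#' Nonparametric bootstrap over genes
#'
#' Resamples characters (genes) with replacement to the original count,
#' re-runs the parsimony search on each pseudo-replicate, and records the
#' bipartitions of the replicate's best tree(s); when a replicate has k
#' tied best trees each contributes 1/k.  Support for a split is the
#' percentage of replicates containing it.  Deterministic given `seed`.
#'
#' @param matrix a `character_matrix`.
#' @param replicates number of bootstrap replicates (default 1000).
#' @param seed integer seed.
#' @param search list: `method` (`"heuristic"` or `"exhaustive"`),
#'   `n_starts`, `swap` for the per-replicate search.
#' @return an object of class `bootstrap_support`: list with `replicates`,
#'   `support` (named percentage vector keyed by canonical split),
#'   `seed`.
#' @export
bootstrap <- function(matrix, replicates = 1000, seed = 1,
                      search = list(method = "heuristic", n_starts = 2,
                                    swap = "SPR")) {
  stopifnot(replicates >= 1)
  n_char <- length(matrix$characters)
  set.seed(seed)
  rep_seeds <- sample.int(.Machine$integer.max, replicates)
  tallies <- new.env(parent = emptyenv())
  for (r in seq_len(replicates)) {
    set.seed(rep_seeds[r])
    w <- tabulate(sample.int(n_char, n_char, replace = TRUE), n_char)
    res <- if (identical(search$method, "exhaustive"))
      exhaustive_search(matrix, weights = w)
    else
      heuristic_search(matrix,
                       n_starts = if (is.null(search$n_starts)) 2 else search$n_starts,
                       swap = if (is.null(search$swap)) "SPR" else search$swap,
                       seed = rep_seeds[r], weights = w)
    kt <- length(res$best_trees)
    for (tr in res$best_trees) {
      for (key in names(bipartitions(tr))) {
        prev <- if (is.null(tallies[[key]])) 0 else tallies[[key]]
        tallies[[key]] <- prev + 1 / kt
      }
    }
  }
  keys <- ls(tallies)
  support <- vapply(keys, function(k) 100 * tallies[[k]] / replicates,
                    numeric(1))
  structure(list(replicates = replicates,
                 support = sort(support, decreasing = TRUE), seed = seed),
            class = "bootstrap_support")
}

#' @export
print.bootstrap_support <- function(x, ...) {
  cat("Bootstrap support over", x$replicates, "replicates (seed",
      x$seed, "):\n")
  for (k in names(x$support))
    cat(sprintf("  %6.1f%%  {%s}\n", x$support[[k]], k))
  invisible(x)
}

#' Strict or majority-rule consensus of trees
#'
#' Strict consensus keeps the splits present in every tree; majority rule
#' keeps splits present in more than half the trees.
#'
#' @param trees list of trees (`multiPhylo`) on the same taxa.
#' @param kind `"strict"` or `"majority"`.
#' @return a `phylo`, possibly non-binary.
#' @export
consensus_tree <- function(trees, kind = c("strict", "majority")) {
  kind <- match.arg(kind)
  if (!length(trees)) stop("cannot take the consensus of zero trees")
  class(trees) <- "multiPhylo"
  if (length(trees) == 1L) return(trees[[1L]])
  p <- if (kind == "strict") 1 else 0.5
  ape::consensus(trees, p = p, check.labels = TRUE)
}
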