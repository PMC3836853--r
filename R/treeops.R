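# Low-level unrooted-tree surgery used by the parsimony search.
#
# Trees are manipulated as plain undirected edge lists (2-column matrix of
# node ids; tips are ids 1..n_tip in taxon order, internal ids above that,
# not necessarily contiguous) and converted back to ape "phylo" objects for
# scoring and user-facing output.

phylo_to_edges <- function(tree) {
  tree <- safe_unroot(tree)
  list(E = tree$edge, n_tip = length(tree$tip.label),
       labels = tree$tip.label)
}

edges_to_phylo <- function(E, n_tip, labels) {
  n_max <- max(E)
  adj <- vector("list", n_max)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1L]; b <- E[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  root <- E[which(E > n_tip)[1L]]
  # preorder DFS from an internal root, renumbering internal nodes so the
  # result is a valid cladewise "phylo" edge matrix
  newid <- integer(n_max)
  newid[seq_len(n_tip)] <- seq_len(n_tip)
  next_internal <- n_tip + 1L
  edge_out <- matrix(0L, nrow = nrow(E), ncol = 2L)
  k <- 0L
  stack_node <- integer(n_max); stack_parent <- integer(n_max)
  top <- 1L
  stack_node[1L] <- root; stack_parent[1L] <- 0L
  while (top > 0L) {
    v <- stack_node[top]; p <- stack_parent[top]; top <- top - 1L
    if (v > n_tip) { newid[v] <- next_internal; next_internal <- next_internal + 1L }
    if (p > 0L) { k <- k + 1L; edge_out[k, ] <- c(newid[p], newid[v]) }
    for (w in adj[[v]]) if (w != p) {
      top <- top + 1L
      stack_node[top] <- w; stack_parent[top] <- v
    }
  }
  structure(list(edge = edge_out, tip.label = labels,
                 Nnode = next_internal - 1L - n_tip),
            class = "phylo")
}

edge_degrees <- function(E, n_max) {
  tabulate(c(E), nbins = n_max)
}

# nodes reachable from v without crossing the edge (u, v)
component_from <- function(adj, v, u) {
  seen <- v
  frontier <- v
  repeat {
    nxt <- setdiff(unlist(adj[frontier]), c(seen, u))
    if (!length(nxt)) break
    seen <- c(seen, nxt)
    frontier <- nxt
  }
  seen
}

build_adj <- function(E) {
  n_max <- max(E)
  adj <- vector("list", n_max)
  for (i in seq_len(nrow(E))) {
    a <- E[i, 1L]; b <- E[i, 2L]
    adj[[a]] <- c(adj[[a]], b)
    adj[[b]] <- c(adj[[b]], a)
  }
  adj
}

drop_edge <- function(E, a, b) {
  hit <- which((E[, 1L] == a & E[, 2L] == b) | (E[, 1L] == b & E[, 2L] == a))
  E[-hit[1L], , drop = FALSE]
}

# subtree-prune-regraft neighborhood of an unrooted tree
spr_edge_neighbors <- function(E, n_tip) {
  adj <- build_adj(E)
  n_max <- max(E)
  deg <- edge_degrees(E, n_max)
  out <- list()
  for (i in seq_len(nrow(E))) {
    for (orient in 1:2) {
      u <- E[i, orient]; v <- E[i, 3L - orient]
      if (deg[u] < 3L) next # pruning everything but one tip: nothing to regraft
      sub_nodes <- component_from(adj, v, u)
      nb <- setdiff(adj[[u]], v) # the two remaining neighbors of u
      a <- nb[1L]; b <- nb[2L]
      E2 <- drop_edge(drop_edge(drop_edge(E, u, v), u, a), u, b)
      E2 <- rbind(E2, c(a, b))
      in_sub <- rep(FALSE, n_max); in_sub[sub_nodes] <- TRUE
      for (j in seq_len(nrow(E2))) {
        x <- E2[j, 1L]; y <- E2[j, 2L]
        if (in_sub[x] || in_sub[y]) next            # can't regraft inside the pruned part
        if ((x == a && y == b) || (x == b && y == a)) next # recreates the original
        E3 <- rbind(E2[-j, , drop = FALSE], c(x, u), c(u, y), c(u, v))
        out[[length(out) + 1L]] <- E3
      }
    }
  }
  out
}

# tree-bisection-reconnection across internal edges; pendant-edge moves are
# already covered by the SPR neighborhood
tbr_internal_neighbors <- function(E, n_tip) {
  adj <- build_adj(E)
  n_max <- max(E)
  out <- list()
  for (i in seq_len(nrow(E))) {
    u <- E[i, 1L]; v <- E[i, 2L]
    if (u <= n_tip || v <= n_tip) next
    A_nodes <- component_from(adj, u, v)
    in_A <- rep(FALSE, n_max); in_A[A_nodes] <- TRUE
    na <- setdiff(adj[[u]], v); nb <- setdiff(adj[[v]], u)
    E0 <- drop_edge(E, u, v)
    E0 <- drop_edge(drop_edge(E0, u, na[1L]), u, na[2L])
    E0 <- drop_edge(drop_edge(E0, v, nb[1L]), v, nb[2L])
    E0 <- rbind(E0, c(na[1L], na[2L]), c(nb[1L], nb[2L]))
    eA <- which(in_A[E0[, 1L]] & in_A[E0[, 2L]])
    eB <- which(!in_A[E0[, 1L]] & !in_A[E0[, 2L]])
    idxA_orig <- nrow(E0) - 1L # the (na1,na2) suppression edge
    idxB_orig <- nrow(E0)
    for (ja in eA) for (jb in eB) {
      if (ja == idxA_orig && jb == idxB_orig) next # original tree
      xa <- E0[ja, 1L]; ya <- E0[ja, 2L]
      xb <- E0[jb, 1L]; yb <- E0[jb, 2L]
      E3 <- rbind(E0[-c(ja, jb), , drop = FALSE],
                  c(xa, u), c(u, ya), c(xb, v), c(v, yb), c(u, v))
      out[[length(out) + 1L]] <- E3
    }
  }
  out
}

# all trees obtained by attaching tip `tip_id` onto each edge of E
attach_tip_everywhere <- function(E, tip_id) {
  new_node <- max(E, tip_id) + 1L
  lapply(seq_len(nrow(E)), function(j) {
    x <- E[j, 1L]; y <- E[j, 2L]
    rbind(E[-j, , drop = FALSE], c(x, new_node), c(new_node, y),
          c(new_node, tip_id))
  })
}

# the unique unrooted "tree" on three tips
star3_edges <- function(tip_ids, internal_id) {
  cbind(rep(internal_id, 3L), tip_ids)
}
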