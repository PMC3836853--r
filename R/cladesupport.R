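#' Define a clade hypothesis query
#'
#' A hypothesis is diagnosed by one or more taxon clusters that must all be
#' present on a gene tree (e.g. the archosaur placement of turtles is the
#' nested clade `((ZF,Ch),PT)`, i.e. clusters `{ZF,Ch}` and `{ZF,Ch,PT}`).
#' Rooted queries are evaluated as clusters on the outgroup-rooted tree;
#' unrooted queries as exact splits.
#'
#' @param name hypothesis label.
#' @param clades list of character vectors, each a taxon set with at least
#'   two members.
#' @param rooted evaluate as rooted clusters (default TRUE).
#' @return an object of class `clade_query`.
#' @export
clade_query <- function(name, clades, rooted = TRUE) {
  if (is.character(clades)) clades <- list(clades)
  stopifnot(length(clades) >= 1,
            all(vapply(clades, length, integer(1)) >= 2))
  structure(list(name = name, clades = lapply(clades, sort),
                 rooted = rooted),
            class = "clade_query")
}

# tip clusters (descendant tip sets) of a rooted tree, internal nodes only
tree_clusters <- function(tree) {
  labels <- tree$tip.label
  n_tip <- length(labels)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  below <- vector("list", max(edge))
  for (t in seq_len(n_tip)) below[[t]] <- labels[t]
  for (e in seq_len(nrow(edge)))
    below[[edge[e, 1L]]] <- c(below[[edge[e, 1L]]], below[[edge[e, 2L]]])
  lapply(below[(n_tip + 1L):max(edge)], sort)
}

#' Does a gene tree contain a clade hypothesis?
#'
#' TRUE iff every clade of the query appears on the tree: as a cluster of
#' the outgroup-rooted tree for rooted queries, or as an exact bipartition
#' for unrooted queries.  A polytomy never certifies a resolved clade, and
#' a tree lacking any query taxon counts as not supporting (the reason is
#' attached as an attribute).
#'
#' @param tree a gene tree (`phylo`).
#' @param query a `clade_query`.
#' @param outgroup outgroup taxon (required for rooted queries).
#' @return logical scalar.
#' @export
clade_present <- function(tree, query, outgroup = NULL) {
  qtaxa <- unique(unlist(query$clades))
  absent <- setdiff(qtaxa, tree$tip.label)
  if (length(absent))
    return(structure(FALSE, reason = paste("missing taxa:",
                                           paste(absent, collapse = ","))))
  if (query$rooted) {
    if (is.null(outgroup))
      stop("rooted clade query '", query$name, "' requires an outgroup",
         call. = FALSE)
    rooted <- root_on_outgroup(tree, outgroup)
    clusters <- tree_clusters(rooted)
    keys <- vapply(clusters, paste, character(1), collapse = ",")
    all(vapply(query$clades, function(cl)
      paste(cl, collapse = ",") %in% keys, logical(1)))
  } else {
    splits <- bipartitions(tree)
    labels <- tree$tip.label
    has_split <- function(cl) {
      comp <- sort(setdiff(labels, cl))
      any(vapply(splits, function(s)
        identical(s, cl) || identical(s, comp), logical(1)))
    }
    all(vapply(query$clades, has_split, logical(1)))
  }
}

#' Classify a gene tree against an ordered set of hypotheses
#'
#' Returns the first matching query's name, or `"other"`.  Top-level
#' queries must be mutually exclusive on the data: a gene tree satisfying
#' two of them is an error naming the gene.
#'
#' @param tree a gene tree.
#' @param queries list of `clade_query`.
#' @param outgroup outgroup taxon for rooted queries.
#' @return the matching hypothesis name or `"other"`.
#' @export
classify_gene <- function(tree, queries, outgroup = NULL) {
  hits <- vapply(queries, function(q)
    isTRUE(clade_present(tree, q, outgroup)), logical(1))
  if (sum(hits) > 1L) {
    id <- if (is.null(tree$gene_id)) "<unnamed>" else tree$gene_id
    stop("gene '", id, "' satisfies non-exclusive hypotheses: ",
         paste(vapply(queries[hits], `[[`, character(1), "name"),
               collapse = " & "), call. = FALSE)
  }
  if (any(hits)) queries[[which(hits)]]$name else "other"
}

#' Tally gene support for competing clade hypotheses
#'
#' The simple count method: each gene tree is classified by the hypothesis
#' whose diagnostic clade(s) it contains, regardless of other
#' relationships; the hypothesis supported by the most genes is preferred.
#' Optional nested queries (progressively larger enclosing topologies of a
#' hypothesis) are counted non-exclusively, so their counts are monotone
#' non-increasing as the queried topology grows.
#'
#' @param trees list of gene trees.
#' @param queries list of mutually exclusive top-level `clade_query`.
#' @param outgroup outgroup taxon for rooted queries.
#' @param nested optional list of additional `clade_query` counted
#'   independently (Table-style nested rows).
#' @return an object of class `support_tally`: list with `total_genes`,
#'   `counts`, `percentages` (display-rounded to whole percent), `other`,
#'   `labels` (per-gene classification), and `nested_counts`.
#' @export
tally <- function(trees, queries, outgroup = NULL, nested = NULL) {
  qnames <- vapply(queries, `[[`, character(1), "name")
  if (!length(trees)) {
    return(structure(list(total_genes = 0L,
                          counts = setNames(rep(0L, length(qnames)), qnames),
                          percentages = setNames(rep(0, length(qnames)), qnames),
                          other = 0L, labels = character(0),
                          nested_counts = NULL),
                     class = "support_tally"))
  }
  labels <- vapply(trees, classify_gene, character(1),
                   queries = queries, outgroup = outgroup)
  names(labels) <- gene_ids(trees)
  counts <- setNames(vapply(qnames, function(q) sum(labels == q),
                            integer(1)), qnames)
  other <- sum(labels == "other")
  nested_counts <- NULL
  if (!is.null(nested)) {
    nested_counts <- setNames(
      vapply(nested, function(q)
        sum(vapply(trees, function(tr)
          isTRUE(clade_present(tr, q, outgroup)), logical(1))),
        integer(1)),
      vapply(nested, `[[`, character(1), "name"))
  }
  structure(list(total_genes = length(trees), counts = counts,
                 percentages = round(100 * counts / length(trees)),
                 other = other, labels = labels,
                 nested_counts = nested_counts),
            class = "support_tally")
}

#' @export
print.support_tally <- function(x, ...) {
  cat("Gene-support tally over", x$total_genes, "gene trees:\n")
  for (q in names(x$counts))
    cat(sprintf("  %-30s %6d (%d%%)\n", q, x$counts[[q]],
                x$percentages[[q]]))
  cat(sprintf("  %-30s %6d\n", "Other topologies", x$other))
  if (!is.null(x$nested_counts)) {
    cat("Nested clade counts (non-exclusive):\n")
    for (q in names(x$nested_counts))
      cat(sprintf("  %-30s %6d\n", q, x$nested_counts[[q]]))
  }
  invisible(x)
}

#' Write a support tally as TSV
#' @param x a `support_tally`.
#' @param path output file.
#' @export
write_tally <- function(x, path) {
  df <- data.frame(hypothesis = c(names(x$counts), "other"),
                   genes = c(unname(x$counts), x$other),
                   percent = c(unname(x$percentages),
                               round(100 * x$other / max(x$total_genes, 1L))))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
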