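#' Parse a Newick string into a validated gene tree
#'
#' Wraps [ape::read.tree()] with validation tailored to per-gene trees:
#' tip labels must be unique, branch lengths must be non-negative, and
#' polytomies are preserved.  Missing branch lengths are set to 0 with a
#' warning (maximum-likelihood gene trees normally carry lengths on every
#' edge).
#'
#' @param text a Newick string (single or unquoted labels accepted).
#' @param gene_id optional identifier stored on the returned tree.
#' @return an object of class `phylo` with an added `gene_id` element.
#' @examples
#' tr <- parse_newick("((A:1,B:2):1,(C:1,D:1):2);", gene_id = "g1")
#' max_branch_length(tr)
#' @export
parse_newick <- function(text, gene_id = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  check_newick_syntax(text)
  tree <- tryCatch(
    ape::read.tree(text = text),
    error = function(e) stop("Newick parse error: ", conditionMessage(e),
                             call. = FALSE)
  )
  if (is.null(tree)) stop("Newick parse error: unreadable tree string",
                          call. = FALSE)
  validate_gene_tree(tree, gene_id = gene_id)
}

# cheap structural pre-check so malformed input fails with a character offset
check_newick_syntax <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1L]]
  depth <- 0L
  for (i in seq_along(chars)) {
    if (chars[i] == "(") depth <- depth + 1L
    if (chars[i] == ")") {
      depth <- depth - 1L
      if (depth < 0L)
        stop("Newick parse error: unmatched ')' at character offset ", i,
             call. = FALSE)
    }
  }
  if (depth > 0L)
    stop("Newick parse error: ", depth, " unclosed '(' by character offset ",
         length(chars), call. = FALSE)
  if (!grepl(";", text, fixed = TRUE))
    stop("Newick parse error: missing terminal ';' at character offset ",
         nchar(text), call. = FALSE)
  invisible(TRUE)
}

validate_gene_tree <- function(tree, gene_id = NULL) {
  if (!inherits(tree, "phylo")) stop("not a 'phylo' tree")
  if (length(tree$tip.label) < 2L)
    stop("gene tree must have at least 2 tips", call. = FALSE)
  dup <- unique(tree$tip.label[duplicated(tree$tip.label)])
  if (length(dup))
    stop("duplicate tip label(s): ", paste(dup, collapse = ", "),
         call. = FALSE)
  if (is.null(tree$edge.length)) {
    warning("tree has no branch lengths; defaulting all to 0")
    tree$edge.length <- rep(0, nrow(tree$edge))
  }
  if (anyNA(tree$edge.length)) {
    warning("missing branch length(s); defaulting to 0")
    tree$edge.length[is.na(tree$edge.length)] <- 0
  }
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) are not allowed", call. = FALSE)
  if (!is.null(gene_id)) tree$gene_id <- as.character(gene_id)
  tree
}

#' Read a collection of gene trees
#'
#' Accepts either a single file with one Newick tree per line (gene ids are
#' taken from `ids`, a sidecar vector, or default to the line number) or a
#' directory of per-gene `.nwk`/`.tre`/`.newick` files (gene id = file stem).
#'
#' @param path file or directory.
#' @param ids optional character vector of gene ids (one-per-line file only).
#' @return a list of gene trees (class `multiPhylo`).
#' @export
read_gene_trees <- function(path, ids = NULL) {
  if (dir.exists(path)) {
    files <- sort(list.files(path, pattern = "\\.(nwk|tre|newick)$",
                             full.names = TRUE))
    if (!length(files)) stop("no .nwk/.tre/.newick files in ", path)
    trees <- lapply(files, function(f)
      parse_newick(trimws(paste(readLines(f, warn = FALSE), collapse = "")),
                   gene_id = sub("\\.[^.]+$", "", basename(f))))
  } else {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no trees found in ", path)
    if (is.null(ids)) ids <- sprintf("gene%04d", seq_along(lines))
    if (length(ids) != length(lines))
      stop("length of ids (", length(ids), ") != number of trees (",
           length(lines), ")")
    trees <- Map(parse_newick, lines, ids)
    names(trees) <- NULL
  }
  names(trees) <- vapply(trees, function(t) t$gene_id, character(1))
  class(trees) <- "multiPhylo"
  trees
}

#' Write gene trees as Newick, one per line
#' @param trees list of gene trees.
#' @param path output file.
#' @export
write_gene_trees <- function(trees, path) {
  writeLines(vapply(trees, ape::write.tree, character(1)), path)
  invisible(path)
}

#' Longest branch of a gene tree
#'
#' Maximum over the tree's edge lengths as given.  Re-rooting with
#' [root_on_outgroup()] keeps the split edge's full length on one side and
#' gives the new root edge length 0, so root placement never changes this
#' value.
#'
#' @param tree a gene tree (`phylo`).
#' @return maximum edge length (0 for a tree without lengths).
#' @export
max_branch_length <- function(tree) {
  if (is.null(tree$edge.length)) return(0)
  max(tree$edge.length)
}

#' Exclude gene trees with an over-long branch
#'
#' Gene trees whose longest branch strictly exceeds `threshold` are removed:
#' unusually long branches flag low-quality alignments, non-orthologous
#' genes, or assembly artifacts.  A tree whose longest branch equals the
#' threshold exactly is kept.
#'
#' @param trees list of gene trees.
#' @param threshold maximum tolerated branch length (substitutions/site);
#'   default 1.5.
#' @return a list with elements `kept`, `removed` (both `multiPhylo`,
#'   input order preserved) and `report`, a data frame with columns
#'   `gene_id`, `max_branch`, `removed`.
#' @export
filter_long_branch <- function(trees, threshold = 1.5) {
  stopifnot(threshold > 0)
  if (!length(trees)) {
    empty <- structure(list(), class = "multiPhylo")
    return(list(kept = empty, removed = empty,
                report = data.frame(gene_id = character(0),
                                    max_branch = numeric(0),
                                    removed = logical(0))))
  }
  mb <- vapply(trees, max_branch_length, numeric(1))
  ids <- gene_ids(trees)
  out <- mb > threshold
  kept <- trees[!out]
  removed <- trees[out]
  class(kept) <- class(removed) <- "multiPhylo"
  list(kept = kept, removed = removed,
       report = data.frame(gene_id = ids, max_branch = mb, removed = out,
                           row.names = NULL))
}

# unroot only when there is something to unroot; ape::unroot errors on
# 2-tip trees and on some already-unrooted structures
safe_unroot <- function(tree) {
  if (length(tree$tip.label) > 2L && ape::is.rooted(tree))
    ape::unroot(tree)
  else tree
}

gene_ids <- function(trees) {
  vapply(seq_along(trees), function(i) {
    id <- trees[[i]]$gene_id
    if (is.null(id)) {
      if (!is.null(names(trees)) && nzchar(names(trees)[i])) names(trees)[i]
      else sprintf("gene%04d", i)
    } else id
  }, character(1))
}

#' Patristic (path-length) distance matrix of a tree
#'
#' Sum of branch lengths along the unique path between every pair of tips.
#' Independent of root placement.
#'
#' @param tree a `phylo`.
#' @return symmetric numeric matrix with tip labels as dimnames.
#' @export
patristic_matrix <- function(tree) {
  d <- ape::cophenetic.phylo(tree)
  d[tree$tip.label, tree$tip.label, drop = FALSE]
}

#' Root a tree on its outgroup
#'
#' Roots on the edge subtending the outgroup taxon; total tree length is
#' conserved (the new root edge on the non-outgroup side gets length 0).
#'
#' @param tree a `phylo`.
#' @param outgroup tip label to root on.
#' @return a rooted `phylo`.
#' @export
root_on_outgroup <- function(tree, outgroup) {
  if (!outgroup %in% tree$tip.label)
    stop("outgroup taxon '", outgroup, "' is not a tip of the tree",
         call. = FALSE)
  rooted <- ape::root(tree, outgroup = outgroup, resolve.root = TRUE)
  if (!is.null(rooted$edge.length))
    rooted$edge.length[!is.finite(rooted$edge.length)] <- 0
  rooted$gene_id <- tree$gene_id
  rooted
}

#' Non-trivial bipartitions (splits) of a tree
#'
#' Each internal edge of the unrooted tree induces a split; only splits with
#' at least two taxa on both sides are returned.  Splits are canonicalized by
#' the sorted taxon set on the side *not* containing the reference taxon.
#' Polytomies yield only the splits actually present.
#'
#' @param tree a `phylo`.
#' @param ref reference taxon used for canonicalization; defaults to the
#'   alphabetically first tip.
#' @return named list of character vectors (one sorted taxon set per split);
#'   names are the canonical `"a,b,c"` keys.
#' @export
bipartitions <- function(tree, ref = NULL) {
  tree <- safe_unroot(tree)
  labels <- tree$tip.label
  if (is.null(ref)) ref <- sort(labels)[1L]
  n_tip <- length(labels)
  edge <- ape::reorder.phylo(tree, "postorder")$edge
  n_node <- max(edge)
  below <- vector("list", n_node)
  for (t in seq_len(n_tip)) below[[t]] <- labels[t]
  for (e in seq_len(nrow(edge)))
    below[[edge[e, 1L]]] <- c(below[[edge[e, 1L]]], below[[edge[e, 2L]]])
  internal_child <- edge[, 2L][edge[, 2L] > n_tip]
  root <- edge[nrow(edge), 1L]
  splits <- list()
  for (nd in internal_child) {
    side <- below[[nd]]
    if (length(side) < 2L || length(side) > n_tip - 2L) next
    if (ref %in% side) side <- setdiff(labels, side)
    side <- sort(side)
    splits[[paste(side, collapse = ",")]] <- side
  }
  splits[!duplicated(names(splits))]
}

#' Canonical topology key of an unrooted tree
#'
#' Sorted concatenation of all canonical non-trivial splits; two trees have
#' equal keys iff they share the same unrooted topology.
#'
#' @param tree a `phylo`.
#' @param ref reference taxon (see [bipartitions()]).
#' @return a single string.
#' @export
topology_key <- function(tree, ref = NULL) {
  paste(sort(names(bipartitions(tree, ref = ref))), collapse = ";")
}
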