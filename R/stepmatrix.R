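#' Convert a gene tree into a step-matrix character
#'
#' Treats the gene's haplotypes (one per taxon) as the states of a single
#' ordered multi-state character and its gene tree as the character-state
#' tree: the transformation cost between two states is the patristic
#' distance between the two haplotypes, proportionally rescaled so the
#' maximum pairwise cost equals `max_step`, then rounded to `decimals`
#' digits (half away from zero).  Because every non-degenerate character is
#' normalized to the same maximum step, all genes carry equal weight in the
#' downstream parsimony analysis regardless of their absolute rate.
#'
#' A tree whose patristic distances are all zero yields an all-zero cost
#' matrix flagged `uninformative`; it cannot affect any tree score.
#'
#' @param tree a gene tree (`phylo`, see [parse_newick()]).
#' @param max_step cost assigned to the largest patristic distance
#'   (default 10).
#' @param decimals digits kept in the cost matrix (default 2, forcing
#'   floating-point tree-length evaluation downstream).
#' @return an object of class `gene_character`: a list with `gene_id`,
#'   `states` (taxon names, one state per taxon present), `cost` (symmetric
#'   matrix), and `uninformative` flag.
#' @examples
#' ch <- build_character(parse_newick("((A:1,B:2):1,(C:1,D:1):2);", "g1"))
#' ch$cost["B", "C"] # 10: the largest distance is pinned to the maximum step
#' @export
build_character <- function(tree, max_step = 10, decimals = 2) {
  stopifnot(max_step > 0, decimals >= 0)
  d <- patristic_matrix(tree)
  d_max <- max(d)
  if (d_max == 0) {
    cost <- d # all zero
    uninformative <- TRUE
  } else {
    cost <- round_half_up(max_step * d / d_max, decimals)
    uninformative <- FALSE
  }
  structure(list(gene_id = if (is.null(tree$gene_id)) NA_character_
                 else tree$gene_id,
                 states = rownames(cost),
                 cost = cost,
                 uninformative = uninformative),
            class = "gene_character")
}

# round half away from zero (all costs are non-negative here);
# base round() ties to even, which is not wanted for reproducible matrices
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' @export
print.gene_character <- function(x, ...) {
  cat("Step-matrix character", if (!is.na(x$gene_id)) paste0("'", x$gene_id, "'"),
      "with", length(x$states), "states",
      if (x$uninformative) "(uninformative)" else "", "\n")
  print(x$cost)
  invisible(x)
}

#' Assemble a character matrix from gene trees
#'
#' One step-matrix character per gene tree, all weighted equally.  Taxa in
#' the registry but absent from a gene are recorded as missing for that
#' character and are scored as standard missing data.
#'
#' @param trees list of gene trees.
#' @param taxa character vector: the full (ordered) taxon set.
#' @param max_step,decimals passed to [build_character()].
#' @return an object of class `character_matrix`: list with `taxa`,
#'   `characters` (list of `gene_character`), `weights` (all 1).
#' @export
build_matrix <- function(trees, taxa, max_step = 10, decimals = 2) {
  stopifnot(is.character(taxa), !anyDuplicated(taxa), length(taxa) >= 2)
  ids <- gene_ids(trees)
  characters <- vector("list", length(trees))
  for (i in seq_along(trees)) {
    tips <- trees[[i]]$tip.label
    bad <- setdiff(tips, taxa)
    if (length(bad))
      stop("gene '", ids[i], "' has tip(s) not in the taxon set: ",
           paste(bad, collapse = ", "), call. = FALSE)
    ch <- build_character(trees[[i]], max_step = max_step,
                          decimals = decimals)
    if (is.na(ch$gene_id)) ch$gene_id <- ids[i]
    ch$missing <- setdiff(taxa, ch$states)
    characters[[i]] <- ch
  }
  structure(list(taxa = taxa, characters = characters,
                 weights = rep(1, length(characters))),
            class = "character_matrix")
}

#' @export
print.character_matrix <- function(x, ...) {
  n_un <- sum(vapply(x$characters, `[[`, logical(1), "uninformative"))
  cat("Character matrix:", length(x$characters), "gene characters over",
      length(x$taxa), "taxa\n")
  if (n_un) cat("  ", n_un, "uninformative (zero-distance) character(s)\n")
  invisible(x)
}

# per-character tip-state index columns aligned to a tip-label order;
# 0 marks a taxon missing from the gene
tip_state_matrix <- function(matrix, tip_labels) {
  n_char <- length(matrix$characters)
  out <- matrix(0L, nrow = length(tip_labels), ncol = n_char)
  for (i in seq_len(n_char)) {
    states <- matrix$characters[[i]]$states
    idx <- match(tip_labels, states)
    idx[is.na(idx)] <- 0L
    out[, i] <- idx
  }
  out
}
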