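#' Expected counts of a 2x2 contingency table
#'
#' Under independence, `E[i,j] = rowsum_i * colsum_j / total`; margins are
#' conserved exactly.
#'
#' @param x a 2x2 matrix of non-negative counts.
#' @return 2x2 matrix of expected counts.
#' @export
expected_counts <- function(x) {
  x <- as.matrix(x)
  stopifnot(identical(dim(x), c(2L, 2L)), all(x >= 0))
  if (sum(x) == 0) stop("contingency table has zero total", call. = FALSE)
  outer(rowSums(x), colSums(x)) / sum(x)
}

#' Pearson chi-square test of a 2x2 table, no continuity correction
#'
#' The uncorrected Pearson statistic `sum((O - E)^2 / E)` with one degree
#' of freedom.  No Yates correction is applied: with thousands of genes per
#' margin the correction is unnecessary and would change the statistic
#' (e.g. the positive-selection table 143/37 vs 1917/741 gives 4.54
#' uncorrected but about 4.18 corrected).
#'
#' @param x a 2x2 matrix of counts (rows = category present/absent,
#'   columns = hypothesis supporters).
#' @return an object of class `chisq2x2`: list with `statistic`, `df`,
#'   `p_value`, `expected`, `observed`.
#' @export
chisq_2x2 <- function(x) {
  x <- as.matrix(x)
  E <- expected_counts(x)
  if (any(E == 0))
    stop("a zero expected cell: the chi-square approximation is invalid; ",
         "use an exact test", call. = FALSE)
  ht <- suppressWarnings(stats::chisq.test(x, correct = FALSE))
  structure(list(statistic = unname(ht$statistic), df = 1L,
                 p_value = unname(ht$p.value), expected = E, observed = x),
            class = "chisq2x2")
}

#' @export
print.chisq2x2 <- function(x, ...) {
  cat(sprintf("2x2 chi-square: X^2 = %.4g, df = 1, P = %.4g\n",
              x$statistic, x$p_value))
  obs <- x$observed
  for (i in 1:2)
    cat(sprintf("  %8d (%.2f)  %8d (%.2f)\n",
                obs[i, 1], x$expected[i, 1], obs[i, 2], x$expected[i, 2]))
  invisible(x)
}

#' Scan gene categories for association with supported hypotheses
#'
#' For every category with more than `min_genes` member genes, builds a
#' 2x2 table of category membership against hypothesis support and runs
#' the uncorrected chi-square test.  Two table layouts are available:
#'
#' * `"focal_vs_other"` (functional-category scans): genes supporting the
#'   focal hypothesis vs all other genes, crossed with category
#'   presence/absence (the A+/A-/O+/O- layout).
#' * `"two_hypotheses"` (category vs two competing placements): restricted
#'   to genes supporting either of two hypotheses; columns are the two
#'   hypotheses, rows category presence/absence.
#'
#' A Benjamini-Hochberg adjusted p-value column is reported for reference
#' but no filtering is applied to it.
#'
#' @param gene_labels named character vector: gene id -> supported
#'   hypothesis label (e.g. from `tally()$labels`).
#' @param categories data frame with columns `gene_id`, `category` (a gene
#'   may appear in many categories), or a named list of category -> gene id
#'   vectors.
#' @param focal hypothesis label defining the focal column.
#' @param alternative second hypothesis label (required for
#'   `"two_hypotheses"`).
#' @param min_genes a category is tested only when strictly more than this
#'   many scanned genes carry it (default 5).
#' @param mode table layout, see above.
#' @return data frame sorted by p-value with columns `category`,
#'   `focal_with`, `focal_without`, `other_with`, `other_without`,
#'   `statistic`, `p_value`, `p_adjust_BH`, and expected counts
#'   `exp_focal_with`, `exp_other_with`.
#' @export
association_scan <- function(gene_labels, categories, focal,
                             alternative = NULL, min_genes = 5,
                             mode = c("focal_vs_other", "two_hypotheses")) {
  mode <- match.arg(mode)
  if (is.data.frame(categories)) {
    stopifnot(all(c("gene_id", "category") %in% names(categories)))
    cat_list <- split(as.character(categories$gene_id),
                      as.character(categories$category))
  } else cat_list <- categories
  genes <- names(gene_labels)
  if (is.null(genes)) stop("gene_labels must be a named vector")
  if (mode == "two_hypotheses") {
    if (is.null(alternative))
      stop("mode 'two_hypotheses' needs an alternative hypothesis label")
    genes <- genes[gene_labels %in% c(focal, alternative)]
  }
  in_focal <- gene_labels[genes] == focal
  rows <- list()
  for (cat_id in names(cat_list)) {
    members <- intersect(cat_list[[cat_id]], genes)
    if (length(members) <= min_genes) next
    with_cat <- genes %in% members
    tab <- matrix(c(sum(with_cat & in_focal), sum(with_cat & !in_focal),
                    sum(!with_cat & in_focal), sum(!with_cat & !in_focal)),
                  nrow = 2, byrow = TRUE)
    if (any(expected_counts(tab) == 0)) next
    res <- chisq_2x2(tab)
    rows[[cat_id]] <- data.frame(
      category = cat_id,
      focal_with = tab[1, 1], focal_without = tab[2, 1],
      other_with = tab[1, 2], other_without = tab[2, 2],
      statistic = res$statistic, p_value = res$p_value,
      exp_focal_with = res$expected[1, 1],
      exp_other_with = res$expected[1, 2])
  }
  if (!length(rows)) {
    warning("no category passed the minimum-size filter")
    return(data.frame(category = character(0), focal_with = integer(0),
                      focal_without = integer(0), other_with = integer(0),
                      other_without = integer(0), statistic = numeric(0),
                      p_value = numeric(0), p_adjust_BH = numeric(0),
                      exp_focal_with = numeric(0),
                      exp_other_with = numeric(0)))
  }
  out <- do.call(rbind, rows)
  out$p_adjust_BH <- p.adjust(out$p_value, method = "BH")
  out <- out[order(out$p_value), ]
  rownames(out) <- NULL
  out
}
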