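#' Run the genes-as-characters pipeline end to end
#'
#' Filter gene trees by maximum branch length, build the step-matrix
#' character matrix, search for the most parsimonious species tree,
#' bootstrap over genes, and tally clade-hypothesis support — each stage
#' optional.  All artifacts are written under `outdir` and every parameter
#' and seed is echoed in the returned run report, so a rerun with the same
#' configuration reproduces every numeric output exactly.
#'
#' @param trees gene trees (`multiPhylo`) or a path accepted by
#'   [read_gene_trees()].
#' @param taxa full taxon set (character vector).
#' @param outgroup optional outgroup taxon (needed for rooted tallies).
#' @param stages subset of `c("filter", "build", "search", "bootstrap",
#'   "tally")`.
#' @param threshold long-branch exclusion threshold (default 1.5).
#' @param max_step,decimals step-matrix scaling parameters.
#' @param search list: `method` (`"exhaustive"` or `"heuristic"`),
#'   `n_starts`, `swap`.
#' @param bootstrap_replicates bootstrap replicate count (default 100).
#' @param queries optional list of `clade_query` for the tally stage.
#' @param outdir output directory (default: no files written).
#' @param seed integer seed for search and bootstrap.
#' @return a `run_report` list: input counts, parameters, and stage
#'   outputs.
#' @export
run_pipeline <- function(trees, taxa, outgroup = NULL,
                         stages = c("filter", "build", "search", "tally"),
                         threshold = 1.5, max_step = 10, decimals = 2,
                         search = list(method = "exhaustive"),
                         bootstrap_replicates = 100, queries = NULL,
                         outdir = NULL, seed = 1) {
  stages <- match.arg(stages, c("filter", "build", "search", "bootstrap",
                                "tally"), several.ok = TRUE)
  if (is.character(trees)) trees <- read_gene_trees(trees)
  if (!length(trees)) stop("no gene trees supplied", call. = FALSE)
  bad <- setdiff(unique(unlist(lapply(trees, `[[`, "tip.label"))), taxa)
  if (length(bad))
    stop("gene trees contain taxa outside the taxon set: ",
         paste(bad, collapse = ", "), call. = FALSE)
  if (any(c("bootstrap", "search") %in% stages) && !"build" %in% stages)
    stop("stages 'search'/'bootstrap' require stage 'build'", call. = FALSE)
  if ("tally" %in% stages && is.null(queries))
    stop("stage 'tally' requires clade queries", call. = FALSE)
  if (!is.null(outdir)) dir.create(outdir, showWarnings = FALSE,
                                   recursive = TRUE)

  report <- list(parameters = list(threshold = threshold,
                                   max_step = max_step, decimals = decimals,
                                   search = search,
                                   bootstrap_replicates = bootstrap_replicates,
                                   seed = seed,
                                   version = as.character(utils::packageVersion("genechar"))),
                 genes_read = length(trees))
  analyzed <- trees
  if ("filter" %in% stages) {
    fl <- filter_long_branch(trees, threshold = threshold)
    analyzed <- fl$kept
    report$genes_filtered <- length(fl$removed)
    if (!is.null(outdir)) {
      write.table(fl$report, file.path(outdir, "filter_report.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
      write_gene_trees(fl$kept, file.path(outdir, "kept_trees.nwk"))
    }
  } else report$genes_filtered <- 0L
  report$genes_analyzed <- length(analyzed)

  if ("build" %in% stages) {
    mat <- build_matrix(analyzed, taxa, max_step = max_step,
                        decimals = decimals)
    report$uninformative_characters <-
      sum(vapply(mat$characters, `[[`, logical(1), "uninformative"))
    if (!is.null(outdir))
      export_nexus(mat, file.path(outdir, "characters.nex"),
                   decimals = decimals)
  }

  if ("search" %in% stages) {
    res <- if (identical(search$method, "heuristic"))
      heuristic_search(mat,
                       n_starts = if (is.null(search$n_starts)) 10 else search$n_starts,
                       swap = if (is.null(search$swap)) "SPR" else search$swap,
                       seed = seed)
    else exhaustive_search(mat)
    report$best_score <- res$score
    report$best_trees <- vapply(res$best_trees, ape::write.tree,
                                character(1))
    report$topologies_evaluated <- res$evaluated
    if (!is.null(outdir))
      writeLines(report$best_trees, file.path(outdir, "best_trees.nwk"))
  }

  if ("bootstrap" %in% stages) {
    bs <- bootstrap(mat, replicates = bootstrap_replicates, seed = seed)
    report$bootstrap <- as.list(bs$support)
    if (!is.null(outdir)) {
      df <- data.frame(split = names(bs$support),
                       support_percent = unname(bs$support))
      write.table(df, file.path(outdir, "bootstrap_support.tsv"),
                  sep = "\t", quote = FALSE, row.names = FALSE)
    }
  }

  if ("tally" %in% stages) {
    tl <- tally(analyzed, queries, outgroup = outgroup)
    report$tally <- list(counts = as.list(tl$counts), other = tl$other,
                         percentages = as.list(tl$percentages))
    if (!is.null(outdir)) write_tally(tl, file.path(outdir, "tally.tsv"))
  }

  if (!is.null(outdir))
    jsonlite::write_json(report, file.path(outdir, "run_report.json"),
                         auto_unbox = TRUE, pretty = TRUE, digits = NA)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat("genechar run:", x$genes_read, "genes read,", x$genes_filtered,
      "filtered,", x$genes_analyzed, "analyzed\n")
  if (!is.null(x$best_score))
    cat("  best score:", format(x$best_score), "over",
        x$topologies_evaluated, "topologies;",
        length(x$best_trees), "best tree(s)\n")
  if (!is.null(x$tally)) {
    cat("  tally:\n")
    for (q in names(x$tally$counts))
      cat(sprintf("    %-28s %d (%d%%)\n", q, x$tally$counts[[q]],
                  x$tally$percentages[[q]]))
  }
  invisible(x)
}
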