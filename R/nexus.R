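nexus_symbols <- function(n) {
  alphabet <- c(0:9, LETTERS, letters)
  if (n > length(alphabet))
    stop("more taxa (", n, ") than available state symbols (",
         length(alphabet), ")", call. = FALSE)
  as.character(alphabet[seq_len(n)])
}

#' Export a character matrix as PAUP-compatible NEXUS
#'
#' Writes a CHARACTERS block (one column per gene; each taxon's cell carries
#' the symbol of its own haplotype state, `?` where the taxon is missing
#' from the gene) and an ASSUMPTIONS block with one
#' `USERTYPE ... (STEPMATRIX)` per gene giving the rescaled cost matrix at
#' fixed decimal precision, plus a `TYPESET` applying each usertype to its
#' column.
#'
#' @param matrix a `character_matrix`.
#' @param path optional output file; when given, a JSON sidecar
#'   `<path>.json` maps gene ids to column indices and state symbols to
#'   taxa.
#' @param decimals decimals used when serializing costs (default 2).
#' @return the NEXUS text, invisibly when `path` is given.
#' @export
export_nexus <- function(matrix, path = NULL, decimals = 2) {
  taxa <- matrix$taxa
  syms <- nexus_symbols(length(taxa))
  names(syms) <- taxa
  n_char <- length(matrix$characters)
  usertype_names <- sprintf("step_%04d", seq_len(n_char))

  rows <- vapply(taxa, function(tx) {
    cells <- vapply(matrix$characters, function(ch)
      if (tx %in% ch$states) syms[[tx]] else "?", character(1))
    paste0(format(tx, width = max(nchar(taxa)) + 2), paste(cells, collapse = ""))
  }, character(1))

  usertypes <- vapply(seq_len(n_char), function(i) {
    ch <- matrix$characters[[i]]
    k <- length(ch$states)
    ssym <- unname(syms[ch$states])
    body <- vapply(seq_len(k), function(r) {
      cells <- vapply(seq_len(k), function(c)
        if (r == c) "." else formatC(ch$cost[r, c], format = "f",
                                     digits = decimals), character(1))
      paste("   ", paste(cells, collapse = " "))
    }, character(1))
    paste(c(sprintf("  USERTYPE %s (STEPMATRIX) = %d", usertype_names[i], k),
            paste("   ", paste(ssym, collapse = " ")), body, "  ;"),
          collapse = "\n")
  }, character(1))

  typeset <- paste0("  TYPESET * genesteps = ",
                    paste(sprintf("%s: %d", usertype_names, seq_len(n_char)),
                          collapse = ", "), ";")

  text <- paste(c(
    "#NEXUS",
    "[genes-as-characters step-matrix export]",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", length(taxa)),
    paste0("  TAXLABELS ", paste(taxa, collapse = " "), ";"),
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", n_char),
    sprintf("  FORMAT SYMBOLS=\"%s\" MISSING=?;", paste(syms, collapse = "")),
    "  MATRIX",
    paste0("    ", rows),
    "  ;",
    "END;",
    "BEGIN ASSUMPTIONS;",
    usertypes,
    typeset,
    "END;",
    ""), collapse = "\n")

  if (!is.null(path)) {
    writeLines(text, path)
    sidecar <- list(
      genes = setNames(as.list(seq_len(n_char)),
                       vapply(matrix$characters, `[[`, character(1), "gene_id")),
      symbols = as.list(setNames(taxa, syms)))
    jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                         pretty = TRUE)
    return(invisible(text))
  }
  text
}

#' Re-import a NEXUS step-matrix character matrix
#'
#' Parses the dialect written by [export_nexus()] (TAXA + CHARACTERS +
#' ASSUMPTIONS with STEPMATRIX usertypes) back into a `character_matrix`.
#' Intended for round-trip checks and for re-loading exported analyses;
#' it is not a general NEXUS reader.
#'
#' @param path file, or a character vector of lines via `text`.
#' @param text NEXUS text (overrides `path`).
#' @return a `character_matrix`.
#' @export
read_nexus_charmatrix <- function(path = NULL, text = NULL) {
  lines <- if (!is.null(text)) strsplit(text, "\n", fixed = TRUE)[[1L]]
           else readLines(path, warn = FALSE)
  lines <- trimws(lines)

  grab <- function(pattern) grep(pattern, lines, ignore.case = TRUE)
  taxa <- strsplit(sub(";.*$", "",
                       sub("^\\s*TAXLABELS\\s+", "", lines[grab("^TAXLABELS")],
                           ignore.case = TRUE)), "\\s+")[[1L]]
  syms <- nexus_symbols(length(taxa))
  taxon_of_sym <- setNames(taxa, syms)

  mstart <- grab("^MATRIX$")[1L]
  mrows <- character(0)
  i <- mstart + 1L
  while (lines[i] != ";") { mrows <- c(mrows, lines[i]); i <- i + 1L }
  cells <- do.call(rbind, lapply(mrows, function(r) {
    parts <- strsplit(r, "\\s+")[[1L]]
    c(parts[1L], parts[2L])
  }))
  row_taxa <- cells[, 1L]
  cols <- do.call(rbind, strsplit(cells[, 2L], "", fixed = TRUE))
  rownames(cols) <- row_taxa
  n_char <- ncol(cols)

  # usertypes, in declaration order
  ustarts <- grab("^USERTYPE\\s")
  characters <- vector("list", n_char)
  for (u in seq_along(ustarts)) {
    hdr <- lines[ustarts[u]]
    k <- as.integer(sub(".*=\\s*(\\d+)\\s*$", "\\1", hdr))
    ssym <- strsplit(lines[ustarts[u] + 1L], "\\s+")[[1L]]
    states <- unname(taxon_of_sym[ssym])
    cost <- matrix(0, k, k, dimnames = list(states, states))
    for (r in seq_len(k)) {
      vals <- strsplit(lines[ustarts[u] + 1L + r], "\\s+")[[1L]]
      cost[r, ] <- vapply(vals, function(v)
        if (v == ".") 0 else as.numeric(v), numeric(1))
    }
    characters[[u]] <- structure(
      list(gene_id = sub("^USERTYPE\\s+(\\S+).*$", "\\1", hdr),
           states = states, cost = cost,
           missing = setdiff(taxa, states),
           uninformative = max(cost) == 0),
      class = "gene_character")
  }
  structure(list(taxa = taxa, characters = characters,
                 weights = rep(1, n_char)),
            class = "character_matrix")
}
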