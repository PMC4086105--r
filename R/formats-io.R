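# Readers and writers for the external formats the pipeline touches:
# HMMER3 per-domain tabular output (domtblout), one-taxon-per-line species
# universe files, gene x column TSV matrices (binary or real), GMT gene-set
# collections, and ranked-result TSVs.  Downstream modules consume only the
# in-memory objects produced here.

DOMTBLOUT_MIN_COLS <- 23L

#' Read HMMER3 per-domain tabular output
#'
#' Parses the \code{--domtblout} dialect of HMMER3: \code{#}-prefixed comment
#' lines are skipped and each data line holds at least 23 whitespace-separated
#' columns, one row per matched domain.  The query name (column 4) is taken as
#' the gene identifier; the target sequence name (column 1) is resolved to a
#' taxon either through an explicit \code{taxon_map} or, by default, by taking
#' a \code{|}-delimited token of the target name.  The full-sequence E-value
#' (column 7) and the per-domain conditional E-value (column 12) are retained;
#' only the latter feeds the presence rule.  One row is returned per domain
#' line; best-domain aggregation happens in \code{\link{build_profiles}}.
#'
#' @param path path to a domtblout file.
#' @param taxon_map optional named character vector mapping target sequence
#'   names to taxon identifiers; overrides the token rule.
#' @param taxon_token integer: which \code{|}-delimited token of the target
#'   name is the taxon when no \code{taxon_map} is given (default 2, matching
#'   \code{db|taxon|protein}-style headers).
#' @param policy \code{"skip"} (default) collects malformed or unresolvable
#'   lines as diagnostics and drops them; \code{"strict"} makes them fatal.
#' @return a data frame with columns \code{query_gene}, \code{target_species},
#'   \code{domain_evalue}, \code{full_evalue} and attribute
#'   \code{"diagnostics"}: a data frame of (line, message) for every skipped
#'   data line.
#' @seealso \code{\link{write_domtblout}}, \code{\link{build_profiles}}
#' @export
read_domtblout <- function(path, taxon_map = NULL, taxon_token = 2L,
                           policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!file.exists(path)) stopf("domtblout file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  is_data <- !grepl("^\\s*(#|$)", lines)
  idx <- which(is_data)

  hits <- vector("list", length(idx))
  diags <- list()
  bad <- function(i, msg) {
    if (policy == "strict") stopf("%s (line %d of %s)", msg, i, path)
    diags[[length(diags) + 1L]] <<- data.frame(line = i, message = msg,
                                               stringsAsFactors = FALSE)
  }

  for (j in seq_along(idx)) {
    i <- idx[j]
    tok <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(tok) < DOMTBLOUT_MIN_COLS) {
      bad(i, sprintf("expected >= %d columns, found %d",
                     DOMTBLOUT_MIN_COLS, length(tok)))
      next
    }
    full_e <- suppressWarnings(as.numeric(tok[7L]))
    dom_e <- suppressWarnings(as.numeric(tok[12L]))
    if (is.na(full_e) || is.na(dom_e) || full_e <= 0 || dom_e <= 0) {
      bad(i, sprintf("unparseable or non-positive E-value fields '%s'/'%s'",
                     tok[7L], tok[12L]))
      next
    }
    target <- tok[1L]
    taxon <- if (!is.null(taxon_map)) {
      unname(taxon_map[target])
    } else {
      parts <- strsplit(target, "|", fixed = TRUE)[[1L]]
      if (length(parts) >= taxon_token) parts[taxon_token] else NA_character_
    }
    if (is.na(taxon) || !nzchar(taxon)) {
      bad(i, sprintf("no resolvable taxon for target '%s'", target))
      next
    }
    hits[[j]] <- data.frame(query_gene = tok[4L], target_species = taxon,
                            domain_evalue = dom_e, full_evalue = full_e,
                            stringsAsFactors = FALSE)
  }

  out <- do.call(rbind, hits[!vapply(hits, is.null, logical(1L))])
  if (is.null(out))
    out <- data.frame(query_gene = character(), target_species = character(),
                      domain_evalue = numeric(), full_evalue = numeric(),
                      stringsAsFactors = FALSE)
  rownames(out) <- NULL
  attr(out, "diagnostics") <- if (length(diags)) do.call(rbind, diags) else
    data.frame(line = integer(), message = character(), stringsAsFactors = FALSE)
  out
}

#' Write homology hits as HMMER3 domtblout
#'
#' Serializes a hit table in the 23-column per-domain dialect so it can be
#' re-read by \code{\link{read_domtblout}}.  Target sequence names are either
#' taken from a \code{target_name} column or synthesized as
#' \code{sp|<taxon>|<gene>} (compatible with the default token rule).
#'
#' @param hits data frame as returned by \code{\link{read_domtblout}} or
#'   \code{\link{simulate_hits}}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_domtblout <- function(hits, path) {
  target <- hits$target_name %||%
    sprintf("sp|%s|%s", hits$target_species, hits$query_gene)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# target name        accession   tlen query name           accession   qlen   E-value  score  bias   #  of  c-Evalue  i-Evalue  score  bias  from    to  from    to  from    to  acc description of target",
               "#------------------- ---------- ----- -------------------- ---------- ----- --------- ------ ----- --- --- --------- --------- ------ ----- ----- ----- ----- ----- ----- ----- ---- ---------------------"),
             con)
  if (nrow(hits))
    writeLines(sprintf(
      "%s - 300 %s - 300 %.10g 100.0 0.1 1 1 %.10g %.10g 95.0 0.1 1 100 1 100 1 100 0.95 -",
      target, hits$query_gene, hits$full_evalue, hits$domain_evalue,
      hits$full_evalue), con)
  invisible(path)
}

#' Read a species universe file
#'
#' One taxon identifier per line; blank lines and \code{#} comments are
#' ignored.  The file order defines the coordinate system of every phyletic
#' profile built against this universe and is immutable thereafter.
#'
#' @param path path to the universe file.
#' @return character vector of taxa in file order.
#' @export
read_species_universe <- function(path) {
  if (!file.exists(path)) stopf("species universe file not found: %s", path)
  lines <- trimws(readLines(path, warn = FALSE))
  keep <- !grepl("^(#|$)", lines)
  taxa <- lines[keep]
  lineno <- which(keep)
  if (anyDuplicated(taxa)) {
    d <- taxa[duplicated(taxa)][1L]
    at <- lineno[taxa == d]
    stopf("duplicate taxon '%s' at lines %s of %s", d,
          paste(at, collapse = " and "), path)
  }
  if (!length(taxa)) stopf("species universe is empty: %s", path)
  taxa
}

#' @rdname read_species_universe
#' @param taxa character vector of taxon identifiers.
#' @export
write_species_universe <- function(taxa, path) {
  writeLines(taxa, path)
  invisible(path)
}

#' Read a labeled gene-by-column TSV matrix
#'
#' First row holds column labels, first column holds gene identifiers.  With
#' \code{kind = "binary"} every cell must be 0 or 1 and missing cells are
#' fatal; with \code{kind = "real"} missing cells are handled per
#' \code{missing}: \code{"fail"} (default) or \code{"drop"} (drop the gene row
#' with a warning).
#'
#' @param path path to a TSV file.
#' @param kind \code{"real"} or \code{"binary"}.
#' @param missing policy for missing cells under \code{kind = "real"}.
#' @return numeric matrix with gene rownames and column labels.
#' @export
read_matrix_tsv <- function(path, kind = c("real", "binary"),
                            missing = c("fail", "drop")) {
  kind <- match.arg(kind)
  missing <- match.arg(missing)
  if (!file.exists(path)) stopf("matrix file not found: %s", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stopf("matrix %s needs a gene column plus >= 1 data column", path)
  genes <- as.character(df[[1L]])
  if (anyDuplicated(genes))
    stopf("duplicate gene row '%s' in %s", genes[duplicated(genes)][1L], path)
  m <- as.matrix(df[, -1L, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- genes
  if (kind == "binary") {
    off <- which(is.na(m) | !(m %in% c(0, 1)))
    if (length(off)) {
      i <- arrayInd(off[1L], dim(m))
      stopf("non-binary cell at (%s, %s) in %s", genes[i[1L]],
            colnames(m)[i[2L]], path)
    }
    storage.mode(m) <- "integer"
  } else if (anyNA(m)) {
    if (missing == "fail") {
      i <- arrayInd(which(is.na(m))[1L], dim(m))
      stopf("missing cell at (%s, %s) in %s", genes[i[1L]],
            colnames(m)[i[2L]], path)
    }
    drop <- rowSums(is.na(m)) > 0
    warnf("dropping %d gene row(s) with missing cells from %s", sum(drop), path)
    m <- m[!drop, , drop = FALSE]
  }
  m
}

#' @rdname read_matrix_tsv
#' @param x matrix with rownames (genes) and colnames to serialize.
#' @param label header of the gene-identifier column (default \code{"gene"}).
#' @export
write_matrix_tsv <- function(x, path, label = "gene") {
  df <- data.frame(rownames(x), x, check.names = FALSE,
                   stringsAsFactors = FALSE)
  colnames(df) <- c(label, colnames(x))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, \code{term TAB description TAB gene TAB
#' gene ...}.  Duplicate genes within a line are deduplicated.  Serves as the
#' local annotation source for the split-half evaluation (in place of a
#' remote functional-annotation service).
#'
#' @param path path to a GMT file.
#' @return named list of character vectors (term -> member genes) with
#'   attribute \code{"description"}, a named character vector per term.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  desc <- character()
  for (i in seq_along(lines)) {
    tok <- strsplit(lines[i], "\t", fixed = TRUE)[[1L]]
    if (length(tok) < 3L)
      stopf("GMT line %d needs term, description and >= 1 gene", i)
    genes <- unique(tok[-(1:2)])
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("GMT line %d has an empty gene set", i)
    sets[[tok[1L]]] <- genes
    desc[tok[1L]] <- tok[2L]
  }
  attr(sets, "description") <- desc
  sets
}

#' @rdname read_gmt
#' @param sets named list of character vectors, optionally with a
#'   \code{"description"} attribute.
#' @export
write_gmt <- function(sets, path) {
  desc <- attr(sets, "description") %||%
    stats::setNames(rep("", length(sets)), names(sets))
  lines <- vapply(names(sets), function(term) {
    paste(c(term, desc[[term]] %||% "", sets[[term]]), collapse = "\t")
  }, character(1L))
  writeLines(lines, path)
  invisible(path)
}

#' Write and read ranked candidate lists
#'
#' The TSV carries \code{rank}, \code{gene}, \code{hamming_distance},
#' \code{pearson_r} with 1-based ranks in list order; floating values are
#' printed with 6 decimals.  \code{NA} correlations (evolution-only rankings
#' or sentinel values) round-trip as \code{NA}.
#'
#' @param results a ranking data frame as returned by
#'   \code{\link{rank_candidates}}.
#' @param path output (or input) TSV path.
#' @return \code{path} invisibly for the writer; a data frame with columns
#'   \code{rank}, \code{gene}, \code{hamming}, \code{r} for the reader.
#' @export
write_ranked_results <- function(results, path) {
  df <- data.frame(rank = results$rank, gene = results$gene,
                   hamming_distance = results$hamming,
                   pearson_r = ifelse(is.na(results$r), NA,
                                      sprintf("%.6f", results$r)),
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_results
#' @export
read_ranked_results <- function(path) {
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          check.names = FALSE, stringsAsFactors = FALSE)
  data.frame(rank = as.integer(df$rank), gene = as.character(df$gene),
             hamming = as.integer(df$hamming_distance),
             r = as.numeric(df$pearson_r), stringsAsFactors = FALSE)
}
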