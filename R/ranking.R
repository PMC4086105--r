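# Candidate ranking: the two-key deterministic order at the heart of the
# method.  Candidates are sorted by Hamming distance ascending (co-evolution
# first), then by Pearson correlation descending within equal distance
# (co-expression refines), with exact ties broken by gene identifier so the
# order is total and reproducible.  Candidates whose correlation is below
# min_corr are excluded BEFORE truncation; note that negative correlations
# are below 0.2, so anti-correlated genes are discarded by design.

#' Ranking configuration
#'
#' Bundles the tunables of \code{\link{rank_candidates}}.  The defaults are
#' the method's published operating point: correlation filter 0.2, list
#' length 125.
#'
#' @param min_corr minimum Pearson correlation; candidates with \code{r <
#'   min_corr} are excluded (default 0.2).
#' @param top_n maximum list length (default 125).
#' @param missing_expression_policy \code{"exclude"} (default) drops
#'   candidates absent from the expression matrix or with undefined
#'   correlation; \code{"keep_with_sentinel"} retains them with \code{NA}
#'   correlation, sorted after all real-correlation candidates of equal
#'   Hamming distance.
#' @return a \code{ranking_config} list.
#' @export
ranking_config <- function(min_corr = 0.2, top_n = 125,
                           missing_expression_policy = c("exclude",
                                                         "keep_with_sentinel")) {
  structure(list(
    min_corr = assert_prob(min_corr, "min_corr"),
    top_n = assert_count(top_n, "top_n"),
    missing_expression_policy = match.arg(missing_expression_policy)
  ), class = "ranking_config")
}

new_ranking <- function(gene, hamming, r, query, evolution_only, config = NULL) {
  out <- data.frame(gene = as.character(gene), hamming = as.integer(hamming),
                    r = as.numeric(r),
                    rank = seq_along(gene) + 0L,  # 1-based list order
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  structure(out, query = query, evolution_only = evolution_only,
            config = config, class = c("evocor_ranking", "data.frame"))
}

#' Rank candidate genes by co-evolution then co-expression
#'
#' Applies the method's deterministic filter-and-rank scheme: (1) drop
#' candidates with \code{r < min_corr}, with undefined \code{r}, or (under
#' the default \code{"exclude"} policy) with no expression record; (2) sort
#' by Hamming distance ascending; (3) within equal distance, by Pearson
#' correlation descending; (4) break exact (distance, correlation) ties by
#' gene identifier ascending; (5) truncate to \code{top_n}; (6) assign
#' 1-based ranks.
#'
#' @param query_gene the query gene identifier (appears in neither input).
#' @param distances data frame (\code{gene}, \code{hamming}) from
#'   \code{\link{distances_to_query}}.
#' @param correlations data frame (\code{gene}, \code{r}) from
#'   \code{\link{correlations_to_query}}.
#' @param config a \code{\link{ranking_config}}.
#' @return an \code{evocor_ranking} data frame with columns \code{gene},
#'   \code{hamming}, \code{r}, \code{rank}.
#' @examples
#' d <- data.frame(gene = c("A", "B", "C", "D"), hamming = c(2, 1, 1, 0))
#' r <- data.frame(gene = c("A", "B", "C", "D"), r = c(0.9, 0.3, 0.8, 0.1))
#' rank_candidates("Q", d, r)  # C, B, A; D fails the 0.2 filter
#' @export
rank_candidates <- function(query_gene, distances, correlations,
                            config = ranking_config()) {
  stopifnot(inherits(config, "ranking_config"))
  if (query_gene %in% distances$gene || query_gene %in% correlations$gene)
    stopf("query gene '%s' must not appear among its own candidates", query_gene)
  if (anyDuplicated(distances$gene) || anyDuplicated(correlations$gene))
    stopf("duplicate candidate genes in distances or correlations")

  r <- correlations$r[match(distances$gene, correlations$gene)]
  keep_sentinel <- config$missing_expression_policy == "keep_with_sentinel"
  keep <- if (keep_sentinel) is.na(r) | r >= config$min_corr
          else !is.na(r) & r >= config$min_corr
  gene <- distances$gene[keep]
  h <- distances$hamming[keep]
  r <- r[keep]

  # NA correlations sort after all real values of equal hamming
  ord <- order(h, ifelse(is.na(r), Inf, -r), gene)
  ord <- ord[seq_len(min(length(ord), config$top_n))]
  new_ranking(gene[ord], h[ord], r[ord], query = query_gene,
              evolution_only = FALSE, config = config)
}

#' Rank candidates by evolutionary history alone
#'
#' Same total order without the co-expression key: Hamming distance
#' ascending, ties broken by gene identifier.  No correlation filter is
#' applied and the correlation column carries the \code{NA} sentinel.
#'
#' @param query_gene the query gene identifier.
#' @param distances data frame (\code{gene}, \code{hamming}).
#' @param top_n maximum list length (default 125).
#' @return an \code{evocor_ranking} data frame.
#' @export
rank_candidates_evolution_only <- function(query_gene, distances, top_n = 125) {
  top_n <- assert_count(top_n, "top_n")
  if (query_gene %in% distances$gene)
    stopf("query gene '%s' must not appear among its own candidates", query_gene)
  ord <- order(distances$hamming, distances$gene)
  ord <- ord[seq_len(min(length(ord), top_n))]
  new_ranking(distances$gene[ord], distances$hamming[ord], NA_real_,
              query = query_gene, evolution_only = TRUE)
}

#' @export
print.evocor_ranking <- function(x, n = 10L, ...) {
  mode <- if (isTRUE(attr(x, "evolution_only"))) "evolution-only"
          else "evolution + expression"
  cat(sprintf("ranked candidates for query '%s' (%s): %d gene(s)\n",
              attr(x, "query"), mode, nrow(x)))
  if (nrow(x)) print.data.frame(utils::head(x, n), row.names = FALSE, ...)
  if (nrow(x) > n) cat(sprintf("... and %d more\n", nrow(x) - n))
  invisible(x)
}

#' Rank candidates for a query straight from profiles and expression
#'
#' Convenience wrapper wiring \code{\link{distances_to_query}},
#' \code{\link{correlations_to_query}} and \code{\link{rank_candidates}}.
#' With \code{evolution_only = TRUE} (or \code{expression = NULL}) the
#' expression stage is skipped entirely.
#'
#' @param query_gene query gene identifier.
#' @param profiles a \code{phyletic_profiles} object.
#' @param expression an \code{expression_matrix}, or \code{NULL}.
#' @param config a \code{\link{ranking_config}}.
#' @param evolution_only rank by profile distance alone?
#' @param include_empty_profiles see \code{\link{distances_to_query}}.
#' @return an \code{evocor_ranking} data frame.
#' @export
evocor_rank <- function(query_gene, profiles, expression = NULL,
                        config = ranking_config(), evolution_only = FALSE,
                        include_empty_profiles = FALSE) {
  d <- distances_to_query(query_gene, profiles, include_empty_profiles)
  if (evolution_only || is.null(expression))
    return(rank_candidates_evolution_only(query_gene, d, config$top_n))
  co <- correlations_to_query(query_gene, expression)
  rank_candidates(query_gene, d, co, config)
}
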