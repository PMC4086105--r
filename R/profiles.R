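# Phyletic profiles: binary presence/absence vectors over a fixed species
# universe, built from profile-HMM homology hits, and Hamming distances
# between them.  The presence rule is a strict E-value cutoff applied to the
# best single-domain conditional E-value of any hit for a (gene, species)
# pair; the default cutoff is 1e-7, and a hit at exactly the cutoff does NOT
# call presence (strict '<').  E-value ties at the cutoff occur in practice,
# so the strictness matters.

#' Build binary phyletic profiles from homology hits
#'
#' Each gene receives a presence/absence vector over the species universe:
#' cell (g, s) is 1 iff some hit of gene g in species s has a per-domain
#' conditional E-value strictly below \code{threshold}.  Hits are OR-combined,
#' so multiple domain rows or paralogous hits cannot un-set a bit.  Genes
#' listed in \code{genes} but absent from the hit table receive all-zero
#' rows rather than being dropped: an all-zero profile is informative and
#' silent dropping would distort downstream rankings.
#'
#' @param hits data frame with columns \code{query_gene},
#'   \code{target_species}, \code{domain_evalue} (see
#'   \code{\link{read_domtblout}}).
#' @param universe character vector of taxa; defines the column order.
#' @param threshold positive E-value cutoff; presence requires
#'   \code{domain_evalue < threshold} (strict).
#' @param genes optional gene roster fixing row set and order; defaults to
#'   the sorted unique query genes of \code{hits}.
#' @param policy \code{"skip"} drops hits whose species is outside the
#'   universe (with a warning); \code{"strict"} makes them fatal.
#' @return a \code{phyletic_profiles} object: an integer 0/1 matrix
#'   (genes x species) with attributes \code{universe} and
#'   \code{evalue_threshold}.
#' @examples
#' hits <- data.frame(query_gene = "g1", target_species = "sp2",
#'                    domain_evalue = 1e-9, full_evalue = 1e-9)
#' build_profiles(hits, universe = c("sp1", "sp2", "sp3"))
#' @export
build_profiles <- function(hits, universe, threshold = 1e-7, genes = NULL,
                           policy = c("skip", "strict")) {
  policy <- match.arg(policy)
  if (!is.numeric(threshold) || length(threshold) != 1L || threshold <= 0)
    stopf("threshold must be a single positive E-value")
  if (anyDuplicated(universe)) stopf("species universe contains duplicates")
  if (!length(universe)) stopf("species universe is empty")

  outside <- setdiff(unique(hits$target_species), universe)
  if (length(outside)) {
    if (policy == "strict")
      stopf("hit species outside the universe: %s",
            paste(outside, collapse = ", "))
    warnf("skipping %d hit(s) in %d species outside the universe",
          sum(hits$target_species %in% outside), length(outside))
    hits <- hits[hits$target_species %in% universe, , drop = FALSE]
  }

  if (is.null(genes)) genes <- sort(unique(hits$query_gene))
  else if (anyDuplicated(genes)) stopf("gene roster contains duplicates")
  unknown <- setdiff(unique(hits$query_gene), genes)
  if (length(unknown))
    stopf("hits reference genes outside the supplied roster: %s",
          paste(utils::head(unknown, 5L), collapse = ", "))

  bits <- matrix(0L, nrow = length(genes), ncol = length(universe),
                 dimnames = list(genes, universe))
  pass <- hits$domain_evalue < threshold  # strict: E == threshold is absent
  if (any(pass))
    bits[cbind(match(hits$query_gene[pass], genes),
               match(hits$target_species[pass], universe))] <- 1L
  new_phyletic_profiles(bits, universe, threshold)
}

new_phyletic_profiles <- function(bits, universe, threshold) {
  stopifnot(identical(colnames(bits), as.character(universe)))
  structure(bits, universe = as.character(universe),
            evalue_threshold = threshold,
            class = c("phyletic_profiles", class(bits)))
}

#' Coerce a binary matrix to a phyletic-profile object
#'
#' Wraps a pre-built gene x species 0/1 matrix (e.g. from
#' \code{\link{read_matrix_tsv}}) as a \code{phyletic_profiles} object.
#'
#' @param bits 0/1 matrix with gene rownames and species colnames.
#' @param evalue_threshold the presence cutoff that produced the matrix, for
#'   provenance (default 1e-7).
#' @return a \code{phyletic_profiles} object.
#' @export
as_phyletic_profiles <- function(bits, evalue_threshold = 1e-7) {
  if (is.null(rownames(bits)) || is.null(colnames(bits)))
    stopf("profile matrix needs gene rownames and species colnames")
  if (!all(bits %in% c(0, 1))) stopf("profile matrix cells must be 0 or 1")
  storage.mode(bits) <- "integer"
  new_phyletic_profiles(bits, colnames(bits), evalue_threshold)
}

#' @export
print.phyletic_profiles <- function(x, ...) {
  cat(sprintf("phyletic profiles: %d genes x %d species (presence: E < %g)\n",
              nrow(x), ncol(x), attr(x, "evalue_threshold")))
  cat(sprintf("mean presence density %.3f\n", mean(x)))
  invisible(x)
}

#' Hamming distance between two binary profiles
#'
#' Number of coordinates at which two equal-length 0/1 vectors differ; the
#' co-evolution dissimilarity between two genes.
#'
#' @param a,b binary vectors of equal length.
#' @return non-negative integer.
#' @examples
#' hamming_distance(c(1, 0, 1, 1), c(1, 1, 0, 1))  # 2
#' @export
hamming_distance <- function(a, b) {
  if (length(a) != length(b))
    stopf("profile length mismatch: %d vs %d", length(a), length(b))
  sum(a != b)
}

#' Hamming distances from one query gene to all other genes
#'
#' @param query_gene gene identifier; must be a row of \code{profiles}.
#' @param profiles a \code{phyletic_profiles} object.
#' @param include_empty_profiles keep candidates whose profile is all-zero?
#'   Default \code{FALSE}: an all-zero profile has distance equal to the
#'   query's presence count yet carries no co-evolution signal, so such genes
#'   are excluded from candidate pools unless requested.
#' @return data frame with columns \code{gene}, \code{hamming}, one row per
#'   non-query gene (the self-pair is excluded).
#' @export
distances_to_query <- function(query_gene, profiles,
                               include_empty_profiles = FALSE) {
  assert_flag(include_empty_profiles, "include_empty_profiles")
  if (!query_gene %in% rownames(profiles))
    stopf("query gene '%s' is not a row of the profile matrix", query_gene)
  q <- profiles[query_gene, ]
  m <- profiles[rownames(profiles) != query_gene, , drop = FALSE]
  if (!include_empty_profiles) m <- m[rowSums(m) > 0L, , drop = FALSE]
  # |a xor b| = |a| + |b| - 2 a.b for binary vectors
  d <- rowSums(m) + sum(q) - 2 * as.vector(m %*% q)
  data.frame(gene = rownames(m), hamming = as.integer(d),
             stringsAsFactors = FALSE)
}

#' All-pairs Hamming distance matrix
#'
#' Computes every pairwise profile distance at once through the binary
#' identity \eqn{d(a,b) = |a| + |b| - 2\,a\cdot b}.
#'
#' @param profiles a \code{phyletic_profiles} object (or 0/1 matrix).
#' @return symmetric integer matrix of gene-by-gene Hamming distances.
#' @export
hamming_matrix <- function(profiles) {
  m <- unclass(profiles)
  rs <- rowSums(m)
  d <- outer(rs, rs, "+") - 2 * tcrossprod(m)
  storage.mode(d) <- "integer"
  d
}
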