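# Evaluation machinery: does the ranker return functionally coherent lists?
# Each result list is randomly split in half; the annotation terms covered by
# the two halves are compared (Jaccard by default).  Coherent lists put
# co-annotated genes in both halves, so their term sets overlap more than
# those of randomized control lists.  The two overlap-fraction distributions
# are compared with a two-sided Kolmogorov-Smirnov test; the
# evolution-only-vs-combined comparison uses a Wilcoxon rank-sum test on
# per-query scores.
#
# The KS p-value is the asymptotic two-sided tail with effective sample size
# n_a n_b / (n_a + n_b); the Wilcoxon statistic is the rank sum of the FIRST
# sample under mid-ranks (not the shifted Mann-Whitney U) with a
# tie-corrected normal approximation.  Both conventions are recorded in the
# returned objects so the numbers are interpretable.

# term lookup index: gene -> character vector of terms
gene_term_index <- function(annotations) {
  genes <- unlist(annotations, use.names = FALSE)
  terms <- rep(names(annotations), lengths(annotations))
  split(terms, genes)
}

terms_of <- function(genes, index) {
  unique(unlist(index[genes], use.names = FALSE))
}

#' Split-half annotation-term overlap of one result list
#'
#' Randomly partitions a gene list into halves of sizes ceiling(n/2) and
#' floor(n/2), collects the union of annotation terms over each half, and
#' returns their overlap: Jaccard \eqn{|T_1 \cap T_2| / |T_1 \cup T_2|} by
#' default, or intersection-over-smaller-set.  Genes without annotations
#' contribute no terms; if both term sets are empty the overlap is 0.
#'
#' @param result_genes non-empty character vector of genes (one result list).
#' @param annotations a gene-set collection (named list term -> genes, see
#'   \code{\link{read_gmt}}).
#' @param seed integer seed for the split, or \code{NULL} to use the current
#'   RNG stream.
#' @param statistic \code{"jaccard"} (default) or \code{"over_smaller"}.
#' @param n_splits average the overlap over this many independent splits
#'   (default 1, a single split).
#' @return overlap fraction in [0, 1].
#' @export
split_half_overlap <- function(result_genes, annotations, seed = NULL,
                               statistic = c("jaccard", "over_smaller"),
                               n_splits = 1L) {
  statistic <- match.arg(statistic)
  n_splits <- assert_count(n_splits, "n_splits")
  if (!length(result_genes)) stopf("result gene list is empty")
  index <- if (is.list(annotations) && !is.null(attr(annotations, "gene_index")))
    attr(annotations, "gene_index") else gene_term_index(annotations)
  with_seed(seed, {
    mean(vapply(seq_len(n_splits), function(i) {
      split_half_overlap_once(result_genes, index, statistic)
    }, numeric(1L)))
  })
}

split_half_overlap_once <- function(result_genes, index, statistic) {
  n <- length(result_genes)
  shuffled <- sample(result_genes)
  half1 <- shuffled[seq_len(ceiling(n / 2))]
  half2 <- shuffled[-seq_len(ceiling(n / 2))]
  t1 <- terms_of(half1, index)
  t2 <- terms_of(half2, index)
  both <- length(intersect(t1, t2))
  denom <- switch(statistic,
                  jaccard = length(union(t1, t2)),
                  over_smaller = min(length(t1), length(t2)))
  if (denom == 0L) 0 else both / denom
}

#' Randomized control result sets
#'
#' Pools the genes of every result set, shuffles the pool with a seeded
#' generator, and re-deals it into sets of the original sizes.  The global
#' gene multiset is conserved, so any structure within individual sets is
#' destroyed while the marginal gene composition is kept.
#'
#' @param result_sets named list of character vectors (query -> result genes).
#' @param seed integer seed, or \code{NULL} for the current RNG stream.
#' @return named list of the same shape with shuffled contents.
#' @export
randomized_control <- function(result_sets, seed = NULL) {
  sizes <- lengths(result_sets)
  pool <- unlist(result_sets, use.names = FALSE)
  with_seed(seed, {
    shuffled <- sample(pool)
    out <- split(shuffled, factor(rep(seq_along(sizes), sizes),
                                  levels = seq_along(sizes)))
    names(out) <- names(result_sets)
    out
  })
}

#' Two-sample two-sided Kolmogorov-Smirnov test
#'
#' D is the supremum absolute difference of the two empirical CDFs over the
#' pooled support; the p-value is the asymptotic two-sided KS tail
#' \eqn{2 \sum_{k\ge1} (-1)^{k-1} e^{-2 k^2 n_e D^2}} evaluated at effective
#' size \eqn{n_e = n_a n_b / (n_a + n_b)}.
#'
#' @param a,b non-empty numeric samples.
#' @return list with elements \code{D}, \code{p}, \code{n_effective} and
#'   \code{method}.
#' @export
ks_two_sample <- function(a, b) {
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  support <- sort(unique(c(a, b)))
  D <- max(abs(stats::ecdf(a)(support) - stats::ecdf(b)(support)))
  ne <- length(a) * length(b) / (length(a) + length(b))
  p <- ks_asymptotic_p(D, ne)
  list(D = D, p = p, n_effective = ne,
       method = "two-sided two-sample KS, asymptotic p at effective n")
}

ks_asymptotic_p <- function(D, ne) {
  if (D <= 0) return(1)
  lambda2 <- ne * D^2
  k <- seq_len(101L)
  p <- 2 * sum((-1)^(k - 1) * exp(-2 * k^2 * lambda2))
  min(1, max(0, p))
}

#' Wilcoxon rank-sum test (rank-sum convention, tie-corrected normal p)
#'
#' W is the sum of pooled mid-ranks of the FIRST sample -- the classical
#' rank-sum statistic, not the shifted Mann-Whitney U reported by
#' \code{stats::wilcox.test} (they differ by \eqn{n_a(n_a+1)/2}).  The
#' p-value uses the normal approximation with the usual tie correction of
#' the rank variance and no continuity correction.
#'
#' @param a,b non-empty numeric samples.
#' @param alternative \code{"two.sided"} (default), \code{"greater"} (first
#'   sample stochastically larger) or \code{"less"}.
#' @return list with elements \code{W}, \code{p}, \code{z} and \code{method}.
#' @export
wilcoxon_rank_sum <- function(a, b,
                              alternative = c("two.sided", "greater", "less")) {
  alternative <- match.arg(alternative)
  if (!length(a) || !length(b)) stopf("both samples must be non-empty")
  na <- length(a); nb <- length(b); N <- na + nb
  rk <- rank(c(a, b))  # mid-ranks for ties
  W <- sum(rk[seq_len(na)])
  mu <- na * (N + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties)
  v <- na * nb / 12 * ((N + 1) - tie_term / (N * (N - 1)))
  z <- if (v > 0) (W - mu) / sqrt(v) else 0
  p <- switch(alternative,
              two.sided = 2 * stats::pnorm(-abs(z)),
              greater = stats::pnorm(z, lower.tail = FALSE),
              less = stats::pnorm(z))
  list(W = W, p = min(1, p), z = z,
       method = "rank-sum W of first sample, mid-ranks, tie-corrected normal approximation")
}

#' Evaluate result sets by split-half overlap against a randomized control
#'
#' The full protocol: compute the split-half term-overlap fraction for every
#' result set, build randomized control sets (\code{\link{randomized_control}})
#' and score them the same way, then compare the two fraction distributions
#' with \code{\link{ks_two_sample}}.  All randomness (control shuffle, every
#' split) flows from the single \code{seed}, so runs are bit-reproducible.
#'
#' @param result_sets named list (query -> character vector of result genes).
#' @param annotations gene-set collection (named list term -> genes).
#' @param seed integer master seed.
#' @param statistic,n_splits passed to \code{\link{split_half_overlap}}.
#' @return an \code{evocor_evaluation} object: list with
#'   \code{method_fractions}, \code{control_fractions} (data frames with
#'   \code{query}, \code{fraction}), \code{ks_D}, \code{ks_p},
#'   \code{n_queries}, \code{statistic}.
#' @export
evaluate_method <- function(result_sets, annotations, seed = 1L,
                            statistic = c("jaccard", "over_smaller"),
                            n_splits = 1L) {
  statistic <- match.arg(statistic)
  if (!length(result_sets)) stopf("no result sets supplied")
  if (is.null(names(result_sets)))
    names(result_sets) <- sprintf("query%d", seq_along(result_sets))
  index <- gene_term_index(annotations)
  ann <- structure(annotations, gene_index = index)
  with_seed(seed, {
    control <- randomized_control(result_sets, seed = NULL)
    mf <- vapply(result_sets, split_half_overlap, numeric(1L),
                 annotations = ann, seed = NULL, statistic = statistic,
                 n_splits = n_splits)
    cf <- vapply(control, split_half_overlap, numeric(1L),
                 annotations = ann, seed = NULL, statistic = statistic,
                 n_splits = n_splits)
    ks <- ks_two_sample(mf, cf)
    structure(list(
      method_fractions = data.frame(query = names(result_sets), fraction = mf,
                                    row.names = NULL, stringsAsFactors = FALSE),
      control_fractions = data.frame(query = names(control), fraction = cf,
                                     row.names = NULL, stringsAsFactors = FALSE),
      ks_D = ks$D, ks_p = ks$p, n_queries = length(result_sets),
      statistic = statistic, seed = seed
    ), class = "evocor_evaluation")
  })
}

#' @export
print.evocor_evaluation <- function(x, ...) {
  cat(sprintf("split-half term-overlap evaluation (%s statistic, %d queries)\n",
              x$statistic, x$n_queries))
  cat(sprintf("  mean overlap: method %.4f, randomized control %.4f\n",
              mean(x$method_fractions$fraction),
              mean(x$control_fractions$fraction)))
  cat(sprintf("  two-sided KS: D = %.4f, p = %.4g\n", x$ks_D, x$ks_p))
  invisible(x)
}

#' ECDF comparison plot of method vs control overlap fractions
#'
#' @param x an \code{evocor_evaluation} object.
#' @param ... further arguments passed to \code{plot}.
#' @export
plot.evocor_evaluation <- function(x, ...) {
  mf <- x$method_fractions$fraction
  cf <- x$control_fractions$fraction
  plot(stats::ecdf(cf), col = "firebrick", verticals = TRUE, pch = NA,
       main = "Split-half term overlap", xlab = "overlap fraction",
       ylab = "ECDF", xlim = c(0, 1), ...)
  graphics::lines(stats::ecdf(mf), col = "steelblue", verticals = TRUE, pch = NA)
  graphics::legend("bottomright", c("method", "randomized control"),
                   col = c("steelblue", "firebrick"), lty = 1, bty = "n")
  invisible(x)
}

#' Compare evolution-only vs combined rankings by per-query overlap
#'
#' For each query gene, ranks candidates under both modes (profile distance
#' alone, and distance refined by expression correlation), scores each list
#' by split-half term overlap, and compares the paired score samples with a
#' Wilcoxon rank-sum test.  The default alternative is one-sided: the
#' combined mode is expected to produce more functionally coherent lists.
#'
#' @param queries character vector of query genes (rows of \code{profiles}).
#' @param profiles a \code{phyletic_profiles} object.
#' @param expression an \code{expression_matrix}.
#' @param annotations gene-set collection.
#' @param config a \code{\link{ranking_config}}.
#' @param seed integer master seed.
#' @param statistic overlap statistic, see \code{\link{split_half_overlap}}.
#'   Defaults to \code{"over_smaller"} here, unlike
#'   \code{\link{evaluate_method}}: the two modes produce lists of very
#'   different lengths (the correlation filter shortens the combined list),
#'   and the Jaccard union normalization mechanically penalizes the shorter
#'   list's term sets regardless of their coherence.  Intersection over the
#'   smaller term set is size-robust and is the recommended statistic for
#'   this paired comparison.
#' @param alternative passed to \code{\link{wilcoxon_rank_sum}} with the
#'   combined scores as first sample (default \code{"greater"}).
#' @return an \code{evocor_comparison} object: list with
#'   \code{scores_evo_only}, \code{scores_combined}, \code{wilcoxon_W},
#'   \code{wilcoxon_p}, \code{wilcoxon_convention}, \code{n_queries}.
#' @export
compare_evo_vs_combined <- function(queries, profiles, expression, annotations,
                                    config = ranking_config(), seed = 1L,
                                    statistic = c("over_smaller", "jaccard"),
                                    alternative = "greater") {
  statistic <- match.arg(statistic)
  if (!length(queries)) stopf("no query genes supplied")
  index <- gene_term_index(annotations)
  ann <- structure(annotations, gene_index = index)
  with_seed(seed, {
    score <- function(ranking) {
      if (!nrow(ranking)) return(0)
      split_half_overlap(ranking$gene, ann, seed = NULL, statistic = statistic)
    }
    evo <- numeric(length(queries))
    comb <- numeric(length(queries))
    for (i in seq_along(queries)) {
      evo[i] <- score(evocor_rank(queries[i], profiles, NULL, config,
                                  evolution_only = TRUE))
      comb[i] <- score(evocor_rank(queries[i], profiles, expression, config))
    }
    w <- wilcoxon_rank_sum(comb, evo, alternative = alternative)
    structure(list(scores_evo_only = evo, scores_combined = comb,
                   wilcoxon_W = w$W, wilcoxon_p = w$p, wilcoxon_z = w$z,
                   wilcoxon_convention = w$method,
                   alternative = alternative, n_queries = length(queries),
                   statistic = statistic, seed = seed),
              class = "evocor_comparison")
  })
}

#' @export
print.evocor_comparison <- function(x, ...) {
  cat(sprintf("evolution-only vs combined ranking (%d queries, %s overlap)\n",
              x$n_queries, x$statistic))
  cat(sprintf("  mean overlap: evolution-only %.4f, combined %.4f\n",
              mean(x$scores_evo_only), mean(x$scores_combined)))
  cat(sprintf("  Wilcoxon rank-sum (combined first, %s): W = %.0f, p = %.4g\n",
              x$alternative, x$wilcoxon_W, x$wilcoxon_p))
  invisible(x)
}
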