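# Expression handling: a gene x sample matrix tagged with its normalization
# state (raw -> log2 -> log2+quantile), the two normalization steps applied
# to tissue-atlas intensities before correlation, and per-gene-pair Pearson
# correlations.  Background correction of raw array data is out of scope:
# matrices arrive either raw at the gene level (log2 + quantile are applied
# here) or already normalized.

#' Construct an expression matrix with normalization provenance
#'
#' @param values numeric gene x sample matrix with rownames and colnames.
#' @param state normalization state: \code{"raw"}, \code{"log2"} or
#'   \code{"log2+quantile"}.  The state only moves forward through
#'   \code{\link{log2_transform}} and \code{\link{quantile_normalize}}.
#' @return an \code{expression_matrix} object.
#' @export
expression_matrix <- function(values,
                              state = c("raw", "log2", "log2+quantile")) {
  state <- match.arg(state)
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stopf("expression matrix needs gene rownames and sample colnames")
  if (anyDuplicated(rownames(values)))
    stopf("duplicate gene rows in expression matrix")
  if (anyNA(values)) stopf("expression matrix contains missing cells")
  storage.mode(values) <- "double"
  structure(values, normalization_state = state,
            class = c("expression_matrix", class(values)))
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples [%s]\n",
              nrow(x), ncol(x), attr(x, "normalization_state")))
  invisible(x)
}

#' Log2-transform an expression matrix
#'
#' Applies \code{log2(value + offset)} cell-wise.  Requires raw input and a
#' strictly positive shifted value everywhere.
#'
#' @param m an \code{expression_matrix} in state \code{"raw"}.
#' @param offset non-negative pseudocount added before the log (default 1).
#' @return the transformed matrix in state \code{"log2"}.
#' @export
log2_transform <- function(m, offset = 1) {
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(m)
  if (attr(m, "normalization_state") != "raw")
    stopf("log2_transform requires state 'raw', got '%s'",
          attr(m, "normalization_state"))
  if (offset < 0) stopf("offset must be non-negative")
  bad <- which(m + offset <= 0)
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(m))
    stopf("non-positive value after offset at (%s, %s): %g + %g <= 0",
          rownames(m)[i[1L]], colnames(m)[i[2L]], m[bad[1L]], offset)
  }
  out <- log2(unclass(m) + offset)
  expression_matrix(out, state = "log2")
}

#' Quantile-normalize an expression matrix
#'
#' Forces every column (sample) to share the same empirical distribution: the
#' reference distribution is the across-column mean of order statistics, and
#' each cell is replaced by the reference value at its within-column rank.
#' Tied values within a column receive the mean of the reference values over
#' their tied ranks (average-ties convention).  Row and column labels are
#' unchanged; within-column rank order is preserved.  Idempotent.
#'
#' @param m an \code{expression_matrix} (typically in state \code{"log2"};
#'   raw input is accepted when the caller opts out of the log transform).
#' @return the normalized matrix in state \code{"log2+quantile"}.  A
#'   single-column matrix is returned unchanged with a warning.
#' @export
quantile_normalize <- function(m) {
  if (!inherits(m, "expression_matrix")) m <- expression_matrix(m)
  if (attr(m, "normalization_state") == "log2+quantile")
    stopf("matrix is already quantile normalized")
  if (ncol(m) < 2L) {
    warnf("quantile normalization needs >= 2 columns; matrix returned unchanged")
    return(expression_matrix(unclass(m), state = "log2+quantile"))
  }
  x <- unclass(m)
  ref <- rowMeans(apply(x, 2L, sort))
  out <- apply(x, 2L, function(col) {
    v <- numeric(length(col))
    v[order(col)] <- ref
    stats::ave(v, col, FUN = mean)  # ties -> mean of reference at tied ranks
  })
  dimnames(out) <- dimnames(x)
  expression_matrix(out, state = "log2+quantile")
}

#' Pearson correlation with an undefined-value sentinel
#'
#' Sample product-moment correlation of two equal-length vectors.  A constant
#' vector makes the correlation undefined; \code{NA} is returned as an
#' explicit sentinel and is never silently mapped to 0, because 0 has ranking
#' meaning downstream (the co-expression filter).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return correlation in [-1, 1], or \code{NA} if either vector is constant.
#' @examples
#' pearson(c(1, 2, 3), c(1, 3, 2))  # 0.5
#' @export
pearson <- function(x, y) {
  if (length(x) != length(y))
    stopf("vector length mismatch: %d vs %d", length(x), length(y))
  if (length(x) < 3L) stopf("need >= 3 paired observations")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) return(NA_real_)
  stats::cor(x, y)
}

#' Pearson correlations from one query gene to all other genes
#'
#' @param query_gene gene identifier; must be a row of \code{m}.
#' @param m an \code{expression_matrix}.
#' @return data frame with columns \code{gene}, \code{r}; one row per
#'   non-query gene.  Constant rows (query or candidate) yield the \code{NA}
#'   sentinel.
#' @export
correlations_to_query <- function(query_gene, m) {
  if (!query_gene %in% rownames(m))
    stopf("query gene '%s' is not a row of the expression matrix", query_gene)
  if (ncol(m) < 3L) stopf("need >= 3 samples for correlation")
  x <- unclass(m)
  q <- x[query_gene, ]
  others <- x[rownames(x) != query_gene, , drop = FALSE]
  if (stats::sd(q) == 0) {
    r <- rep(NA_real_, nrow(others))
  } else {
    r <- suppressWarnings(as.vector(stats::cor(t(others), q)))
    r[apply(others, 1L, stats::sd) == 0] <- NA_real_
  }
  data.frame(gene = rownames(others), r = r, stringsAsFactors = FALSE)
}
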