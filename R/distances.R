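# Pairwise distance matrices by the dot-product/norm decomposition: one
# dense matrix product (crossprod) plus column reductions gives Euclidean,
# Cosine, and Pearson distances between every query and corpus vector.
# Vectors are matrix *columns* throughout.

.check_vector_matrix <- function(M, what = "matrix") {
  if (!is.matrix(M) || !is.numeric(M))
    stop("`", what, "` must be a numeric matrix (columns are vectors)",
         call. = FALSE)
  if (nrow(M) < 1L || ncol(M) < 1L)
    stop("`", what, "` must have at least one row and one column",
         call. = FALSE)
  if (!all(is.finite(M))) {
    bad <- which(!apply(M, 2L, function(x) all(is.finite(x))))[1L]
    stop("`", what, "` column ", bad, " contains non-finite values",
         call. = FALSE)
  }
  invisible(M)
}

#' Column means and squared norms
#'
#' The two vector reductions the distance decomposition needs, computed in
#' one pass over the matrix: per-column mean and per-column squared
#' Euclidean norm.
#'
#' @param M Numeric matrix whose columns are vectors.
#' @return A list with `means` and `sqnorms`, each of length `ncol(M)`.
#' @export
column_stats <- function(M) {
  .check_vector_matrix(M, "M")
  list(means = colMeans(M), sqnorms = colSums(M^2))
}

#' All query-corpus dot products as one matrix product
#'
#' Entry `(j, i)` is the inner product of query column `j` and corpus
#' column `i`; the whole m-by-n block is `t(Q) %*% C`, delegated to the
#' BLAS-backed `crossprod()`.
#'
#' @param Q,C Numeric matrices with the same number of rows (the vector
#'   dimension d); columns are vectors.
#' @return An `m x n` numeric matrix of dot products.
#' @export
dot_matrix <- function(Q, C) {
  .check_vector_matrix(Q, "Q"); .check_vector_matrix(C, "C")
  if (nrow(Q) != nrow(C))
    stop("Q and C must share the vector dimension d (nrow)", call. = FALSE)
  crossprod(Q, C)
}

.distance_matrix <- function(values, metric, reduced = FALSE) {
  structure(values, metric = metric, reduced = reduced,
            class = c("distance_matrix", class(values)))
}

#' Reduced Euclidean comparison values
#'
#' The squared distance between query q and corpus vector c expands to
#' `||q||^2 - 2 q.c + ||c||^2`; within one query row the `||q||^2` term is
#' a common additive constant, so comparisons only need
#' `||c||^2 - 2 q.c`. These reduced values preserve the within-row
#' ordering of the true distances (they may be negative).
#'
#' @param dots Dot-product matrix from [dot_matrix()].
#' @param corpus_sqnorms Squared corpus column norms (length `ncol(dots)`).
#' @return An m-by-n matrix of comparison values with attributes
#'   `metric = "euclidean"` and `reduced = TRUE`.
#' @export
euclidean_reduced <- function(dots, corpus_sqnorms) {
  if (length(corpus_sqnorms) != ncol(dots))
    stop("`corpus_sqnorms` length must equal ncol(dots)", call. = FALSE)
  v <- matrix(corpus_sqnorms, nrow = nrow(dots), ncol = ncol(dots),
              byrow = TRUE) - 2 * dots
  .distance_matrix(v, "euclidean", reduced = TRUE)
}

#' True Euclidean distances from reduced comparison values
#'
#' Restores the per-query `||q||^2` term and takes the square root; tiny
#' negative residue from floating-point cancellation is clamped to zero.
#'
#' @param reduced Matrix from [euclidean_reduced()].
#' @param query_sqnorms Squared query column norms (length `nrow(reduced)`).
#' @return An m-by-n matrix of Euclidean distances (`reduced = FALSE`).
#' @export
euclidean_full <- function(reduced, query_sqnorms) {
  if (!isTRUE(attr(reduced, "reduced")))
    stop("`reduced` must carry the reduced-values flag", call. = FALSE)
  if (length(query_sqnorms) != nrow(reduced))
    stop("`query_sqnorms` length must equal nrow(reduced)", call. = FALSE)
  v <- sqrt(pmax(reduced + query_sqnorms, 0))
  .distance_matrix(unclass(v), "euclidean", reduced = FALSE)
}

#' Cosine distances from dot products and norms
#'
#' `1 - q.c / (||q|| ||c||)`, in `[0, 2]`. Zero-norm vectors have no
#' direction and are rejected by name.
#'
#' @param dots Dot-product matrix.
#' @param query_sqnorms,corpus_sqnorms Squared column norms of the query
#'   and corpus matrices.
#' @return An m-by-n matrix of cosine distances.
#' @export
cosine_distance <- function(dots, query_sqnorms, corpus_sqnorms) {
  if (any(query_sqnorms == 0))
    stop("query column ", which(query_sqnorms == 0)[1L],
         " has zero norm; cosine distance is undefined", call. = FALSE)
  if (any(corpus_sqnorms == 0))
    stop("corpus column ", which(corpus_sqnorms == 0)[1L],
         " has zero norm; cosine distance is undefined", call. = FALSE)
  v <- 1 - dots / sqrt(outer(query_sqnorms, corpus_sqnorms))
  v <- pmin(pmax(v, 0), 2)    # clamp float residue at the range ends
  .distance_matrix(v, "cosine", reduced = FALSE)
}

#' Center every column at mean zero
#'
#' Subtracts each column's mean from its entries; the Pearson distance is
#' the cosine distance of the centered data.
#'
#' @param M Numeric matrix whose columns are vectors.
#' @param stats Optional precomputed [column_stats()] of `M`.
#' @return The centered matrix.
#' @export
center_columns <- function(M, stats = NULL) {
  if (is.null(stats)) stats <- column_stats(M)
  sweep(M, 2L, stats$means, `-`)
}

#' Pearson distances between query and corpus columns
#'
#' `1 - r(q, c)` where `r` is the sample correlation; computed as the
#' cosine distance of the column-centered matrices, which is the same
#' quantity because the normalization constant cancels. Constant
#' (zero-variance) columns have no defined correlation and are rejected
#' by name.
#'
#' @param Q,C Numeric matrices with equal vector dimension; columns are
#'   vectors, `d >= 2`.
#' @return An m-by-n matrix of Pearson distances in `[0, 2]`.
#' @export
pearson_distance <- function(Q, C) {
  .check_vector_matrix(Q, "Q"); .check_vector_matrix(C, "C")
  if (nrow(Q) != nrow(C))
    stop("Q and C must share the vector dimension d (nrow)", call. = FALSE)
  if (nrow(Q) < 2L)
    stop("Pearson distance needs vector dimension d >= 2", call. = FALSE)
  Qc <- center_columns(Q); Cc <- center_columns(C)
  qs <- colSums(Qc^2); cs <- colSums(Cc^2)
  if (any(qs == 0))
    stop("query column ", which(qs == 0)[1L],
         " is constant; Pearson distance is undefined", call. = FALSE)
  if (any(cs == 0))
    stop("corpus column ", which(cs == 0)[1L],
         " is constant; Pearson distance is undefined", call. = FALSE)
  v <- cosine_distance(dot_matrix(Qc, Cc), qs, cs)
  .distance_matrix(unclass(v), "pearson", reduced = FALSE)
}

#' Reuse a dot-product matrix for the reciprocal search
#'
#' The corpus-to-query dot-product block is the transpose of the
#' query-to-corpus block, so the expensive matrix product is computed only
#' once when neighbors are needed in both directions.
#'
#' @param dots The `Q -> C` dot-product matrix.
#' @return The `C -> Q` dot-product matrix.
#' @export
reciprocal_by_transpose <- function(dots) t(dots)

#' Full distance matrix for a named metric
#'
#' Convenience wrapper over the decomposition: one [dot_matrix()] call plus
#' column reductions, returning true (non-reduced) distances.
#'
#' @param Q,C Numeric matrices with equal vector dimension; columns are
#'   vectors.
#' @param metric `"euclidean"`, `"cosine"`, or `"pearson"`.
#' @return An m-by-n matrix of distances with a `metric` attribute.
#' @examples
#' C <- cbind(c(0, 0), c(3, 4))
#' distance_matrix(cbind(c(0, 0)), C, "euclidean")  # 0 5
#' @export
distance_matrix <- function(Q, C, metric = c("euclidean", "cosine", "pearson")) {
  metric <- match.arg(metric)
  .check_vector_matrix(Q, "Q"); .check_vector_matrix(C, "C")
  if (metric == "pearson") return(pearson_distance(Q, C))
  qs <- column_stats(Q); cs <- column_stats(C)
  dots <- dot_matrix(Q, C)
  if (metric == "euclidean")
    euclidean_full(euclidean_reduced(dots, cs$sqnorms), qs$sqnorms)
  else
    cosine_distance(dots, qs$sqnorms, cs$sqnorms)
}

#' Evaluate distance rows in fixed-height tiles
#'
#' Splits the m query columns into consecutive blocks of at most
#' `tile_rows` and evaluates each block of the distance matrix separately,
#' so the full m-by-n matrix need never be materialized at once.
#' Concatenating the blocks reproduces the monolithic computation exactly:
#' dot products here accumulate per query column in a fixed order
#' (independent of the tile shape), so every choice of `tile_rows` yields
#' bit-identical rows — optimized BLAS kernels switch algorithms with the
#' operand shape and would break that exactness.
#'
#' @param Q,C Numeric matrices with equal vector dimension.
#' @param metric Metric name; for `"euclidean"`, `reduced = TRUE` yields
#'   the comparison-only values the selection stage consumes.
#' @param tile_rows Rows per block, at least 1.
#' @param reduced Emit reduced Euclidean comparison values.
#' @return A list of blocks, each a list with `row_offset` (0-based index
#'   of the block's first query) and `values` (the block's distance rows).
#' @export
tiled_distance_rows <- function(Q, C,
                                metric = c("euclidean", "cosine", "pearson"),
                                tile_rows = 64L, reduced = FALSE) {
  metric <- match.arg(metric)
  tile_rows <- as.integer(tile_rows)
  if (is.na(tile_rows) || tile_rows < 1L)
    stop("`tile_rows` must be >= 1", call. = FALSE)
  if (reduced && metric != "euclidean")
    stop("reduced comparison values exist only for the Euclidean metric",
         call. = FALSE)
  .check_vector_matrix(Q, "Q"); .check_vector_matrix(C, "C")
  if (metric == "pearson") {
    Q <- center_columns(Q); C <- center_columns(C)
    qs <- colSums(Q^2); cs <- colSums(C^2)
    if (any(qs == 0))
      stop("query column ", which(qs == 0)[1L],
           " is constant; Pearson distance is undefined", call. = FALSE)
    if (any(cs == 0))
      stop("corpus column ", which(cs == 0)[1L],
           " is constant; Pearson distance is undefined", call. = FALSE)
  } else {
    qs <- colSums(Q^2); cs <- colSums(C^2)
  }
  m <- ncol(Q)
  starts <- seq.int(1L, m, by = tile_rows)
  lapply(starts, function(s) {
    e <- min(s + tile_rows - 1L, m)
    Qb <- Q[, s:e, drop = FALSE]
    # per-query fixed-order accumulation: bit-identical for every tiling
    dots <- matrix(0, e - s + 1L, ncol(C))
    for (jj in seq_len(e - s + 1L)) dots[jj, ] <- colSums(Qb[, jj] * C)
    vals <- if (metric == "euclidean") {
      red <- euclidean_reduced(dots, cs)
      if (reduced) red else euclidean_full(red, qs[s:e])
    } else {
      cosine_distance(dots, qs[s:e], cs)
    }
    vals <- unclass(vals)
    attr(vals, "metric") <- NULL; attr(vals, "reduced") <- NULL
    list(row_offset = s - 1L, values = vals)
  })
}
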