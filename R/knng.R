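# End-to-end k-NN / k-NNG construction: tiled distance rows streamed into
# the multi-query quickselect, plus the run configuration object.

#' Run configuration for a k-NN build
#'
#' @param metric `"euclidean"`, `"cosine"`, or `"pearson"`.
#' @param k Neighbors per query.
#' @param mode `"auto"`, `"warp"`, or `"block"`. `"auto"` picks warp when
#'   the query count reaches `warp_threshold` (enough independent rows to
#'   fill one lane group each) and block otherwise; the two modes return
#'   identical results, the choice only mirrors the utilization trade-off.
#' @param group_count Lane groups per row in block mode, 1..16.
#' @param seed Integer seed for the pivot streams, recorded in output
#'   metadata.
#' @param tile_rows Query rows evaluated per distance tile.
#' @param exclude_self Drop each corpus point from its own neighbor list
#'   when querying the corpus against itself (the graph-theoretic
#'   convention); the flag restores self-inclusion.
#' @param raw_reduced Report reduced Euclidean comparison values instead of
#'   true distances.
#' @param warp_threshold Query count at which `"auto"` switches to warp
#'   mode.
#' @return A validated list of class `knn_config`.
#' @export
knn_config <- function(metric = c("euclidean", "cosine", "pearson"),
                       k = 8L, mode = c("auto", "warp", "block"),
                       group_count = 4L, seed = 1L, tile_rows = 64L,
                       exclude_self = TRUE, raw_reduced = FALSE,
                       warp_threshold = 448L) {
  metric <- match.arg(metric); mode <- match.arg(mode)
  k <- as.integer(k)
  if (is.na(k) || k < 1L) stop("`k` must be a positive integer", call. = FALSE)
  group_count <- as.integer(group_count)
  if (is.na(group_count) || group_count < 1L || group_count > 16L)
    stop("`group_count` must be in 1..16", call. = FALSE)
  tile_rows <- as.integer(tile_rows)
  if (is.na(tile_rows) || tile_rows < 1L)
    stop("`tile_rows` must be >= 1", call. = FALSE)
  if (raw_reduced && metric != "euclidean")
    stop("`raw_reduced` applies only to the Euclidean metric", call. = FALSE)
  structure(list(metric = metric, k = k, mode = mode,
                 group_count = group_count, seed = as.integer(seed),
                 tile_rows = tile_rows, exclude_self = isTRUE(exclude_self),
                 raw_reduced = isTRUE(raw_reduced),
                 warp_threshold = as.integer(warp_threshold)),
            class = "knn_config")
}

.resolve_mode <- function(config, m) {
  if (config$mode != "auto") return(config$mode)
  if (m >= config$warp_threshold) "warp" else "block"
}

.new_knn_result <- function(indices, distances, config, mode, m, n,
                            passes, self_excluded) {
  structure(list(indices = indices, distances = distances,
                 metric = config$metric, k = ncol(indices), mode = mode,
                 group_count = config$group_count, seed = config$seed,
                 tile_rows = config$tile_rows,
                 raw_reduced = config$raw_reduced,
                 self_excluded = self_excluded,
                 passes = passes, m = m, n = n),
            class = "knn_result")
}

# shared core: select k_sel nearest corpus columns for every query column
.knn_core <- function(Q, C, config, k_sel) {
  m <- ncol(Q); n <- ncol(C)
  mode <- .resolve_mode(config, m)
  reduced <- config$metric == "euclidean"
  q_sq <- if (reduced) colSums(Q^2) else NULL
  blocks <- tiled_distance_rows(Q, C, config$metric, config$tile_rows,
                                reduced = reduced)
  out_i <- matrix(0L, m, k_sel); out_v <- matrix(0, m, k_sel)
  passes <- integer(m)
  for (b in blocks) {
    sel <- multiselect_rows(b$values, k_sel, mode = mode,
                            group_count = config$group_count,
                            seed = config$seed, row_offset = b$row_offset)
    rows <- b$row_offset + seq_len(nrow(b$values))
    vals <- sel$values
    if (reduced && !config$raw_reduced)
      vals <- sqrt(pmax(vals + q_sq[rows], 0))
    out_i[rows, ] <- sel$indices
    out_v[rows, ] <- vals
    passes[rows] <- sel$passes
  }
  # restoring ||q||^2 preserves order but equalizes clamped near-zero values;
  # re-sort each row so the ascending-by-(value, index) contract holds exactly
  for (r in seq_len(m)) {
    ord <- order(out_v[r, ], out_i[r, ])
    out_v[r, ] <- out_v[r, ord]; out_i[r, ] <- out_i[r, ord]
  }
  list(indices = out_i, values = out_v, passes = passes, mode = mode)
}

#' k nearest corpus neighbors of every query vector
#'
#' Brute-force exact k-NN: all query-corpus distances are computed tile by
#' tile through the dot-product/norm decomposition, and each row's k
#' smallest values are found by the multi-query quickselect. For the
#' Euclidean metric, selection runs on reduced comparison values
#' (`||c||^2 - 2 q.c`), which order identically to true distances; reported
#' distances are the true values unless `raw_reduced` is set.
#'
#' @param Q Query matrix (d×m, columns are vectors).
#' @param C Corpus matrix (d×n, columns are vectors).
#' @param config A [knn_config()]; its `k` must not exceed n.
#' @return A `knn_result` with m×k matrices `indices` (0-based corpus
#'   columns) and `distances` (ascending within each row), per-row
#'   partition-pass counts, and the run configuration.
#' @examples
#' C <- cbind(c(0, 0), c(1, 0), c(5, 5), c(0, 2))
#' r <- build_knn(cbind(c(0, 0)), C, knn_config("euclidean", k = 2))
#' r$indices   # 0 1
#' r$distances # 0 1
#' @export
build_knn <- function(Q, C, config = knn_config()) {
  if (!inherits(config, "knn_config"))
    stop("`config` must come from knn_config()", call. = FALSE)
  .check_vector_matrix(Q, "Q"); .check_vector_matrix(C, "C")
  if (nrow(Q) != nrow(C))
    stop("Q and C must share the vector dimension d (nrow)", call. = FALSE)
  if (config$k > ncol(C))
    stop("`k` (", config$k, ") exceeds the corpus size n (", ncol(C), ")",
         call. = FALSE)
  core <- .knn_core(Q, C, config, config$k)
  .new_knn_result(core$indices, core$values, config, core$mode,
                  ncol(Q), ncol(C), core$passes, self_excluded = FALSE)
}

#' k-nearest-neighbor graph over a corpus
#'
#' Every corpus point is also a query. With `exclude_self` (the default)
#' the selection runs with k+1 and each point's own entry is removed, so k
#' true neighbors are still returned; with self-inclusion each point's
#' first neighbor on tie-free data is itself at distance zero.
#'
#' @param C Corpus matrix (d×n, columns are vectors).
#' @param config A [knn_config()]; `k` must be at most `n - 1` when
#'   excluding self, `n` otherwise.
#' @return A `knn_result`; row j never contains index j when self is
#'   excluded.
#' @export
build_knng <- function(C, config = knn_config()) {
  if (!inherits(config, "knn_config"))
    stop("`config` must come from knn_config()", call. = FALSE)
  .check_vector_matrix(C, "C")
  n <- ncol(C)
  if (!config$exclude_self) {
    res <- build_knn(C, C, config)
    res$self_excluded <- FALSE
    return(res)
  }
  if (config$k > n - 1L)
    stop("`k` (", config$k, ") exceeds n - 1 (", n - 1L,
         ") with self-exclusion", call. = FALSE)
  core <- .knn_core(C, C, config, config$k + 1L)
  m <- n; k <- config$k
  out_i <- matrix(0L, m, k); out_v <- matrix(0, m, k)
  for (r in seq_len(m)) {
    drop_at <- match(r - 1L, core$indices[r, ])
    if (is.na(drop_at)) drop_at <- k + 1L   # a duplicate displaced self
    keep <- setdiff(seq_len(k + 1L), drop_at)
    out_i[r, ] <- core$indices[r, keep]
    out_v[r, ] <- core$values[r, keep]
  }
  .new_knn_result(out_i, out_v, config, core$mode, m, n, core$passes,
                  self_excluded = TRUE)
}
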