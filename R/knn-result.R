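# Accessors and tidiers for knn_result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
print.knn_result <- function(x, ...) {
  cat(sprintf(
    "<knn_result> %d quer%s x %d corpus vectors, k = %d (%s, %s mode)\n",
    x$m, if (x$m == 1L) "y" else "ies", x$n, x$k, x$metric, x$mode))
  cat(sprintf("  self %s; seed %d; partition passes: median %.1f, max %d\n",
              if (x$self_excluded) "excluded" else "included",
              x$seed, stats::median(x$passes), max(x$passes)))
  cat(sprintf("  distances: %s\n",
              if (x$raw_reduced) "reduced Euclidean comparison values"
              else "true metric values"))
  invisible(x)
}

#' Edge-list view of a k-NN result
#'
#' One row per (query, neighbor) edge: 0-based ids, 1-based rank within the
#' query's ascending neighbor list, and the distance. This is the same
#' table [write_neighbors()] writes in edge-list format.
#'
#' @param x A `knn_result`.
#' @param ... Unused.
#' @return A tibble with columns `query_id`, `neighbor_id`, `rank`,
#'   `distance` (m·k rows).
#' @method tidy knn_result
#' @export
tidy.knn_result <- function(x, ...) {
  tibble::tibble(
    query_id = rep(seq_len(x$m) - 1L, each = x$k),
    neighbor_id = as.integer(t(x$indices)),
    rank = rep(seq_len(x$k), x$m),
    distance = as.numeric(t(x$distances)))
}

#' One-row summary of a k-NN result
#'
#' @param x A `knn_result`.
#' @param ... Unused.
#' @return A one-row tibble with the run shape, metric, mode, seed, edge
#'   count, and partition-pass statistics.
#' @method glance knn_result
#' @export
glance.knn_result <- function(x, ...) {
  tibble::tibble(
    m = x$m, n = x$n, k = x$k, metric = x$metric, mode = x$mode,
    group_count = x$group_count, seed = x$seed,
    self_excluded = x$self_excluded, edges = x$m * x$k,
    median_passes = stats::median(x$passes),
    max_passes = max(x$passes))
}

#' Distance-by-rank plot of a k-NN result
#'
#' Shows the distribution of neighbor distances at each rank — a quick
#' visual check that distances grow with rank and that the graph has no
#' pathological rows.
#'
#' @param object A `knn_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot knn_result
#' @export
autoplot.knn_result <- function(object, ...) {
  edges <- tidy(object)
  ggplot2::ggplot(edges,
                  ggplot2::aes(x = factor(.data$rank), y = .data$distance)) +
    ggplot2::geom_boxplot(outlier.size = 0.5) +
    ggplot2::labs(
      x = "neighbor rank", y = paste0(object$metric, " distance"),
      title = sprintf("k-NN distances by rank (m = %d, n = %d, k = %d)",
                      object$m, object$n, object$k)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 .data
NULL
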