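# Synthetic fixtures and independent brute-force oracles. The generators
# reproduce the regime the method is benchmarked under — uniform random
# vectors with attached indices — plus clustered, duplicate-heavy, and
# constant variants that stress tie handling. The oracles share no code
# with the selection engine or the distance decomposition.

#' Specification of a synthetic fixture
#'
#' @param kind `"uniform"` (i.i.d. values in `[0, 1)`), `"clustered"`
#'   (Gaussian clusters around well-separated centers), `"duplicate-heavy"`
#'   (a fraction of corpus columns are exact copies of a few templates), or
#'   `"constant"` (every column identical, so each distance row is one
#'   repeated value).
#' @param d Vector dimension.
#' @param n Corpus size.
#' @param m Query count (ignored when queries are taken equal to the
#'   corpus).
#' @param k Neighbor count carried along for downstream runs.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @param duplicate_fraction Fraction of corpus columns replaced by
#'   template copies (duplicate-heavy kind only).
#' @param clusters Number of cluster centers (clustered kind only).
#' @param cluster_radius Within-cluster Gaussian scale; centers are spaced
#'   at least 10 radii apart along a random direction.
#' @return A validated list of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("uniform", "clustered", "duplicate-heavy",
                                  "constant"),
                         d = 16L, n = 256L, m = 32L, k = 8L, seed = 1L,
                         duplicate_fraction = 0.5, clusters = 4L,
                         cluster_radius = 0.05) {
  kind <- match.arg(kind)
  d <- as.integer(d); n <- as.integer(n); m <- as.integer(m); k <- as.integer(k)
  if (any(is.na(c(d, n, m, k))) || d < 1L || n < 1L || m < 1L || k < 1L)
    stop("d, n, m, k must be positive integers", call. = FALSE)
  if (k > n) stop("`k` cannot exceed the corpus size n", call. = FALSE)
  if (duplicate_fraction < 0 || duplicate_fraction > 1)
    stop("`duplicate_fraction` must lie in [0, 1]", call. = FALSE)
  if (clusters < 1L) stop("`clusters` must be >= 1", call. = FALSE)
  structure(list(kind = kind, d = d, n = n, m = m, k = k,
                 seed = as.integer(seed),
                 duplicate_fraction = duplicate_fraction,
                 clusters = as.integer(clusters),
                 cluster_radius = cluster_radius),
            class = "fixture_spec")
}

#' Generate a query/corpus matrix pair from a fixture spec
#'
#' Deterministic for a fixed spec (including seed); all values are finite.
#' Clustered corpora carry the per-column cluster labels in attribute
#' `"cluster"` on both matrices, for tests that count intra-cluster edges.
#'
#' @param spec A [fixture_spec()].
#' @return A list with `Q` (d×m) and `C` (d×n) matrices and the `spec`.
#' @export
generate_fixture <- function(spec) {
  if (!inherits(spec, "fixture_spec"))
    stop("`spec` must be a fixture_spec", call. = FALSE)
  withr::with_seed(spec$seed, {
    out <- switch(spec$kind,
      "uniform" = {
        list(Q = matrix(runif(spec$d * spec$m), spec$d, spec$m),
             C = matrix(runif(spec$d * spec$n), spec$d, spec$n))
      },
      "clustered" = {
        g <- spec$clusters
        u <- rnorm(spec$d); u <- u / sqrt(sum(u^2))
        sep <- 10 * spec$cluster_radius * sqrt(2 * spec$d) * 2
        centers <- outer(u, (seq_len(g) - 1L) * sep)   # d × g, spaced >= 10 radii
        lab_c <- rep_len(seq_len(g), spec$n)
        lab_q <- rep_len(seq_len(g), spec$m)
        C <- centers[, lab_c, drop = FALSE] +
          matrix(rnorm(spec$d * spec$n, sd = spec$cluster_radius), spec$d)
        Q <- centers[, lab_q, drop = FALSE] +
          matrix(rnorm(spec$d * spec$m, sd = spec$cluster_radius), spec$d)
        attr(C, "cluster") <- lab_c; attr(Q, "cluster") <- lab_q
        list(Q = Q, C = C)
      },
      "duplicate-heavy" = {
        C <- matrix(runif(spec$d * spec$n), spec$d, spec$n)
        n_dup <- round(spec$duplicate_fraction * spec$n)
        if (n_dup > 0L) {
          n_templates <- max(1L, min(4L, spec$n - n_dup))
          templates <- matrix(runif(spec$d * n_templates), spec$d)
          which_dup <- sample.int(spec$n, n_dup)
          C[, which_dup] <- templates[, rep_len(seq_len(n_templates), n_dup),
                                      drop = FALSE]
        }
        list(Q = matrix(runif(spec$d * spec$m), spec$d, spec$m), C = C)
      },
      "constant" = {
        template <- runif(spec$d)
        list(Q = matrix(template, spec$d, spec$m),
             C = matrix(template, spec$d, spec$n))
      })
    out$spec <- spec
    out
  })
}

#' Sort-based top-k oracle
#'
#' The independent ground truth for selection: a full stable sort of the
#' row ascending by `(value, index)`, returning the first k pairs. Shares
#' no code with the quickselect engine.
#'
#' @param values Numeric row.
#' @param k Number of smallest entries, `1..length(values)`.
#' @param indices Optional 0-based original ids (default `0..n-1`).
#' @return A list with `indices` (0-based) and `values`, each length k,
#'   ascending by `(value, index)`.
#' @examples
#' oracle_topk(c(9, 3, 7, 1, 5), 2)  # values 1, 3
#' @export
oracle_topk <- function(values, k, indices = NULL) {
  n <- length(values)
  if (k < 1L || k > n) stop("`k` must be in 1..", n, call. = FALSE)
  if (is.null(indices)) indices <- seq_len(n) - 1L
  ord <- order(values, indices)[seq_len(k)]
  list(indices = as.integer(indices[ord]), values = as.numeric(values[ord]))
}

#' Naive per-pair distance oracle
#'
#' Direct per-pair evaluation of the textbook formulas with explicit loops
#' — no matrix product, no norm decomposition — used as ground truth for
#' the fast distance path. Pearson goes through `stats::cor()`.
#'
#' @param Q,C Numeric matrices with equal vector dimension; columns are
#'   vectors.
#' @param metric `"euclidean"`, `"cosine"`, or `"pearson"`.
#' @return An m-by-n matrix of distances.
#' @export
oracle_distance <- function(Q, C, metric = c("euclidean", "cosine", "pearson")) {
  metric <- match.arg(metric)
  m <- ncol(Q); n <- ncol(C)
  out <- matrix(0, m, n)
  for (j in seq_len(m)) {
    q <- Q[, j]
    for (i in seq_len(n)) {
      cc <- C[, i]
      out[j, i] <- switch(metric,
        "euclidean" = sqrt(sum((q - cc)^2)),
        "cosine" = 1 - sum(q * cc) / sqrt(sum(q^2) * sum(cc^2)),
        "pearson" = 1 - stats::cor(q, cc))
    }
  }
  out
}
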