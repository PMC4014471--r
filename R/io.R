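# File I/O: vector matrices from delimited text or MatrixMarket, neighbor
# results to edge lists or index/distance matrices with a JSON run sidecar.
# Floating-point values are written as %.17g so a read-back reproduces every
# double bit-exactly and repeated runs are byte-identical.

.fmt_dbl <- function(x) sprintf("%.17g", x)

#' Read a vector matrix from a file
#'
#' Delimited text (CSV/TSV) goes through `data.table::fread`; MatrixMarket
#' coordinate files through `Matrix::readMM`; the dense MatrixMarket
#' "array" flavor is parsed directly. By default columns of the file are
#' the vectors; `orientation = "rows"` transposes after reading.
#'
#' @param path Input file.
#' @param format `"auto"` (by extension: `.mtx` MatrixMarket, `.tsv`/`.tab`
#'   tab-delimited, otherwise comma-delimited), `"csv"`, `"tsv"`, or
#'   `"mtx"`.
#' @param orientation Are vectors the file's `"columns"` (default) or
#'   `"rows"`?
#' @param header Does the delimited file carry a header line?
#' @return A numeric matrix whose columns are vectors.
#' @export
read_vectors <- function(path, format = c("auto", "csv", "tsv", "mtx"),
                         orientation = c("columns", "rows"), header = FALSE) {
  format <- match.arg(format); orientation <- match.arg(orientation)
  if (!file.exists(path)) stop("input file not found: ", path, call. = FALSE)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, mtx = "mtx", tsv = "tsv", tab = "tsv", "csv")
  }
  M <- if (format == "mtx") {
    .read_mtx(path)
  } else {
    sep <- if (format == "tsv") "\t" else ","
    dt <- data.table::fread(path, sep = sep, header = header,
                            data.table = FALSE)
    as.matrix(dt)
  }
  dimnames(M) <- NULL
  storage.mode(M) <- "double"
  if (orientation == "rows") M <- t(M)
  M
}

.read_mtx <- function(path) {
  head1 <- readLines(path, n = 1L)
  if (!grepl("^%%MatrixMarket", head1))
    stop("not a MatrixMarket file: ", path, call. = FALSE)
  if (grepl("\\barray\\b", head1)) {
    lines <- readLines(path)
    lines <- lines[!startsWith(lines, "%")]
    dims <- scan(text = lines[1L], what = integer(), quiet = TRUE)
    vals <- scan(text = lines[-1L], what = double(), quiet = TRUE)
    if (length(vals) != prod(dims[1:2]))
      stop("MatrixMarket array file has wrong value count", call. = FALSE)
    matrix(vals, dims[1L], dims[2L])   # array format is column-major
  } else {
    as.matrix(Matrix::readMM(path))
  }
}

#' Write a vector matrix to a file
#'
#' @param M Numeric matrix (columns are vectors).
#' @param path Output file.
#' @param format `"csv"`, `"tsv"`, or `"mtx"` (MatrixMarket dense array).
#' @return `path`, invisibly.
#' @export
write_vectors <- function(M, path, format = c("csv", "tsv", "mtx")) {
  format <- match.arg(format)
  if (format == "mtx") {
    con <- file(path, "w"); on.exit(close(con))
    writeLines(c("%%MatrixMarket matrix array real general",
                 paste(nrow(M), ncol(M))), con)
    writeLines(.fmt_dbl(as.vector(M)), con)
  } else {
    chr <- matrix(.fmt_dbl(M), nrow(M), ncol(M))
    data.table::fwrite(data.table::as.data.table(chr), path,
                       sep = if (format == "tsv") "\t" else ",",
                       col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Write a k-NN result to files
#'
#' `edge-list` writes one TSV (`<prefix>_edges.tsv`) with columns
#' `query_id` (0-based), `neighbor_id` (0-based), `rank` (1-based), and
#' `distance`; `matrices` writes `<prefix>_indices.csv` and
#' `<prefix>_distances.csv`, one row per query. Both formats also write a
#' `<prefix>_run.json` sidecar recording the full run configuration
#' (metric, k, mode, group count, seed, tiling, self-exclusion) and the
#' per-row pass counts, so [read_neighbors()] can reconstruct the result
#' exactly.
#'
#' @param result A `knn_result`.
#' @param prefix Output path prefix.
#' @param format `"edge-list"` or `"matrices"`.
#' @return Character vector of the files written, invisibly.
#' @export
write_neighbors <- function(result, prefix,
                            format = c("edge-list", "matrices")) {
  format <- match.arg(format)
  if (!inherits(result, "knn_result"))
    stop("`result` must be a knn_result", call. = FALSE)
  files <- character(0)
  if (format == "edge-list") {
    edges <- tidy(result)
    edges$distance <- .fmt_dbl(edges$distance)
    f <- paste0(prefix, "_edges.tsv")
    data.table::fwrite(edges, f, sep = "\t", quote = FALSE)
    files <- f
  } else {
    fi <- paste0(prefix, "_indices.csv")
    fd <- paste0(prefix, "_distances.csv")
    data.table::fwrite(data.table::as.data.table(result$indices), fi,
                       col.names = FALSE)
    chr <- matrix(.fmt_dbl(result$distances), result$m, result$k)
    data.table::fwrite(data.table::as.data.table(chr), fd,
                       col.names = FALSE, quote = FALSE)
    files <- c(fi, fd)
  }
  meta <- result[c("metric", "k", "mode", "group_count", "seed", "tile_rows",
                   "raw_reduced", "self_excluded", "passes", "m", "n")]
  fj <- paste0(prefix, "_run.json")
  jsonlite::write_json(meta, fj, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(files, fj))
}

#' Reconstruct a k-NN result from matrices-format files
#'
#' Reads `<prefix>_indices.csv`, `<prefix>_distances.csv`, and
#' `<prefix>_run.json` written by [write_neighbors()] and rebuilds the
#' `knn_result` exactly.
#'
#' @param prefix The prefix passed to [write_neighbors()].
#' @return A `knn_result`.
#' @export
read_neighbors <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_run.json"),
                              simplifyVector = TRUE)
  ind <- as.matrix(data.table::fread(paste0(prefix, "_indices.csv"),
                                     header = FALSE))
  dst <- as.matrix(data.table::fread(paste0(prefix, "_distances.csv"),
                                     header = FALSE))
  dimnames(ind) <- NULL; dimnames(dst) <- NULL
  storage.mode(ind) <- "integer"; storage.mode(dst) <- "double"
  structure(list(indices = ind, distances = dst, metric = meta$metric,
                 k = as.integer(meta$k), mode = meta$mode,
                 group_count = as.integer(meta$group_count),
                 seed = as.integer(meta$seed),
                 tile_rows = as.integer(meta$tile_rows),
                 raw_reduced = meta$raw_reduced,
                 self_excluded = meta$self_excluded,
                 passes = as.integer(meta$passes),
                 m = as.integer(meta$m), n = as.integer(meta$n)),
            class = "knn_result")
}
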