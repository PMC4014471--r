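# Multi-query quickselect: per-row iterative partitioning with random pivots,
# remaining-k accounting, buffer swapping, and a copy-avoiding reference stack.
# Rows are independent; the partition step streams 32-lane segments through
# the ballot/popcount primitives (warp mode) or through up to 16 interleaved
# lane groups combined by a serial prefix sum (block mode).

#' Selection state for one row
#'
#' Holds the two value/index buffers (input and auxiliary), the active
#' half-open range, the remaining-k counter, the partition-pass counter, and
#' the reference stack of ranges already confirmed to belong to the k-NN
#' set. Confirmed ranges are never copied between buffers; the stack records
#' which buffer each one lives in.
#'
#' @param values Numeric row of metric values.
#' @param indices Integer vector of the original (0-based) column indices,
#'   same length as `values`; defaults to `0..n-1`.
#' @param k Number of smallest elements to select.
#' @return An environment of class `selection_state`.
#' @export
new_selection_state <- function(values, indices = NULL, k) {
  n <- length(values)
  if (is.null(indices)) indices <- seq_len(n) - 1L
  if (length(indices) != n)
    stop("`values` and `indices` lengths differ", call. = FALSE)
  if (k < 1L || k > n)
    stop("`k` must be in 1..length(values)", call. = FALSE)
  st <- new.env(parent = emptyenv())
  st$bufs <- list(
    partition_sink(values = as.numeric(values), indices = as.integer(indices)),
    partition_sink(length = n)
  )
  st$cur <- 1L                      # buffer holding the active range
  st$s <- 1L; st$e <- n             # active range, 1-based inclusive
  st$k <- as.integer(k)
  st$k_remaining <- as.integer(k)
  st$passes <- 0L
  st$stack <- vector("list", 0L)    # reference stack: list(buf, s, e)
  st$finished <- FALSE
  st$orig_values <- as.numeric(values)
  st$orig_indices <- as.integer(indices)
  class(st) <- c("selection_state", class(st))
  st
}

#' Pick a pivot uniformly from a range of values
#'
#' Draws one element of `values` uniformly at random using R's ambient RNG
#' stream, so the choice is deterministic under a fixed seed. A
#' median-of-three variant (sampling three positions and taking the value
#' median) is available but off by default, matching the randomized-pivot
#' analysis of quickselect.
#'
#' @param values Non-empty numeric vector (the active range).
#' @param median_of_three Use the median of three sampled elements.
#' @return A single pivot value.
#' @export
select_pivot <- function(values, median_of_three = FALSE) {
  n <- length(values)
  if (n == 0L) stop("cannot select a pivot from an empty range", call. = FALSE)
  if (n == 1L) return(values[1L])
  if (median_of_three) {
    cand <- values[sample.int(n, 3L, replace = TRUE)]
    return(sort(cand)[2L])
  }
  values[sample.int(n, 1L)]
}

# Stream the active range of the current buffer through partition_segment
# into the destination window [s, e] of the other buffer. Returns the side
# counts; does not touch the state's bookkeeping fields.
.stream_partition <- function(src, dst, s, e, pivot) {
  dst$start <- s; dst$end <- e
  cursor <- partition_cursor()
  off <- s
  while (off <= e) {
    hi <- min(off + 31L, e)
    cursor <- partition_segment(src$values[off:hi], src$indices[off:hi],
                                pivot, cursor, dst)
    off <- hi + 1L
  }
  cursor
}

#' Partition the active range around a pivot (warp mode)
#'
#' Streams the active range in 32-lane segments through
#' [partition_segment()] into the other buffer: elements below the pivot
#' end up contiguous at the left of the written window, elements at or
#' above it contiguous at the right. The buffers then swap roles — the
#' destination becomes the active buffer — and the side counts are
#' returned.
#'
#' @param state A [new_selection_state()] environment.
#' @param pivot Pivot value.
#' @return A list with `n_less` and `n_geq` (class `partition_result`).
#' @export
partition_row <- function(state, pivot) {
  src <- state$bufs[[state$cur]]
  dst_id <- 3L - state$cur
  cursor <- .stream_partition(src, state$bufs[[dst_id]], state$s, state$e, pivot)
  if (cursor$less_count + cursor$geq_count != state$e - state$s + 1L)
    stop("internal error: partition lost elements", call. = FALSE)
  state$cur <- dst_id
  state$passes <- state$passes + 1L
  structure(list(n_less = cursor$less_count, n_geq = cursor$geq_count),
            class = "partition_result")
}

#' Partition the active range with interleaved lane groups (block mode)
#'
#' Emulates the thread-block variant: the active range is dealt round-robin
#' into `group_count` interleaved lane-group streams, each stream is staged
#' exactly as in warp mode, and the per-group side counts are combined by a
#' serial prefix sum that assigns every group its block-level write base.
#' The result is contiguous per side and multiset-identical to
#' [partition_row()]; with `group_count = 1` the output is byte-identical.
#'
#' @inheritParams partition_row
#' @param group_count Number of lane groups, 1..16.
#' @return A `partition_result` list with `n_less`, `n_geq`, and the
#'   per-group write bases in `less_bases` / `geq_bases`.
#' @export
partition_row_block <- function(state, pivot, group_count = 4L) {
  group_count <- as.integer(group_count)
  if (is.na(group_count) || group_count < 1L || group_count > 16L)
    stop("`group_count` must be in 1..16", call. = FALSE)
  src <- state$bufs[[state$cur]]
  dst_id <- 3L - state$cur
  dst <- state$bufs[[dst_id]]
  s <- state$s; e <- state$e
  len <- e - s + 1L
  gc_ <- min(group_count, len)

  # stage every interleaved stream through the warp primitive
  pos0 <- seq.int(s, e)
  staged <- vector("list", gc_)
  for (g in seq_len(gc_)) {
    at <- pos0[seq.int(g, len, by = gc_)]
    lg <- length(at)
    loc <- partition_sink(length = lg)
    cur <- .stream_partition(
      partition_sink(values = src$values[at], indices = src$indices[at]),
      loc, 1L, lg, pivot)
    staged[[g]] <- list(sink = loc, n_less = cur$less_count,
                        n_geq = cur$geq_count, len = lg)
  }

  # serial prefix sum over per-group side counts -> block-level write bases
  nl <- vapply(staged, `[[`, integer(1), "n_less")
  ng <- vapply(staged, `[[`, integer(1), "n_geq")
  less_base <- cumsum(c(0L, nl))[seq_len(gc_)]
  geq_base <- cumsum(c(0L, ng))[seq_len(gc_)]

  dst$start <- s; dst$end <- e
  for (g in seq_len(gc_)) {
    gs <- staged[[g]]
    if (gs$n_less > 0L) {
      at <- s + less_base[g] + seq_len(gs$n_less) - 1L
      dst$values[at] <- gs$sink$values[seq_len(gs$n_less)]
      dst$indices[at] <- gs$sink$indices[seq_len(gs$n_less)]
      dst$writes <- dst$writes + 1L
    }
    if (gs$n_geq > 0L) {
      at <- e - geq_base[g] - gs$n_geq + seq_len(gs$n_geq)
      dst$values[at] <- gs$sink$values[gs$len - gs$n_geq + seq_len(gs$n_geq)]
      dst$indices[at] <- gs$sink$indices[gs$len - gs$n_geq + seq_len(gs$n_geq)]
      dst$writes <- dst$writes + 1L
    }
  }
  if (sum(nl) + sum(ng) != len)
    stop("internal error: block partition lost elements", call. = FALSE)
  state$cur <- dst_id
  state$passes <- state$passes + 1L
  structure(list(n_less = sum(nl), n_geq = sum(ng),
                 less_bases = less_base, geq_bases = geq_base),
            class = "partition_result")
}

#' Advance the selection loop after a partition
#'
#' Applies the quickselect branch: if the left (below-pivot) side fits
#' within the remaining k, it is pushed onto the reference stack as
#' confirmed — no data is copied — the remaining-k counter drops by its
#' length, and the search continues in the right side; otherwise the right
#' side is discarded and the search continues in the left side. When the
#' remaining k reaches zero the row is finished.
#'
#' @param state A `selection_state` updated by the immediately preceding
#'   partition call.
#' @param result The `partition_result` that call returned.
#' @return The state, invisibly.
#' @export
selection_step <- function(state, result) {
  n_less <- result$n_less
  if (n_less <= state$k_remaining) {
    if (n_less > 0L) {
      state$stack[[length(state$stack) + 1L]] <-
        list(buf = state$cur, s = state$s, e = state$s + n_less - 1L)
      state$k_remaining <- state$k_remaining - n_less
    }
    state$s <- state$s + n_less
    if (state$k_remaining == 0L) state$finished <- TRUE
  } else {
    state$e <- state$s + n_less - 1L
  }
  invisible(state)
}

#' Resolve a zero-progress partition on duplicate-heavy data
#'
#' When the pivot is the minimum of the active range, every element lands
#' on the geq side and the plain quickselect branch makes no progress; a
#' range of identical values would loop forever. This guard counts the
#' elements exactly equal to the pivot: if they cover the remaining k, that
#' many are confirmed and the row finishes; otherwise all of them are
#' confirmed and the search continues on the strictly-greater remainder,
#' so the active range shrinks by at least one element every round.
#'
#' @param state A `selection_state` whose last partition returned
#'   `n_less == 0`.
#' @param pivot The pivot of that partition.
#' @return The state, invisibly.
#' @export
resolve_degenerate <- function(state, pivot) {
  src <- state$bufs[[state$cur]]
  dst_id <- 3L - state$cur
  dst <- state$bufs[[dst_id]]
  s <- state$s; e <- state$e
  win <- s:e
  v <- src$values[win]; ix <- src$indices[win]
  eq <- v == pivot
  n_eq <- sum(eq)
  if (n_eq == 0L)
    stop("internal error: degenerate guard invoked without pivot ties",
         call. = FALSE)
  dst$start <- s; dst$end <- e
  dst$values[win] <- c(v[eq], v[!eq])
  dst$indices[win] <- c(ix[eq], ix[!eq])
  dst$writes <- dst$writes + 2L
  state$cur <- dst_id
  take <- min(n_eq, state$k_remaining)
  state$stack[[length(state$stack) + 1L]] <-
    list(buf = dst_id, s = s, e = s + take - 1L)
  state$k_remaining <- state$k_remaining - take
  state$s <- s + n_eq
  if (state$k_remaining == 0L) state$finished <- TRUE
  invisible(state)
}

# Run one row to completion. Returns values/indices (ascending by value,
# ties by index), the pass count, and optionally the per-pass trace.
.multiselect_row <- function(values, indices, k, row_seed,
                             mode = "warp", group_count = 4L,
                             instrument = FALSE) {
  st <- new_selection_state(values, indices, k)
  n <- length(values)
  trace <- if (instrument) list() else NULL
  withr::with_seed(row_seed, {
    while (!st$finished) {
      len <- st$e - st$s + 1L
      if (st$k_remaining == len) {
        # whole active range is the remainder of the answer
        st$stack[[length(st$stack) + 1L]] <-
          list(buf = st$cur, s = st$s, e = st$e)
        st$k_remaining <- 0L
        st$finished <- TRUE
        break
      }
      if (st$passes >= n)
        stop("internal error: pass bound exceeded", call. = FALSE)
      src <- st$bufs[[st$cur]]
      pivot <- select_pivot(src$values[st$s:st$e])
      if (instrument)
        input_snapshot <- list(values = src$values[st$s:st$e],
                               indices = src$indices[st$s:st$e])
      res <- if (mode == "block")
        partition_row_block(st, pivot, group_count)
      else
        partition_row(st, pivot)
      if (instrument) {
        out <- st$bufs[[st$cur]]
        trace[[length(trace) + 1L]] <- list(
          type = "pivot", pivot = pivot, input = input_snapshot,
          less = list(values = out$values[seq2(st$s, st$s + res$n_less - 1L)],
                      indices = out$indices[seq2(st$s, st$s + res$n_less - 1L)]),
          geq = list(values = out$values[seq2(st$s + res$n_less, st$e)],
                     indices = out$indices[seq2(st$s + res$n_less, st$e)]))
      }
      if (res$n_less == 0L) {
        resolve_degenerate(st, pivot)
        if (instrument)
          trace[[length(trace) + 1L]] <- list(type = "degenerate", pivot = pivot)
      } else {
        selection_step(st, res)
      }
    }
  })
  # gather confirmed ranges from the reference stack
  total <- sum(vapply(st$stack, function(en) en$e - en$s + 1L, integer(1)))
  if (total != k)
    stop("internal error: reference stack holds ", total,
         " elements, expected ", k, call. = FALSE)
  vals <- numeric(k); idx <- integer(k); at <- 0L
  for (en in st$stack) {
    b <- st$bufs[[en$buf]]
    ln <- en$e - en$s + 1L
    vals[at + seq_len(ln)] <- b$values[en$s:en$e]
    idx[at + seq_len(ln)] <- b$indices[en$s:en$e]
    at <- at + ln
  }
  # canonicalize boundary ties to lowest-original-index-first
  v_max <- max(vals)
  t_boundary <- sum(vals == v_max)
  cand <- st$orig_indices[st$orig_values == v_max]
  keep <- vals < v_max
  vals <- c(vals[keep], rep(v_max, t_boundary))
  idx <- c(idx[keep], sort(cand)[seq_len(t_boundary)])
  ord <- order(vals, idx)
  list(values = vals[ord], indices = idx[ord], passes = st$passes,
       trace = trace)
}

# seq() that is empty when to < from (used for trace slices)
seq2 <- function(from, to) if (to < from) integer(0) else seq.int(from, to)

# deterministic per-row pivot-stream seed; depends only on the run seed and
# the row's absolute position, never on tiling or mode
.row_seed <- function(seed, global_row) {
  ((seed %% 2147483647) * 69069 + global_row * 104729) %% 2147483629 + 1
}

#' Select the k smallest entries of every row
#'
#' Runs the multi-query quickselect over each row of a distance matrix
#' independently: random pivots from a per-row seeded stream, 32-lane
#' ballot/popcount partitioning (warp mode) or interleaved lane groups with
#' a serial prefix sum (block mode), remaining-k accounting, and the
#' copy-avoiding reference stack. Each row's result is its k smallest
#' values with their original column indices, sorted ascending by value
#' (ties broken by lowest index).
#'
#' @param values Numeric matrix (rows are independent selection problems),
#'   or a single numeric vector treated as one row.
#' @param k Number of smallest entries per row, `1..ncol`.
#' @param mode `"warp"` (one lane group) or `"block"` (interleaved groups).
#' @param group_count Lane groups for block mode, 1..16.
#' @param seed Integer seed for the pivot streams.
#' @param indices Optional integer vector of original 0-based column ids
#'   (defaults to `0..n-1`).
#' @param row_offset Absolute index of the first row (used by tiled callers
#'   so per-row pivot streams do not depend on tile boundaries).
#' @param instrument Record a per-pass trace (pivot, input, both output
#'   sides) for every row; used by conservation checks.
#' @return A list with `indices` and `values` (m×k matrices), `passes`
#'   (per-row partition-pass counts), and `trace` when instrumented.
#' @examples
#' r <- multiselect_rows(rbind(c(9, 3, 7, 1, 5)), k = 2, seed = 1)
#' r$values   # 1 3
#' r$indices  # 3 1
#' @export
multiselect_rows <- function(values, k, mode = c("warp", "block"),
                             group_count = 4L, seed = 1L, indices = NULL,
                             row_offset = 0L, instrument = FALSE) {
  mode <- match.arg(mode)
  if (is.vector(values)) values <- matrix(values, nrow = 1L)
  m <- nrow(values); n <- ncol(values)
  k <- as.integer(k)
  if (is.na(k) || k < 1L || k > n)
    stop("`k` must be in 1..", n, call. = FALSE)
  bad <- which(!apply(values, 1L, function(r) all(is.finite(r))))
  if (length(bad))
    stop("non-finite distance values in row ", bad[1L], call. = FALSE)
  if (is.null(indices)) indices <- seq_len(n) - 1L
  out_i <- matrix(0L, m, k); out_v <- matrix(0, m, k)
  passes <- integer(m)
  trace <- if (instrument) vector("list", m) else NULL
  for (r in seq_len(m)) {
    rs <- .row_seed(seed, row_offset + r)
    res <- .multiselect_row(values[r, ], indices, k, rs, mode, group_count,
                            instrument)
    out_i[r, ] <- res$indices
    out_v[r, ] <- res$values
    passes[r] <- res$passes
    if (instrument) trace[[r]] <- res$trace
  }
  list(indices = out_i, values = out_v, passes = passes, trace = trace)
}
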