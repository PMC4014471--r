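# 32-lane partition primitives: a deterministic emulation of the warp-scale
# ballot / population-count machinery used to partition a segment of at most
# 32 (value, index) pairs around a pivot with exactly two contiguous writes.

.lane_env <- new.env(parent = emptyenv())

# 16-bit popcount lookup table, built once on first use.
.popc16 <- function() {
  if (is.null(.lane_env$popc16)) {
    tab <- 0L
    for (b in 1:16) tab <- c(tab, tab + 1L)   # doubling: popc(2x)=popc(x), popc(2x+1)=popc(x)+1
    .lane_env$popc16 <- tab
  }
  .lane_env$popc16
}

#' Lane word: a 32-bit ballot result
#'
#' A lane word packs one predicate bit per lane into an unsigned 32-bit
#' integer (held as a double, since R has no native unsigned 32-bit type).
#' Lane `i` owns bit `i`, with lane 0 at the least-significant bit. `width`
#' is the number of active lanes; bits at or above `width` must be clear,
#' which is how segments shorter than 32 (array tails) mask out inactive
#' lanes without sentinel values.
#'
#' @param bits Non-negative number below 2^32 with no bit set at or above
#'   `width`.
#' @param width Active lane count, an integer in 1..32.
#' @return An object of class `lane_word` with fields `bits` and `width`.
#' @seealso [lane_ballot()], [lane_offsets()]
#' @export
lane_word <- function(bits, width) {
  width <- as.integer(width)
  bits <- as.numeric(bits)
  if (length(width) != 1L || is.na(width) || width < 1L || width > 32L)
    stop("`width` must be a single integer in 1..32", call. = FALSE)
  if (length(bits) != 1L || is.na(bits) || bits < 0 || bits >= 2^32 || bits != floor(bits))
    stop("`bits` must be a single non-negative integer below 2^32", call. = FALSE)
  if (width < 32L && bits >= 2^width)
    stop("`bits` has a set bit at or above `width`", call. = FALSE)
  structure(list(bits = bits, width = width), class = "lane_word")
}

#' @export
print.lane_word <- function(x, ...) {
  pat <- paste(rev(as.integer((x$bits %/% 2^(0:(x$width - 1))) %% 2)), collapse = "")
  cat(sprintf("<lane_word width=%d bits=0b%s>\n", x$width, pat))
  invisible(x)
}

#' Warp ballot vote
#'
#' Packs a logical predicate vector (one entry per active lane) into a
#' [lane_word()]: bit `i` is set iff `predicates[i + 1]` is `TRUE`. This is
#' the warp voting operation that lets every lane see, in a single word,
#' which lanes hold elements on which side of the pivot.
#'
#' @param predicates Logical vector of length 1..32, no missing values.
#' @return A `lane_word` with `width = length(predicates)`.
#' @examples
#' lane_ballot(c(FALSE, TRUE, FALSE, TRUE))  # bits 0b1010
#' @export
lane_ballot <- function(predicates) {
  w <- length(predicates)
  if (!is.logical(predicates) || w < 1L || w > 32L || anyNA(predicates))
    stop("`predicates` must be a logical vector of length 1..32 without NA",
         call. = FALSE)
  lane_word(sum(2^(seq_len(w) - 1L)[predicates]), w)
}

#' Population count of a 32-bit word
#'
#' Counts the set bits of each element of `word`. Vectorized; accepts raw
#' numeric words or a single [lane_word()].
#'
#' @param word Numeric vector of values in `[0, 2^32)`, or a `lane_word`.
#' @return Integer vector of counts in 0..32.
#' @examples
#' lane_popc(c(0, 10, 2^32 - 1))  # 0, 2, 32
#' @export
lane_popc <- function(word) {
  if (inherits(word, "lane_word")) word <- word$bits
  word <- as.numeric(word)
  if (anyNA(word) || any(word < 0 | word >= 2^32 | word != floor(word)))
    stop("`word` entries must be integers in [0, 2^32)", call. = FALSE)
  tab <- .popc16()
  tab[word %% 65536 + 1L] + tab[word %/% 65536 + 1L]
}

#' Per-lane staged write offsets from a ballot word
#'
#' Given a ballot word under the convention set bit = element >= pivot, each
#' lane finds its write slot by masking off its own and all higher lanes and
#' popcounting the remainder — the emulated equivalent of the shift-and-popc
#' idiom. Lanes with a clear bit (element < pivot) receive a left-side
#' offset equal to the number of clear bits among lower lanes; lanes with a
#' set bit receive a right-side offset equal to the number of set bits among
#' lower lanes. Offsets on each side are a permutation of
#' `0..(side size - 1)`.
#'
#' @param word A [lane_word()].
#' @return A list with integer vectors `left_offsets` and `right_offsets`
#'   of length `width`; each lane has its offset on its own side and `NA`
#'   on the other.
#' @export
lane_offsets <- function(word) {
  if (!inherits(word, "lane_word")) stop("`word` must be a lane_word", call. = FALSE)
  w <- word$width
  lanes <- seq_len(w) - 1L
  low_mask <- word$bits %% 2^lanes          # bits of lanes strictly below lane i
  set_before <- lane_popc(low_mask)
  zero_before <- lanes - set_before
  is_set <- as.logical((word$bits %/% 2^lanes) %% 2)
  left <- ifelse(is_set, NA_integer_, zero_before)
  right <- ifelse(is_set, set_before, NA_integer_)
  list(left_offsets = as.integer(left), right_offsets = as.integer(right))
}

#' Partition cursor
#'
#' Running totals of elements written to each side of the pivot so far;
#' these play the role of the two global counters that tell each flushed
#' segment where in the destination buffer its two blocks land.
#'
#' @param less_count,geq_count Non-negative integers.
#' @return A list with class `partition_cursor`.
#' @export
partition_cursor <- function(less_count = 0L, geq_count = 0L) {
  less_count <- as.integer(less_count); geq_count <- as.integer(geq_count)
  if (is.na(less_count) || is.na(geq_count) || less_count < 0L || geq_count < 0L)
    stop("cursor counts must be non-negative integers", call. = FALSE)
  structure(list(less_count = less_count, geq_count = geq_count),
            class = "partition_cursor")
}

#' Partition one 32-wide segment around a pivot
#'
#' Stages a segment of at most 32 (value, index) pairs in a width-wide
#' scratch array — elements below the pivot packed from the left, elements
#' at or above it packed on the right, slots given by [lane_offsets()] —
#' then flushes it with exactly two contiguous block writes into the
#' destination sink: the less block at position `cursor$less_count` of the
#' less region (growing rightward from the window start) and the geq block
#' at `cursor$geq_count` from the window end (blocks growing leftward, lane
#' order kept within each block). Ties with the pivot go to the geq side.
#'
#' @param values,indices Equal-length vectors of 1..32 metric values and
#'   their original column indices.
#' @param pivot Pivot value.
#' @param cursor A [partition_cursor()] with the totals written so far.
#' @param sink An environment created by [partition_sink()] that owns the
#'   destination window.
#' @return The advanced `partition_cursor`. The sink's `writes` counter
#'   advances by the number of non-empty block writes (at most two).
#' @export
partition_segment <- function(values, indices, pivot, cursor, sink) {
  w <- length(values)
  if (w < 1L || w > 32L)
    stop("segment must hold 1..32 elements", call. = FALSE)
  if (length(indices) != w)
    stop("`values` and `indices` lengths differ", call. = FALSE)
  word <- lane_ballot(values >= pivot)
  offs <- lane_offsets(word)
  n_geq <- lane_popc(word)
  n_less <- w - n_geq

  # staged scratch: less lanes at left_offset, geq lanes right of them
  staged_v <- numeric(w); staged_i <- integer(w)
  less_lane <- which(!is.na(offs$left_offsets))
  geq_lane <- which(!is.na(offs$right_offsets))
  staged_v[offs$left_offsets[less_lane] + 1L] <- values[less_lane]
  staged_i[offs$left_offsets[less_lane] + 1L] <- indices[less_lane]
  staged_v[n_less + offs$right_offsets[geq_lane] + 1L] <- values[geq_lane]
  staged_i[n_less + offs$right_offsets[geq_lane] + 1L] <- indices[geq_lane]

  # flush: two contiguous writes into the sink's window
  if (n_less > 0L) {
    at <- sink$start + cursor$less_count + seq_len(n_less) - 1L
    if (at[n_less] >= sink$split_guard())
      stop("internal error: less side overflows its output range", call. = FALSE)
    sink$values[at] <- staged_v[seq_len(n_less)]
    sink$indices[at] <- staged_i[seq_len(n_less)]
    sink$writes <- sink$writes + 1L
  }
  if (n_geq > 0L) {
    at <- sink$end - cursor$geq_count - n_geq + seq_len(n_geq)
    if (at[1L] <= sink$start + cursor$less_count + n_less - 1L)
      stop("internal error: geq side overflows its output range", call. = FALSE)
    sink$values[at] <- staged_v[n_less + seq_len(n_geq)]
    sink$indices[at] <- staged_i[n_less + seq_len(n_geq)]
    sink$writes <- sink$writes + 1L
  }
  partition_cursor(cursor$less_count + n_less, cursor$geq_count + n_geq)
}

#' Destination sink for staged partition flushes
#'
#' Owns a destination window `[start, end]` (1-based, inclusive) over a pair
#' of value/index vectors, plus a counter of block writes issued. The less
#' region grows rightward from `start`; the geq region grows leftward from
#' `end`.
#'
#' @param length Window length (allocates fresh vectors), or pass existing
#'   vectors via `values`/`indices`.
#' @param start,end Window bounds; default the whole vectors.
#' @param values,indices Optional pre-existing destination vectors.
#' @return An environment with fields `values`, `indices`, `start`, `end`,
#'   `writes`.
#' @export
partition_sink <- function(length = NULL, values = NULL, indices = NULL,
                           start = 1L, end = NULL) {
  if (is.null(values)) values <- numeric(length)
  if (is.null(indices)) indices <- integer(base::length(values))
  if (is.null(end)) end <- base::length(values)
  e <- new.env(parent = emptyenv())
  e$values <- values; e$indices <- indices
  e$start <- as.integer(start); e$end <- as.integer(end)
  e$writes <- 0L
  # upper bound the less region may not cross (end of window + 1)
  e$split_guard <- function() e$end + 1L
  e
}
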