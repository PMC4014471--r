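# Loop-and-count oracles for the lane primitives and small row generators.
# These share no code with the package's vectorized implementations.

# per-lane loop over lower lanes: the literal definition of the offsets
naive_offsets <- function(bits) {
  w <- length(bits)
  left <- rep(NA_integer_, w)
  right <- rep(NA_integer_, w)
  for (i in seq_len(w)) {
    prior <- bits[seq_len(i - 1L)]
    if (bits[i]) right[i] <- sum(prior) else left[i] <- sum(!prior)
  }
  list(left_offsets = left, right_offsets = right)
}

word_bits <- function(value, width) as.logical((value %/% 2^(0:(width - 1))) %% 2)

# random selection rows in the regimes the engine must handle
random_row <- function(kind, n) {
  switch(kind,
    uniform = runif(n),
    clustered = {
      centers <- runif(4) * 100
      centers[sample.int(4, n, replace = TRUE)] + rnorm(n, sd = 0.1)
    },
    `duplicate-heavy` = sample(round(runif(max(2L, n %/% 20)), 3), n,
                               replace = TRUE),
    constant = rep(runif(1), n))
}

expect_matches_oracle <- function(sel, row_values, k, row = 1L) {
  want <- oracle_topk(row_values, k)
  expect_identical(sel$values[row, ], want$values)
  expect_identical(sel$indices[row, ], want$indices)
}
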