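---
title: "Exact k-NN graphs by multi-query quickselect: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Exact k-NN graphs by multi-query quickselect: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knnselect)
```

## The problem

Given a corpus of $n$ vectors $c_i \in \mathbb{R}^d$ and $m$ query vectors
$q_j$, the exact $k$-nearest-neighbor problem asks, for every query, for
the $k$ corpus vectors at smallest distance. When every corpus point is
also a query ($Q = C$) the result is the $k$-NN *graph* ($k$-NNG), a basic
ingredient of manifold learning, clustering, and expression-profile
similarity analysis (where the Pearson distance between gene or sample
profiles is the natural metric). In high dimension, spatial indexes
degrade to linear scans and the brute-force method — compute the full
$m \times n$ distance matrix, then select each row's $k$ smallest entries
— is the method of choice. This package implements that pipeline exactly,
with both stages shaped like their massively parallel originals: the
distance stage as one dense matrix product plus column reductions, and the
selection stage as a *multi-query quickselect* built on a deterministic
emulation of a 32-lane SIMD ("warp") partition primitive.

## Distance decomposition

All three metrics reduce to dot products and per-column reductions.
Writing $\|x\|$ for the Euclidean norm and $\bar x$ for the mean of a
vector's entries:

* **Euclidean**: $d(q,c) = \|q - c\| = \sqrt{\|q\|^2 - 2\,q\cdot c + \|c\|^2}$.
* **Cosine**: $d(q,c) = 1 - \dfrac{q \cdot c}{\|q\|\,\|c\|} \in [0,2]$.
* **Pearson**: $d(q,c) = 1 - r(q,c)$, which equals the cosine distance of
  the mean-centered vectors $q - \bar q$, $c - \bar c$; the sample-vs-
  population normalization of the variance cancels in $r$, so the distance
  does not depend on that convention.

The $m \times n$ block of dot products is one dense product
$Q^{\mathsf T} C$; means and squared norms are column reductions computed
in a single pass (`column_stats()`). Because the $\|q\|^2$ term is
constant within a query row, selection for the Euclidean metric runs on
the *reduced* comparison values $\|c\|^2 - 2\,q\cdot c$
(`euclidean_reduced()`), which order each row identically; true distances
are restored afterwards for reporting, clamping the tiny negative residue
that floating-point cancellation can leave before the square root. When
neighbors are needed in both directions, the reverse dot-product block is
the transpose of the forward one (`reciprocal_by_transpose()`), so the
matrix product is paid for once.

Degenerate columns are hard errors by name: a zero-norm column under the
cosine metric and a constant column under Pearson have no defined
direction or correlation, and silently propagating `NaN` into a neighbor
graph is never acceptable.

### Tiling and numerical exactness

`tiled_distance_rows()` evaluates the distance matrix in consecutive
blocks of `tile_rows` queries so the full $m \times n$ matrix need not be
materialized. The package guarantees that every tiling yields
*bit-identical* rows. Optimized BLAS libraries do not offer that property
— they switch kernels with the operand shape, so a one-column product can
differ in the last ulp from the same row of a full product — so the tiled
path accumulates each query's dot products in a fixed order independent of
the tile shape. The exported `dot_matrix()` keeps the BLAS product for
one-shot use, where bit-stability across callings is not part of the
contract.

## The selection stage

Each row of the distance matrix is an independent selection problem:
find the $k$ smallest of $n$ values while carrying each value's original
column index. The engine is an iterative quickselect over a pair of
buffers (input and auxiliary):

1. choose a pivot uniformly at random from the active range;
2. partition the active range into the other buffer — values below the
   pivot packed left, values at or above it packed right (ties go right);
3. if the left side fits in the remaining $\hat k$, push it onto the
   **reference stack** as confirmed output, subtract its length from
   $\hat k$, and continue in the right side; otherwise discard the right
   side and continue in the left;
4. stop when $\hat k = 0$ (or when the active range's length equals
   $\hat k$, in which case the whole range is confirmed).

The reference stack records `(buffer, start, end)` triples, so confirmed
ranges are never copied between buffers. At termination the stack holds
exactly $k$ elements; they are gathered, and the final row is sorted
ascending by value with ties broken by the lowest original index.

### The 32-lane partition primitive

The partition step is built from an emulation of the warp-scale machinery
of data-parallel selection. A segment of at most 32 `(value, index)` pairs
is processed at once:

* `lane_ballot()` packs the predicate *value ≥ pivot* into a 32-bit word,
  one bit per lane (lane 0 at the least-significant bit — the convention
  is arbitrary as long as it is fixed, and any fixed choice produces the
  same partition);
* each lane finds its write slot by masking off its own and all higher
  lanes and popcounting the rest (`lane_offsets()` / `lane_popc()`),
  giving, on each side, a permutation of $0..(\text{side size}-1)$;
* the staged segment is flushed with exactly **two contiguous block
  writes** into the destination window, at positions given by two running
  counters (`partition_cursor()`): the below-pivot region grows rightward
  from the window start, the at-or-above region grows leftward from its
  end.

Segments shorter than 32 (array tails) simply use a smaller ballot width;
no sentinel values are injected, so sentinels can never collide with real
data. Within a flushed segment each side keeps lane order, a stability
choice that downstream code does not rely on (final ordering is imposed at
the end).

In **block mode** (`partition_row_block()`), the active range is dealt
round-robin into up to 16 interleaved lane-group streams — the emulated
analogue of multiple warps in one thread block. Each group stages its
stream exactly as above; a *serial* prefix sum over the per-group side
counts then assigns every group its block-level write base. With one
group, block mode is byte-identical to warp mode, and for any group count
the output is multiset-identical; the two modes exist because the
originals trade per-query parallelism against the number of concurrent
queries, a scheduling concern that does not affect results here.

### Ties, duplicates, and termination

The $\ge$ predicate sends pivot-equal elements right, so a range of
identical values never shrinks: plain quickselect would loop forever on a
constant row, and a 99%-duplicate row could exceed any reasonable pass
budget waiting for a lucky pivot. Whenever a partition produces an empty
left side (the pivot is the range minimum), `resolve_degenerate()` counts
the elements exactly equal to the pivot, confirms as many of them as the
remaining $\hat k$ needs, and continues on the strictly-greater remainder.
Every round therefore removes at least one element from the active range,
which gives a hard bound of *passes ≤ row length* on any input; on
distinct-valued rows the guard can still fire (the pivot is the unique
minimum with probability $1/\text{len}$) and then simply confirms that
minimum, which is both correct and progress. With uniform random pivots
the expected pass count is logarithmic; the test suite checks a median of
at most $4\log_2 n$ over its random campaign.

Which indices are reported when equal values straddle the $k$ boundary is
inherently arbitrary; the engine canonicalizes to *lowest index first* by
one linear scan of the original row. This makes the full result — not
just the value multiset — independent of pivot history, and hence
identical across warp/block modes, group counts, and tilings.

### Determinism

Every pivot stream is seeded from the pair (run seed, absolute row
index), so results are bit-identical across runs, across `tile_rows`
choices (the absolute row index does not depend on tile boundaries), and
across execution modes. The seed is recorded in the JSON sidecar of every
output, and distances are serialized as `%.17g`, which round-trips
doubles exactly — two runs with the same configuration produce
byte-identical files.

## Synthetic data and oracles

`generate_fixture()` reproduces the regime the method is designed to be
exercised under — i.i.d. uniform random vectors in $[0,1)^d$ with
attached indices — plus three stress variants: Gaussian clusters around
centers spaced at least ten cluster radii apart (used to check that
nearest-neighbor edges stay within clusters), duplicate-heavy corpora
(exact copies of a few template columns, stressing tie handling), and
constant corpora (every distance row is a single repeated value). Default
shapes are desk-sized ($n \le 4096$, $m \le 512$ in the shipped test
campaigns) — large enough to exercise dozens of partition passes per row
while keeping the full randomized suite in seconds on one CPU; the
structure of the regime, not the raw scale, is what the correctness
properties depend on.

What the generators do *not* emulate: real expression matrices are not
i.i.d. uniform — they have correlated features, heavy-tailed counts, and
batch structure. Passing tests demonstrate exact agreement with the
brute-force definition of the $k$-NNG under every input regime tested,
including adversarial duplicate structure; they are not evidence about
biological interpretability of any particular metric on any particular
dataset.

The oracles are deliberately naive: `oracle_topk()` fully sorts a row
(stable in `(value, index)`) and `oracle_distance()` evaluates the
textbook formulas pair by pair with explicit loops (Pearson through
`stats::cor()`). They share no code with the engine or the decomposition,
which is what makes the equivalence tests meaningful.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k` | 8 | neighbors per query; selection cost grows only mildly with `k` |
| `metric` | `euclidean` | `euclidean`, `cosine`, or `pearson` |
| `mode` | `auto` | `warp` when `m >= warp_threshold` (default 448, one row per emulated warp slot), else `block`; results are identical either way |
| `group_count` | 4 | interleaved lane groups per row in block mode (1–16) |
| `tile_rows` | 64 | query rows per distance tile; memory, never results |
| `seed` | 1 | pivot-stream seed; recorded in output metadata |
| `exclude_self` | `TRUE` | drop each point from its own neighbor list in `build_knng()` (selection runs with $k+1$, then removes self) |

Self-exclusion is the graph-theoretic convention; with exact duplicate
points the twin, not the point itself, may occupy the distance-zero slot,
and the removal logic handles either case. Median-of-three pivoting is
available in `select_pivot()` but off by default: the uniform-pivot
analysis is the one the pass-count expectations are calibrated against.

## Known limitations

* The engine emulates the *semantics* of the two-level parallel scheme —
  ballot words, staged two-write flushes, prefix-summed group bases, the
  reference stack — not its speed; everything executes serially in R.
* Inputs are densified in memory; there is no out-of-core batching for
  corpora that exceed RAM, and no sparse fast path.
* Only the three metrics above are provided; Manhattan or Mahalanobis
  distances would need their own decompositions.
* Approximate methods are out of scope by design: every result is exact
  and oracle-checkable.
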