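# knnselect

Exact k-nearest-neighbor graphs for high-dimensional vectors, built the
brute-force way — and checked against brute-force oracles.

In high dimension, tree and hashing indexes degrade to linear scans, so
the preferred *exact* k-NN method is to compute the full m×n distance
matrix and select each row's k smallest entries. `knnselect` implements
both stages in the shape of their massively parallel originals:

* **Distances** (Euclidean, Cosine, Pearson) by the dot-product/norm
  decomposition: one dense matrix product `t(Q) %*% C` plus per-column
  means and squared norms. For Euclidean rows, selection runs on the
  *reduced* comparison values `||c||² − 2 q·c` (the per-query `||q||²`
  term is a row constant and cannot change the ordering); Pearson distance
  `1 − r(q, c)` is computed as the Cosine distance of the mean-centered
  columns.
* **Selection** by a multi-query quickselect: each row is partitioned
  iteratively around random pivots, with the partition step built from a
  deterministic 32-lane emulation of the SIMD warp primitives — a ballot
  word packing the `value ≥ pivot` predicate one bit per lane,
  popcount-derived per-lane write offsets, staged segments flushed with
  exactly two contiguous writes — plus a block mode that combines up to 16
  interleaved lane groups by a serial prefix sum, and a reference stack
  that confirms output ranges without copying buffers.

Results are exact and fully deterministic: a fixed seed gives
byte-identical output regardless of execution mode, lane-group count, or
distance tiling. Typical users are bioinformaticians and ML practitioners
who need a trustworthy exact k-NNG (for example over expression profiles
with the Pearson metric) or a reference to validate approximate methods
against.

## Worked example

Sixty expression-like profiles over fifty features; build the 4-NN graph
under the Pearson metric:

```r
library(knnselect)
set.seed(42)
expr <- matrix(rnorm(50 * 60), nrow = 50)   # 50 features x 60 profiles
g <- build_knng(expr, knn_config("pearson", k = 4, seed = 7))
g
#> <knn_result> 60 queries x 60 corpus vectors, k = 4 (pearson, block mode)
#>   self excluded; seed 7; partition passes: median 6.0, max 11
#>   distances: true metric values
head(tidy(g), 5)
#> # A tibble: 5 x 4
#>   query_id neighbor_id  rank distance
#>      <int>       <int> <int>    <dbl>
#> 1        0           8     1    0.710
#> 2        0          19     2    0.711
#> 3        0          47     3    0.718
#> 4        0          51     4    0.757
#> 5        1          31     1    0.754
```

Each tidy row is one directed edge of the graph: profile 0's nearest
neighbor is profile 8 at Pearson distance 0.710 (correlation ≈ 0.29 —
these are independent Gaussian profiles, so no strong correlations exist
to find). `glance(g)` returns a one-row summary (shape, metric, mode,
seed, 240 edges, pass statistics) and `autoplot(g)` plots the distance
distribution by neighbor rank. `write_neighbors(g, "out")` writes the
edge list plus a JSON sidecar with the full run configuration;
`build_knn(Q, C, config)` searches a separate query set, and
`generate_fixture()` / `oracle_topk()` / `oracle_distance()` provide
synthetic inputs and independent brute-force ground truth.

A shell interface with the same capabilities is installed at
`system.file("cli", "knnselect", package = "knnselect")`, with subcommands
`knn`, `knng`, `fixtures`, and `selftest`.

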