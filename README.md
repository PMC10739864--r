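# nbflow

Non-backtracking spectral community detection for sparse undirected
networks, written for the regime where classical spectral methods break:
structural connectomes and other biological graphs whose mean degree stays
small while the network grows. In that regime the leading eigenvectors of
the adjacency, Laplacian and modularity matrices localise on hubs; the
transfer operators of *non-backtracking* walks do not, and their isolated
eigenvalues keep encoding community structure all the way down to the
information-theoretic detectability limit.

## What the package computes

For a simple undirected graph with adjacency `A`, degrees `d`, `N` nodes
and `C` edges, `nbflow` builds the Hashimoto matrix `B` on the `M = 2C`
directed edges (`B[(i→j),(k→l)] = 1` iff `j = k`, `l ≠ i`) and its
row-stochastic flow normalisation

```
F[(i→j),(k→l)] = δ_jk (1 − δ_li) / (d_j − 1),
```

whose spectrum splits into a bulk confined to the complex disc of radius
`r = sqrt(⟨d/(d−1)⟩ / ⟨d⟩)` plus isolated real eigenvalues — one per
community. Eigenvectors are projected from edges to nodes by the in-flow
sum `u_i = Σ_j A_ij v_{j→i}` and clustered with k-means. The number of
clusters a given sparse graph can actually support is selected with the
SBM detectability condition

```
c_in − c_out > k √c,   c_in = N·w_in,  c_out = N·w_out,  c = (c_in + c_out)/2,
```

evaluated on affinities re-estimated from the graph's own partitions at
each `k` (`select_kmax()`). A planted-SBM generator and benchmark compare
the flow operator against the normalized Laplacian, Laplacian and
modularity pipelines by adjusted mutual information (AMI), and partition
metrics (Newman Q, MI/AMI with exact permutation-model expectation,
hypergeometric overlap enrichment, cluster cosine similarity) support the
downstream biology.

## Worked example

```r
library(nbflow)

# a connectome-sized planted SBM: 7 blocks, N = 279, w_in/w_out = 4.4
sbm <- generate_sbm(connectome_sizes(), w_in = 0.22, w_out = 0.05, seed = 1)
g   <- preprocess_graph(sbm$graph)      # drop isolated nodes, keep giant component

sp <- nb_spectrum(g, kind = "flow", n_eig = 24, seed = 1)
sp
#> <nb_spectrum> flow matrix, 24 eigenvalues (M = 5864)
#>   bulk radius r = 0.22383; isolated eigenvalues: 4
#>   1.0000, 0.3936, 0.3591, 0.2927

fit <- spectral_cluster(g, operator = "flow", k = 7, seed = 1)
glance(fit)
#> # A tibble: 1 × 9
#>   operator     k n_nodes n_pruned inertia q_score min_size max_size  seed
#>   <chr>    <int>   <int>    <int>   <dbl>   <dbl>    <int>    <int> <int>
#> 1 flow         7     279        0    29.9   0.268       28       53     1

adjusted_mutual_information(fit, sbm$partition)
#> [1] 0.7819
```

At `w_in/w_out = 4.4` the graph sits close to its detectability limit —
only 4 of the 7 community eigenvalues clear the bulk edge, and recovery is
partial (AMI ≈ 0.78), which is exactly the regime where the flow operator
is worth its extra machinery. Far above threshold (`w_in = 0.6`) the same
pipeline recovers the blocks at AMI > 0.95.

The detectability scan and the benchmark both return plain tibbles:

```r
km <- select_kmax(g, k_range = 2:6, seed = 1)
autoplot(km)          # gap vs k√c curves; crossing = resolution limit

bench <- run_benchmark(w_in_grid = c(0.1, 0.22, 0.6), replicates = 20,
                       operators = c("flow", "norm_laplacian"), base_seed = 1)
tidy(bench)
```

A thin command-line front-end wraps the same functions
(`system.file("cli", "nbflow.R", package = "nbflow")`) with subcommands
`cluster`, `spectrum`, `kmax`, `bench`, `compare`, `enrich`, `run` and
`fixture`, reading edge lists (`source,target[,type]` CSV/TSV, e.g. a
connectome's chemical-synapse subgraph via `--type chemical`) and writing
CSV tables.

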