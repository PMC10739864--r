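---
title: "Non-backtracking spectral community detection in sparse networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-backtracking spectral community detection in sparse networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nbflow)
```

## The problem

Sparse biological networks — structural connectomes above all — sit in a
regime where classical spectral community detection degrades. When the mean
degree is a constant rather than a growing function of the network size, the
leading eigenvectors of the adjacency, Laplacian and modularity matrices
localise on high-degree vertices (hubs) instead of on the cyclic structure
that defines communities, and recovery fails well before the
information-theoretic limit. Non-backtracking random walks avoid this
failure: a walker that may never immediately reverse its last step cannot
rattle back and forth across a hub, so the spectrum of its transfer operator
keeps a clean separation between a structureless "bulk" and a handful of
isolated eigenvalues that encode the mesoscopic structure.

`nbflow` implements this programme end to end: the edge-space operators,
their spectra, the node embedding and k-means step, a detectability test
that decides how many clusters a given sparse graph can support, a planted
stochastic-block-model (SBM) simulator and operator-comparison benchmark,
and the partition-quality and agreement metrics needed to interpret the
results on annotated networks such as the *C. elegans* connectome.

## Operators

For an undirected simple graph with adjacency $A$, degrees $d_i$, $N$ nodes
and $C$ edges, the package builds:

* the **Hashimoto (non-backtracking) matrix** $B$ on the $M = 2C$ directed
  edges, $B_{i \to j,\, k \to l} = 1$ iff $j = k$ and $l \neq i$ — its
  powers count non-backtracking walks;
* the **flow matrix** $F_{i \to j,\, k \to l} =
  \delta_{jk}(1 - \delta_{li}) / (d_j - 1)$, the row-stochastic
  normalisation of $B$ that conserves the walker's probability flow;
* the **modularity matrix** $M = A - dd^\top / 2C$;
* the **Laplacian** $L = D - A$ and the **symmetric normalized Laplacian**
  $L_\mathrm{norm} = I - D^{-1/2} A D^{-1/2}$.

The bulk of the flow spectrum lies inside the complex disc of radius
$r = \sqrt{\langle d(d-1)^{-1}\rangle / \langle d \rangle}$; real
eigenvalues outside that disc are *isolated*, and their count estimates the
number of communities. Because $F$ divides by $d_j - 1$, the flow matrix is
built on the graph's 2-core; hanging trees are invisible to non-backtracking
walks anyway, and the peeled vertices are re-attached after clustering
(below).

Eigenvectors of $F$ live on directed edges. They are translated to nodes by
summing the in-flow, $u_i = \sum_j A_{ij} v_{j \to i}$; for the trivial
Perron vector ($v \equiv 1$) this returns exactly the degree vector, which
is why the trivial eigenvector is dropped from the default embedding — it
carries degree information, not community information.

## The clustering pipeline

`spectral_cluster()` gives all four operators the same front-end. For a
requested cluster count $k$:

* flow / Hashimoto: eigenvectors $2..k$ by descending real part, projected
  to nodes. Eigensolvers return vectors up to a global complex phase; each
  vector is rotated by the phase that maximises its real norm, and isolated
  eigenvectors are checked to be numerically real afterwards (residual
  imaginary norm below $10^{-6}$). A complex-conjugate pair contributes the
  real and imaginary parts of one member as two real coordinates.
* modularity: leading $k-1$ eigenvectors by algebraic eigenvalue.
* Laplacians: eigenvectors $2..k$ by ascending eigenvalue.

k-means with 100 random restarts (Hartigan–Wong, 300 iterations, best
within-cluster sum of squares kept, seed exposed) partitions the embedding.
We use base R's canonical k-means with many random restarts rather than a
k-means++ initialiser; at these problem sizes the restart budget makes the
initialisation scheme immaterial, and the seed contract — identical graph
and seed, identical partition — is what matters for reproducibility.

Vertices peeled with the 2-core are then attached to the cluster holding the
plurality of their already-labelled neighbours (ties towards the lowest
cluster label), sweeping repeatedly so chains of pendant vertices resolve
outward-in. How out-of-core vertices should be labelled is genuinely open —
the operator itself says nothing about them — and the plurality rule is this
package's choice.

## Detectability and the choice of k

A planted SBM with intra/inter connection probabilities $w_{in}, w_{out}$
and rescaled affinities $c_{in} = N w_{in}$, $c_{out} = N w_{out}$,
$c = (c_{in} + c_{out})/2$ admits asymptotic recovery of $k$ equal blocks
only when

$$ c_{in} - c_{out} > k \sqrt{c}. $$

`estimate_affinities()` estimates $w_{in}, w_{out}$ from any partition as
pooled intra- and inter-cluster edge densities (singleton clusters are
excluded from the intra denominator), and `select_kmax()` scans
$k = 2, 3, \ldots$, clustering afresh at each $k$ and returning the largest
$k$ whose estimated affinities still satisfy the condition. The two
diagnostic curves — the affinity gap and the threshold $k\sqrt{c}$ — are
returned as a table and plotted by `autoplot()`; their crossing is the
resolution limit of the data. We use $c = (c_{in} + c_{out})/2$ exactly as
written above, although a $k$-block SBM's mean degree would weight
$c_{out}$ by $k - 1$; the definition is kept for consistency with the
detectability condition as stated, and the closed-form diagnostic
$(\hat w_{in} - \hat w_{out})/\bar w \cdot \sqrt{N}$ is reported only as a
column of the scan table.

Two empirical caveats, both visible in the package's own tests. First, the
affinities are estimated on an *optimised* partition, so on a completely
structureless graph an optimised bisection overfits density fluctuations
(the same phenomenon as the positive modularity of random graphs) and the
condition can pass at $k = 2$ even when no structure exists. Second, when
the scan range exceeds the number of isolated eigenvalues, over-split
partitions remain near-refinements of the true blocks — k-means may even
carve denser sub-blocks — so the affinity gap does not collapse at the true
$k$; the scan terminates where the rising threshold $k\sqrt{c}$ overtakes
the roughly constant gap. On a strong three-block SBM this happens around
$k \approx (c_{in} - c_{out})/\sqrt{c}$, i.e. the selected $k_{max}$ is an
upper resolution bound, not a consistent estimator of the planted block
count. Within the regime the method is designed for — scanning up to the
isolated-eigenvalue count of a real sparse network — the two caveats do not
bite.

## The SBM generator and benchmark

`generate_sbm()` draws every intra-block pair independently with probability
`w_in` and every inter-block pair with `w_out` (uniform planted partition
model, no self-loops), reproducibly from a seed. `run_benchmark()` sweeps
`w_in`, generating fresh SBMs per replicate, clustering the largest
component with each operator at the true $k$ and scoring adjusted mutual
information against the planted labels; out-of-component nodes enter the
AMI as singleton clusters, since sparse samples near the threshold are
frequently disconnected.

The default conditions mirror a small sparse connectome: $N = 279$ nodes in
seven blocks of sizes $(55, 50, 45, 40, 35, 30, 24)$, $w_{out} = 0.05$, and
a 12-point `w_in` grid over $[0.05, 0.6]$ passing through the empirically
relevant ratio $w_{in}/w_{out} \approx 4.4$. The block sizes are a
configuration default, not a constant: any size vector is accepted. The
generator emulates the size, density and block structure of connectome-like
graphs but none of their other features — no degree correction, no
weighted or directed edges, no spatial constraints — so benchmark results
transfer to real data only insofar as the planted-partition model does.

At the defaults, 200 replicates per grid point reproduce the full benchmark
in about an hour on one core; the package's tests and acceptance script run
a single grid point ($w_{in} = 0.22$) at 50 replicates, which resolves the
operator ordering to within about $\pm 0.01$ AMI in a few minutes.

## Metrics

* `q_score()`: Newman modularity
  $Q = \frac{1}{2C}\sum_{ij}\left(A_{ij} - \frac{d_i d_j}{2C}\right)
  \delta_{g_i g_j}$ over ordered pairs.
* `mutual_information()` / `adjusted_mutual_information()`: contingency
  based, natural logarithm (nats). The AMI uses the exact expectation of MI
  under the fixed-marginals permutation model (a hypergeometric sum, not
  Monte-Carlo) and normalises by $\max\{H(U), H(V)\} - E\{MI\}$, so chance
  agreement scores 0 and identical partitions 1; two single-cluster
  partitions are identical and return 1 by convention.
* `overlap_enrichment()`: one-sided hypergeometric over-representation
  p-value per (cluster, annotation category), computed on the universe of
  nodes present in both inputs; raw p-values, no multiple-testing
  correction. The choice of test is this package's; for connectome-style
  analyses the annotation categories (ganglia, functional groups,
  contactome strata) are consumed as plain `node,label` tables.
* `partition_cosine()`: clusters (optionally merged into named
  compartments) as binary membership indicators over the union node set;
  pairwise cosines `overlap / sqrt(size_u * size_v)`.

## Numerical choices

* **Eigensolves.** Edge operators are sparse $M \times M$ with
  $M = 2C \sim 10^4$ for connectome-scale graphs; the package uses an
  Arnoldi largest-real-part solve (compiled via RcppArmadillo) requesting
  `max(2k, 24)` eigenpairs with a Krylov subspace several times larger, and
  escalates the subspace and iteration cap on partial convergence. Matrices
  with $M \le 400$ (and node operators, $N \le 2000$ in practice here) are
  solved densely. A dense/sparse agreement check to $10^{-8}$ on isolated
  eigenvalues is part of the test-suite.
* **Isolated eigenvalues.** Relative imaginary tolerance $10^{-6}$, margin
  2% above the bulk radius; the trivial Perron eigenvalue is always
  classified isolated, since for regular graphs it sits exactly on the
  bulk circle.
* **Determinism.** Every stochastic step (SBM sampling, Arnoldi start
  vector, k-means restarts) draws from R's RNG under an explicit seed;
  benchmark cell seeds are derived from the master seed by one
  `sample.int()` call, so any cell can be regenerated in isolation.
* **Degenerate inputs.** Self-loops are dropped with a warning (the
  operators are defined on distinct-endpoint edges); graphs whose 2-core is
  empty (trees) cannot carry non-backtracking flow and are rejected with an
  instructive error; edgeless graphs fail fast in every constructor.

## Problem sizes in the test-suite

The tests and the acceptance script are sized for a desk run: walk-count
oracles enumerate graphs of at most 8 nodes; recovery and detectability
checks use $N = 300$ three-block SBMs over 20 seeds; the operator
comparison uses the connectome-sized seven-block configuration at
$w_{in} = 0.22$ with 50 replicates. These sizes were chosen so that every
claim the package makes about itself is recomputed from scratch in minutes
while keeping the Monte-Carlo error comfortably inside each test's
tolerance.

## Known limitations

* Weighted, directed and degree-corrected models are out of scope; the
  generator and operators treat simple unweighted graphs only.
* The detectability scan inherits the overfitting caveats described above;
  treat `k_max` as the resolution limit of the data under the planted-SBM
  lens, not as a model-selection criterion.
* Near the detectability threshold the community eigenvalues approach the
  bulk edge and may appear as near-real conjugate pairs; the embedding
  handles them, but cluster assignments there are intrinsically noisy — as
  the benchmark's phase-transition shape shows.
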