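#' Newman modularity Q of a partition
#'
#' `Q = (1/2C) * sum_ij (A_ij - d_i d_j / 2C) * delta(g_i, g_j)` over ordered
#' node pairs: the intra-cluster edge excess over the degree-preserving null
#' model. Lies in `[-1, 1)`; 0 for the one-cluster partition.
#'
#' @param graph An igraph object with at least one edge.
#' @param partition A partition covering the graph (see [as_partition()]).
#' @return A scalar.
#' @export
q_score <- function(graph, partition) {
  C <- igraph::ecount(graph)
  if (C == 0L) abort("q_score of an edgeless graph")
  nodes <- graph_nodes(graph)
  lab <- partition_labels(partition, nodes)
  deg <- igraph::degree(graph)

  el <- igraph::as_edgelist(graph)
  li <- lab[match(el[, 1], nodes)]
  lj <- lab[match(el[, 2], nodes)]
  intra <- sum(li == lj)                         # undirected intra edges
  deg_tot <- vapply(split(deg, lab), sum, numeric(1))
  intra / C - sum((deg_tot / (2 * C))^2)
}

# contingency counts between two partitions restricted to their common nodes
contingency <- function(U, V) {
  u <- as_partition(U)
  v <- as_partition(V)
  common <- intersect(u$node, v$node)
  if (length(common) == 0L) abort("partitions share no nodes")
  lu <- u$cluster[match(common, u$node)]
  lv <- v$cluster[match(common, v$node)]
  table(factor(lu), factor(lv))
}

#' Mutual information between two partitions
#'
#' `MI(U, V) = sum_ij P_UV(i,j) log( P_UV(i,j) / (P_U(i) P_V(j)) )` from the
#' contingency table of the common node set, in nats (natural log). Always
#' `0 <= MI <= min(H(U), H(V))`.
#'
#' @param U,V Partitions over the same node set (see [as_partition()]).
#' @return A scalar (nats).
#' @export
mutual_information <- function(U, V) {
  tab <- contingency(U, V)
  n <- sum(tab)
  p <- tab / n
  pu <- rowSums(p)
  pv <- colSums(p)
  terms <- p * log(p / outer(pu, pv))
  sum(terms[tab > 0])
}

partition_entropy <- function(sizes, n) {
  p <- sizes[sizes > 0] / n
  -sum(p * log(p))
}

# exact expected MI under the permutation (hypergeometric, fixed-marginals)
# model
expected_mi <- function(tab) {
  n <- sum(tab)
  a <- rowSums(tab)
  b <- colSums(tab)
  emi <- 0
  for (ai in a) {
    for (bj in b) {
      lo <- max(1, ai + bj - n)
      hi <- min(ai, bj)
      if (hi < lo) next
      nij <- lo:hi
      w <- stats::dhyper(nij, ai, n - ai, bj)
      emi <- emi + sum(w * (nij / n) * log(n * nij / (ai * bj)))
    }
  }
  emi
}

#' Adjusted mutual information between two partitions
#'
#' `AMI = (MI - E[MI]) / (max(H(U), H(V)) - E[MI])`, where `E[MI]` is the
#' exact expectation of the mutual information under random permutation of
#' node labels with both sets of cluster sizes held fixed (hypergeometric
#' model). AMI is 1 for identical partitions and centred at 0 for chance
#' agreement; it is invariant to cluster relabelling and to the logarithm
#' base. When both partitions are trivial (a single cluster each) the two
#' partitions are identical and 1 is returned by convention.
#'
#' @inheritParams mutual_information
#' @return A scalar in `[-1, 1]`.
#' @export
adjusted_mutual_information <- function(U, V) {
  tab <- contingency(U, V)
  n <- sum(tab)
  mi <- {
    p <- tab / n
    terms <- p * log(p / outer(rowSums(p), colSums(p)))
    sum(terms[tab > 0])
  }
  hu <- partition_entropy(rowSums(tab), n)
  hv <- partition_entropy(colSums(tab), n)
  emi <- expected_mi(tab)
  denom <- max(hu, hv) - emi
  if (abs(denom) < .Machine$double.eps * 64) {
    # both partitions trivial: identical by construction
    return(1)
  }
  (mi - emi) / denom
}

#' Hypergeometric over-representation of annotation categories in clusters
#'
#' For every (cluster, category) pair, counts the overlap within the universe
#' of nodes present in both the partition and the annotation (unannotated
#' nodes are dropped with a message) and computes the one-sided
#' hypergeometric tail p-value for over-representation. Raw p-values are
#' reported without multiple-testing correction.
#'
#' @param partition A partition (see [as_partition()]).
#' @param annotation A tibble with columns `node`, `label` (see
#'   [read_annotation()]).
#' @return A tibble with columns `cluster`, `category`, `overlap`,
#'   `cluster_size`, `category_size`, `universe`, `expected`, `p_value`.
#' @export
overlap_enrichment <- function(partition, annotation) {
  p <- as_partition(partition)
  ann <- tibble(node = as.character(annotation$node),
                label = as.character(annotation$label))
  common <- intersect(p$node, ann$node)
  if (length(common) == 0L) abort("no annotated nodes found in the partition")
  dropped <- length(union(p$node, ann$node)) - length(common)
  if (dropped > 0L) {
    inform(paste0("overlap_enrichment: universe restricted to ", length(common),
                  " nodes (", dropped, " without both cluster and label dropped)"))
  }
  lu <- p$cluster[match(common, p$node)]
  lv <- ann$label[match(common, ann$node)]
  tab <- table(factor(lu), factor(lv))
  n <- sum(tab)
  cs <- rowSums(tab)
  ms <- colSums(tab)

  tidyr::expand_grid(ci = seq_along(cs), mi = seq_along(ms)) |>
    purrr::pmap_dfr(function(ci, mi) {
      x <- tab[ci, mi]
      tibble(
        cluster = as.integer(rownames(tab)[ci]),
        category = colnames(tab)[mi],
        overlap = as.integer(x),
        cluster_size = as.integer(cs[ci]),
        category_size = as.integer(ms[mi]),
        universe = as.integer(n),
        expected = cs[ci] * ms[mi] / n,
        p_value = phyper(x - 1, ms[mi], n - ms[mi], cs[ci], lower.tail = FALSE)
      )
    })
}

#' Cosine similarity between clusters of two partitions
#'
#' Each cluster (optionally merged into named groups, e.g. compartments) is
#' represented as a binary membership indicator over the union of the two
#' node sets; the similarity of two clusters is the cosine of the angle
#' between their indicators: `overlap / sqrt(size_u * size_v)`.
#'
#' @param U,V Partitions, possibly over different node sets.
#' @param groups_u,groups_v Optional named vectors mapping cluster labels of
#'   `U` / `V` to group names; member clusters are merged before comparison.
#' @return A tibble with columns `cluster_u`, `cluster_v`, `overlap`,
#'   `size_u`, `size_v`, `cosine`.
#' @export
partition_cosine <- function(U, V, groups_u = NULL, groups_v = NULL) {
  u <- merge_groups(as_partition(U), groups_u)
  v <- merge_groups(as_partition(V), groups_v)
  if (length(intersect(u$node, v$node)) == 0L) {
    abort("partitions share no nodes; cosine undefined")
  }
  su <- split(u$node, u$cluster)
  sv <- split(v$node, v$cluster)
  tidyr::expand_grid(cu = names(su), cv = names(sv)) |>
    purrr::pmap_dfr(function(cu, cv) {
      ov <- length(intersect(su[[cu]], sv[[cv]]))
      tibble(cluster_u = cu, cluster_v = cv, overlap = ov,
             size_u = length(su[[cu]]), size_v = length(sv[[cv]]),
             cosine = ov / sqrt(length(su[[cu]]) * length(sv[[cv]])))
    })
}

merge_groups <- function(p, groups) {
  if (is.null(groups)) {
    p$cluster <- as.character(p$cluster)
    return(p)
  }
  mapped <- groups[as.character(p$cluster)]
  if (anyNA(mapped)) abort("groups mapping does not cover every cluster label")
  p$cluster <- unname(mapped)
  p
}
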