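# independent oracles: exhaustive enumeration / exact combinatorics, kept
# deliberately naive and separate from the package's implementations

# count non-backtracking walks of exactly p edge-transitions between every
# ordered pair of directed edges, by depth-first enumeration of node
# sequences (never touches the Hashimoto matrix)
count_nb_walks <- function(graph, p, edge_index = directed_edge_index(graph)) {
  M <- nrow(edge_index)
  W <- matrix(0, M, M)
  nodes <- graph_nodes(graph)
  adj <- lapply(nodes, function(v) names(igraph::neighbors(graph, v)))
  names(adj) <- nodes
  key <- stats::setNames(edge_index$idx,
                         paste(edge_index$from, edge_index$to, sep = "->"))
  for (e in seq_len(M)) {
    walk <- function(prev, cur, t) {
      if (t == p) {
        f <- key[[paste(prev, cur, sep = "->")]]
        W[e, f] <<- W[e, f] + 1
        return(invisible())
      }
      for (nxt in adj[[cur]]) if (nxt != prev) walk(cur, nxt, t + 1L)
    }
    walk(edge_index$from[e], edge_index$to[e], 0L)
  }
  W
}

# exact expected mutual information under the permutation model, by averaging
# MI over every permutation of the node labels of V (n! enumeration)
ami_permutation_oracle <- function(U, V) {
  u <- as_partition(U)
  v <- as_partition(V)
  stopifnot(setequal(u$node, v$node))
  nodes <- sort(u$node)
  lu <- u$cluster[match(nodes, u$node)]
  lv <- v$cluster[match(nodes, v$node)]
  n <- length(nodes)
  mi_of <- function(a, b) {
    tab <- table(a, b)
    p <- tab / n
    pu <- rowSums(p); pv <- colSums(p)
    sum((p * log(p / outer(pu, pv)))[tab > 0])
  }
  perms <- all_permutations(n)
  emi <- mean(vapply(seq_len(nrow(perms)),
                     function(i) mi_of(lu, lv[perms[i, ]]), numeric(1)))
  mi <- mi_of(lu, lv)
  h <- function(x) { p <- table(x) / n; -sum(p * log(p)) }
  (mi - emi) / (max(h(lu), h(lv)) - emi)
}

all_permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    rest <- seq_len(n)[-i]
    cbind(i, matrix(rest[sub], nrow = nrow(sub)))
  }))
}

# hypergeometric upper-tail by explicit binomial-coefficient summation
hyper_tail_oracle <- function(x, category, universe, cluster) {
  xs <- x:min(category, cluster)
  sum(choose(category, xs) * choose(universe - category, cluster - xs)) /
    choose(universe, cluster)
}

# Newman Q by the literal double sum over ordered node pairs
q_direct_oracle <- function(graph, partition) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph))
  nodes <- graph_nodes(graph)
  p <- as_partition(partition)
  lab <- p$cluster[match(nodes, p$node)]
  d <- rowSums(A)
  twoC <- sum(d)
  same <- outer(lab, lab, "==")
  sum((A - outer(d, d) / twoC)[same]) / twoC
}
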