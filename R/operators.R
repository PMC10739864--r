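#' Directed-edge index of an undirected graph
#'
#' The non-backtracking operators live on the `M = 2C` directed edges obtained
#' by orienting every undirected edge both ways. Undirected edges are taken in
#' lexicographic endpoint order; for each, the `min -> max` orientation comes
#' first, then `max -> min`, giving a deterministic matrix layout.
#'
#' @param graph An igraph object with named vertices.
#' @return A tibble with columns `idx`, `from`, `to`, `rev` (index of the
#'   reversed edge); `idx -> rev -> idx` is the identity.
#' @export
directed_edge_index <- function(graph) {
  el <- igraph::as_edgelist(graph)
  if (nrow(el) == 0L) {
    return(tibble(idx = integer(), from = character(), to = character(),
                  rev = integer()))
  }
  a <- pmin(el[, 1], el[, 2])
  b <- pmax(el[, 1], el[, 2])
  o <- order(a, b, method = "radix")
  a <- a[o]
  b <- b[o]
  C <- length(a)
  from <- character(2L * C)
  to <- character(2L * C)
  from[seq(1L, 2L * C, by = 2L)] <- a
  to[seq(1L, 2L * C, by = 2L)] <- b
  from[seq(2L, 2L * C, by = 2L)] <- b
  to[seq(2L, 2L * C, by = 2L)] <- a
  rev <- as.integer(seq_len(2L * C) + rep(c(1L, -1L), C))
  tibble(idx = seq_len(2L * C), from = from, to = to, rev = rev)
}

# successor structure shared by B and F: row edge (i -> j) connects to every
# column edge (j -> l) with l != i
nb_successors <- function(graph, edge_index) {
  nodes <- graph_nodes(graph)
  M <- nrow(edge_index)
  out_by_node <- split(edge_index$idx, factor(edge_index$from, levels = nodes))
  succ <- out_by_node[match(edge_index$to, nodes)]
  ii <- rep(edge_index$idx, lengths(succ))
  jj <- unlist(succ, use.names = FALSE)
  keep <- jj != edge_index$rev[ii]
  list(i = ii[keep], j = jj[keep], M = M)
}

#' Non-backtracking (Hashimoto) matrix
#'
#' Transfer matrix of non-backtracking walks: entry `(i->j, k->l)` is 1 iff
#' `j = k` and `l != i`, i.e. a walker at directed edge `i->j` may continue
#' along any edge leaving `j` except straight back to `i`. Powers of B count
#' non-backtracking walks of the corresponding length.
#'
#' @param graph A simple undirected igraph object (no self-loops).
#' @param edge_index Optional precomputed [directed_edge_index()].
#' @return A sparse 0/1 `M x M` [Matrix][Matrix::sparseMatrix] over the
#'   directed-edge index, with the index attached as attribute `edge_index`.
#' @export
build_hashimoto <- function(graph, edge_index = directed_edge_index(graph)) {
  s <- nb_successors(graph, edge_index)
  B <- Matrix::sparseMatrix(i = s$i, j = s$j, x = 1, dims = c(s$M, s$M))
  structure(B, edge_index = edge_index, kind = "hashimoto")
}

#' Non-backtracking flow matrix
#'
#' Row-stochastic normalisation of the Hashimoto matrix: entry
#' `(i->j, k->l) = delta_jk (1 - delta_li) / (d_j - 1)`, so each step
#' conserves the probability flow of the non-backtracking walker. Requires
#' minimum degree 2 (build on the [two_core()]); every row then sums to 1 and
#' the Perron eigenvalue is exactly 1.
#'
#' @inheritParams build_hashimoto
#' @return A sparse `M x M` row-stochastic Matrix with attribute `edge_index`.
#' @export
build_flow <- function(graph, edge_index = directed_edge_index(graph)) {
  deg <- igraph::degree(graph)
  low <- graph_nodes(graph)[deg < 2L]
  if (length(low) > 0L) {
    abort(paste0("flow matrix needs minimum degree 2; offending node(s): ",
                 paste(utils::head(low, 5L), collapse = ", "),
                 " - run two_core() first"))
  }
  s <- nb_successors(graph, edge_index)
  dm1 <- deg[match(edge_index$to, graph_nodes(graph))] - 1
  F_ <- Matrix::sparseMatrix(i = s$i, j = s$j, x = 1 / dm1[s$i], dims = c(s$M, s$M))
  structure(F_, edge_index = edge_index, kind = "flow")
}

#' Bulk spectral radius of the flow matrix
#'
#' The non-informative bulk of the flow spectrum lies in the complex disc of
#' radius `sqrt( mean(d/(d-1)) / mean(d) )` (vertex-averages over degrees).
#' Eigenvalues outside this disc are "isolated" and encode the community
#' structure. For a d-regular graph the radius is `1/sqrt(d-1)`.
#'
#' @param graph An igraph object with minimum degree >= 2.
#' @return A positive scalar.
#' @export
bulk_radius <- function(graph) {
  deg <- igraph::degree(graph)
  if (any(deg < 2L)) abort("bulk_radius: graph has a vertex of degree < 2")
  sqrt(mean(deg / (deg - 1)) / mean(deg))
}

#' Modularity matrix
#'
#' `M = A - d d^T / (2C)`: adjacency minus the degree-preserving null
#' expectation. Symmetric with vanishing row sums.
#'
#' @param graph An igraph object with at least one edge.
#' @return A dense symmetric `N x N` matrix with vertex-name dimnames.
#' @export
build_modularity <- function(graph) {
  if (igraph::ecount(graph) == 0L) abort("modularity matrix of an edgeless graph")
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  d <- igraph::degree(graph)
  A - outer(d, d) / (2 * igraph::ecount(graph))
}

#' Graph Laplacian and symmetric normalized Laplacian
#'
#' `L = D - A`; `L_norm = I - D^{-1/2} A D^{-1/2}`. Both are positive
#' semi-definite with smallest eigenvalue 0 (for `L_norm` on graphs with no
#' isolated vertex).
#'
#' @param graph An igraph object.
#' @param normalized Build the symmetric normalized Laplacian.
#' @return A dense symmetric `N x N` matrix.
#' @export
build_laplacian <- function(graph, normalized = FALSE) {
  A <- as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE))
  d <- igraph::degree(graph)
  if (!normalized) return(diag(d, nrow = length(d)) - A)
  if (any(d == 0L)) abort("normalized Laplacian undefined with isolated vertices")
  s <- 1 / sqrt(d)
  diag(1, nrow = length(d)) - (s * A) * rep(s, each = length(d))
}

#' Build any of the package's node/edge operators by name
#'
#' @param graph An igraph object.
#' @param kind One of `"flow"`, `"hashimoto"`, `"adjacency"`, `"laplacian"`,
#'   `"norm_laplacian"`, `"modularity"`.
#' @return The operator matrix (sparse for edge operators, dense for node
#'   operators).
#' @export
build_operator <- function(graph, kind) {
  kind <- match.arg(kind, c("flow", "hashimoto", "adjacency", "laplacian",
                            "norm_laplacian", "modularity"))
  switch(kind,
    flow = build_flow(graph),
    hashimoto = build_hashimoto(graph),
    adjacency = as.matrix(igraph::as_adjacency_matrix(graph, sparse = TRUE)),
    laplacian = build_laplacian(graph, normalized = FALSE),
    norm_laplacian = build_laplacian(graph, normalized = TRUE),
    modularity = build_modularity(graph)
  )
}

#' Export an operator to Matrix Market format
#'
#' @param op A matrix as returned by [build_operator()].
#' @param path Output `.mtx` path.
#' @export
write_operator_mtx <- function(op, path) {
  Matrix::writeMM(methods::as(methods::as(Matrix::Matrix(op, sparse = TRUE),
                                          "generalMatrix"), "CsparseMatrix"), path)
  invisible(path)
}
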