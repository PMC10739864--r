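#' Coerce to a partition tibble
#'
#' A partition is a tibble with columns `node` (character) and `cluster`
#' (positive integer), covering each node exactly once. Accepted inputs:
#' such a data frame, a named vector/factor of labels, or an `nb_cluster`
#' fit.
#'
#' @param x Object to coerce.
#' @return A tibble with columns `node`, `cluster` (1-based consecutive
#'   integers are not enforced; labels are kept as given, coerced to integer
#'   codes when non-numeric).
#' @export
as_partition <- function(x) {
  if (inherits(x, "nb_cluster")) return(x$partition)
  if (is.data.frame(x)) {
    if (!all(c("node", "cluster") %in% names(x))) {
      abort("partition data frame needs columns `node` and `cluster`")
    }
    cl <- x$cluster
    if (!is.numeric(cl)) cl <- as.integer(factor(cl))
    return(tibble(node = as.character(x$node), cluster = as.integer(cl)))
  }
  if ((is.atomic(x) || is.factor(x)) && !is.null(names(x))) {
    cl <- if (is.numeric(x)) as.integer(x) else as.integer(factor(x))
    return(tibble(node = names(x), cluster = cl))
  }
  abort("cannot interpret object as a partition")
}

partition_labels <- function(partition, nodes) {
  p <- as_partition(partition)
  if (anyDuplicated(p$node) > 0L) abort("partition assigns a node twice")
  lab <- p$cluster[match(nodes, p$node)]
  if (anyNA(lab)) {
    abort(paste0("partition does not cover node(s): ",
                 paste(utils::head(nodes[is.na(lab)], 5L), collapse = ", ")))
  }
  lab
}

#' Spectral clustering with any of the package operators
#'
#' Uniform front-end over the four spectral pipelines compared in the
#' package. For the edge operators (`"flow"`, `"hashimoto"`) the graph is
#' pruned to its [two_core()], the operator's leading eigenvectors are
#' projected onto nodes via [edge_to_node()], and peeled vertices are
#' re-attached afterwards to the cluster holding the plurality of their
#' already-labelled neighbours (ties towards the lowest cluster label). For
#' the node operators the embedding uses the standard informative
#' eigenvectors (Laplacians: ascending eigenvalues 2..k; modularity: leading
#' k-1 by algebraic eigenvalue). k-means (multiple random restarts, best
#' within-cluster sum of squares kept) partitions the embedding.
#'
#' By default the trivial flow/Hashimoto eigenvector is dropped (its node
#' projection is the degree vector, which carries no community signal),
#' giving a `k - 1`-dimensional embedding; set `include_trivial = TRUE` to
#' keep it.
#'
#' @param graph A connected igraph object (preprocess first; see
#'   [preprocess_graph()]).
#' @param operator One of `"flow"`, `"hashimoto"`, `"norm_laplacian"`,
#'   `"laplacian"`, `"modularity"`.
#' @param k Number of clusters (>= 2).
#' @param seed Integer seed controlling the eigensolver start vector and the
#'   k-means restarts; identical graph + seed gives an identical partition.
#' @param include_trivial Keep the trivial leading eigenvector in the
#'   embedding (edge operators only).
#' @param n_eig Eigenpairs requested from the edge-operator solver; default
#'   `max(2k, 24)` leaves headroom for conjugate pairs.
#' @param nstart,iter_max k-means restarts and iteration cap.
#' @return An object of class `nb_cluster`: list with `partition` (tibble
#'   `node`, `cluster` with exactly `k` non-empty clusters), `k`, `operator`,
#'   `seed`, `embedding` (tibble), `spectrum` (for edge operators), `sizes`,
#'   `pruned` (vertices labelled by the plurality rule), `inertia`.
#' @export
spectral_cluster <- function(graph, operator = c("flow", "hashimoto",
                                                 "norm_laplacian", "laplacian",
                                                 "modularity"),
                             k, seed = 1L, include_trivial = FALSE,
                             n_eig = NULL, nstart = 100L, iter_max = 300L) {
  operator <- match.arg(operator)
  if (k < 2L) abort("k must be at least 2")
  if (!igraph::is_connected(graph)) {
    abort("spectral_cluster needs a connected graph; see largest_component()")
  }

  if (operator %in% c("flow", "hashimoto")) {
    core <- two_core(graph)
    if (igraph::vcount(core$graph) == 0L) {
      abort("graph has an empty 2-core; no cycles to carry non-backtracking flow")
    }
    n_eig <- n_eig %||% max(2L * k, 24L)
    spec <- nb_spectrum(core$graph, kind = operator, n_eig = n_eig, seed = seed)
    sel <- if (include_trivial) seq_len(k) else seq(2L, k)
    if (max(sel) > length(spec$values)) {
      abort("not enough eigenpairs computed for the requested k")
    }
    emb <- realify_embedding(spec, sel)
    pruned <- core$pruned
  } else {
    emb <- node_operator_embedding(graph, operator, k)
    spec <- NULL
    pruned <- character()
  }

  if (nrow(unique(as.data.frame(emb))) < k) {
    abort("embedding has fewer than k distinct points; try a smaller k")
  }
  km <- withr::with_seed(seed, tryCatch(
    kmeans(emb, centers = k, nstart = nstart, iter.max = iter_max),
    error = function(e) abort(paste0("k-means failed (", conditionMessage(e),
                                     "); try a smaller k"))
  ))
  labels <- stats::setNames(km$cluster, rownames(emb))

  if (length(pruned) > 0L) {
    labels <- c(labels, assign_by_plurality(graph, labels, pruned))
  }
  nodes <- graph_nodes(graph)
  part <- tibble(node = nodes, cluster = as.integer(labels[nodes]))
  sizes <- tabulate(part$cluster, nbins = k)
  if (any(sizes == 0L)) abort("clustering produced an empty cluster; try a smaller k")

  structure(list(partition = part, k = as.integer(k), operator = operator,
                 seed = as.integer(seed),
                 embedding = as_tibble(emb, rownames = "node"),
                 spectrum = spec, sizes = sizes, pruned = pruned,
                 inertia = km$tot.withinss, graph = graph),
            class = "nb_cluster")
}

# turn the selected (possibly complex) projected eigenvectors into real
# coordinates: real eigenvalues give their real projection; a selected
# conjugate pair contributes the real and imaginary parts of one member
realify_embedding <- function(spectrum, sel) {
  vals <- spectrum$values
  cols <- list()
  done <- logical(length(sel))
  for (a in seq_along(sel)) {
    if (done[a]) next
    i <- sel[a]
    if (abs(Im(vals[i])) <= 1e-8 * max(1, Mod(vals[i]))) {
      cols[[length(cols) + 1L]] <- Re(project_edge_vector(spectrum, i)$u)
      done[a] <- TRUE
      next
    }
    partner <- which(!done & abs(vals[sel] - Conj(vals[i])) <
                       1e-8 * max(1, Mod(vals[i])) & seq_along(sel) != a)
    u <- project_edge_vector(spectrum, i)$u
    cols[[length(cols) + 1L]] <- Re(u)
    done[a] <- TRUE
    if (length(partner) > 0L) {
      cols[[length(cols) + 1L]] <- Im(u)
      done[partner[1]] <- TRUE
    }
  }
  emb <- do.call(cbind, cols)
  rownames(emb) <- graph_nodes(spectrum$graph)
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  emb
}

node_operator_embedding <- function(graph, operator, k) {
  op <- build_operator(graph, operator)
  e <- eigen(op, symmetric = TRUE)          # eigenvalues descending
  N <- nrow(op)
  idx <- if (operator == "modularity") {
    seq_len(k - 1L)                         # leading k-1 by algebraic value
  } else {
    seq(N - 1L, by = -1L, length.out = k - 1L)  # ascending 2..k
  }
  emb <- e$vectors[, idx, drop = FALSE]
  rownames(emb) <- graph_nodes(graph)
  colnames(emb) <- paste0("dim", seq_len(ncol(emb)))
  emb
}

# plurality-neighbour labelling of 2-core-pruned vertices: repeated sweeps
# assign any unlabelled vertex with at least one labelled neighbour to the
# most common neighbouring label (ties -> lowest label)
assign_by_plurality <- function(graph, labels, pruned) {
  todo <- sort(pruned, method = "radix")
  out <- stats::setNames(integer(0), character(0))
  all_labels <- labels
  while (length(todo) > 0L) {
    progressed <- FALSE
    for (v in todo) {
      nb <- igraph::neighbors(graph, v)$name
      nl <- all_labels[nb]
      nl <- nl[!is.na(nl)]
      if (length(nl) == 0L) next
      tab <- table(nl)
      lab <- as.integer(min(as.integer(names(tab)[tab == max(tab)])))
      out[v] <- lab
      all_labels[v] <- lab
      progressed <- TRUE
    }
    todo <- setdiff(todo, names(out))
    if (!progressed) {
      abort(paste0("cannot attach pruned node(s) to any labelled neighbour: ",
                   paste(utils::head(todo, 5L), collapse = ", ")))
    }
  }
  out
}

#' @export
#' @method print nb_cluster
print.nb_cluster <- function(x, ...) {
  cat("<nb_cluster> ", x$operator, " operator, k = ", x$k,
      ", N = ", nrow(x$partition), "\n", sep = "")
  cat("  cluster sizes: ", paste(x$sizes, collapse = ", "), "\n", sep = "")
  if (length(x$pruned) > 0L) {
    cat("  ", length(x$pruned), " vertices attached by the plurality rule\n",
        sep = "")
  }
  invisible(x)
}

#' @export
tidy.nb_cluster <- function(x, ...) x$partition

#' @export
glance.nb_cluster <- function(x, ...) {
  tibble(operator = x$operator, k = x$k, n_nodes = nrow(x$partition),
         n_pruned = length(x$pruned), inertia = x$inertia,
         q_score = q_score(x$graph, x$partition),
         min_size = min(x$sizes), max_size = max(x$sizes), seed = x$seed)
}
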