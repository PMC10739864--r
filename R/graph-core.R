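#' Read an undirected simple graph from a delimited edge list
#'
#' Reads a 2- or 3-column delimited file (`source, target[, type]`) into an
#' undirected, unweighted, simple [igraph][igraph::igraph-package] graph.
#' Reciprocal and duplicate rows are collapsed to a single edge, self-loops are
#' dropped with a warning, and vertices are ordered lexicographically (C
#' locale) so that every matrix built downstream has a reproducible layout
#' independent of row order in the file.
#'
#' The delimiter (comma or tab) and an optional header row are auto-detected.
#' Connectome edge lists typically carry an edge-type column distinguishing
#' chemical synapses from gap junctions; `edge_type` keeps only rows of one
#' type before collapsing.
#'
#' @param path Path to the edge-list file.
#' @param edge_type Optional category; keep only rows whose third column
#'   equals this value. Requires a 3-column file.
#' @param keep_order Keep first-appearance vertex order from the file instead
#'   of sorting lexicographically.
#' @return An undirected simple igraph object with character vertex names.
#' @seealso [write_edge_list()], [read_graphml()], [preprocess_report()]
#' @export
read_edge_list <- function(path, edge_type = NULL, keep_order = FALSE) {
  if (!file.exists(path)) abort(paste0("edge-list file not found: ", path))
  lines <- readLines(path, warn = FALSE)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) abort(paste0("empty edge-list file: ", path))

  delim <- if (grepl("\t", lines[[1]], fixed = TRUE)) "\t" else ","
  fields <- strsplit(lines, delim, fixed = TRUE)
  fields <- lapply(fields, trimws)

  header_names <- c("source", "target", "from", "to", "node1", "node2",
                    "type", "edge_type", "weight", "pre", "post")
  has_header <- any(tolower(fields[[1]]) %in% header_names)
  if (has_header) {
    fields <- fields[-1]
    line_no <- line_no[-1]
    if (length(fields) == 0L) abort(paste0("edge-list file has only a header: ", path))
  }

  ncol <- length(fields[[1]])
  if (!ncol %in% c(2L, 3L)) {
    abort(paste0("line ", line_no[[1]], ": expected 2 or 3 columns, found ", ncol))
  }
  bad <- which(lengths(fields) != ncol)
  if (length(bad) > 0L) {
    abort(paste0("line ", line_no[[bad[1]]], ": expected ", ncol,
                 " columns, found ", lengths(fields)[[bad[1]]]))
  }

  mat <- do.call(rbind, fields)
  edges <- tibble(source = mat[, 1], target = mat[, 2])
  if (ncol == 3L) edges$type <- mat[, 3]

  if (!is.null(edge_type)) {
    if (ncol != 3L) abort("edge_type filter given but the file has no type column")
    edges <- dplyr::filter(edges, .data$type == edge_type)
    if (nrow(edges) == 0L) {
      abort(paste0("no edges of type '", edge_type, "' in ", path))
    }
  }

  graph_from_edges(edges, keep_order = keep_order)
}

#' Build a canonical undirected simple graph from an edge table
#'
#' @param edges Data frame with columns `source` and `target` (characters or
#'   coercible).
#' @param nodes Optional character vector of vertex names to include even when
#'   they carry no edge (isolated vertices survive).
#' @param keep_order Keep first-appearance vertex order instead of sorting.
#' @return An undirected simple igraph object.
#' @export
graph_from_edges <- function(edges, nodes = NULL, keep_order = FALSE) {
  src <- as.character(edges$source)
  tgt <- as.character(edges$target)

  loops <- src == tgt
  if (any(loops)) {
    warn(paste0("dropped ", sum(loops), " self-loop(s): ",
                paste(utils::head(unique(src[loops]), 5L), collapse = ", ")))
    src <- src[!loops]
    tgt <- tgt[!loops]
  }

  # collapse parallel and reciprocal entries to one undirected edge
  a <- pmin(src, tgt)
  b <- pmax(src, tgt)
  key <- paste(a, b, sep = "\r")
  dup <- duplicated(key)
  a <- a[!dup]
  b <- b[!dup]

  verts <- unique(c(nodes, src, tgt))
  if (!keep_order) verts <- sort(verts, method = "radix")
  g <- igraph::graph_from_data_frame(
    data.frame(from = a, to = b, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = verts, stringsAsFactors = FALSE)
  )
  canonicalize_graph(g)
}

# enforce the package-wide invariants: simple, undirected, vertices in
# C-locale lexicographic order (unless the caller already fixed an order)
canonicalize_graph <- function(g, sort_vertices = FALSE) {
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  if (is.null(igraph::V(g)$name)) {
    igraph::V(g)$name <- sprintf("v%0*d", nchar(igraph::vcount(g)), seq_len(igraph::vcount(g)))
  }
  if (sort_vertices) {
    g <- igraph::permute(g, match(igraph::V(g)$name,
                                  sort(igraph::V(g)$name, method = "radix")))
  }
  g
}

#' Vertex names in canonical order
#' @param graph An igraph object with named vertices.
#' @return Character vector of vertex names.
#' @export
graph_nodes <- function(graph) igraph::V(graph)$name

#' Write a graph back to a delimited edge list
#'
#' Inverse of [read_edge_list()]: writes `source,target` rows (lexicographic
#' endpoint order within and across rows), so read -> write -> read is the
#' identity on the graph.
#'
#' @param graph An igraph object.
#' @param path Output path.
#' @param delim Field delimiter, `","` (default) or `"\t"`.
#' @return `path`, invisibly.
#' @export
write_edge_list <- function(graph, path, delim = ",") {
  el <- igraph::as_edgelist(graph)
  if (nrow(el) > 0L) {
    a <- pmin(el[, 1], el[, 2])
    b <- pmax(el[, 1], el[, 2])
    o <- order(a, b, method = "radix")
    lines <- paste(a[o], b[o], sep = delim)
  } else {
    lines <- character()
  }
  writeLines(c(paste("source", "target", sep = delim), lines), path)
  invisible(path)
}

#' Read / write GraphML for interchange
#'
#' @param path File path.
#' @return `read_graphml()` returns a canonical undirected simple igraph.
#' @export
read_graphml <- function(path) {
  if (!file.exists(path)) abort(paste0("GraphML file not found: ", path))
  canonicalize_graph(igraph::read_graph(path, format = "graphml"),
                     sort_vertices = TRUE)
}

#' @rdname read_graphml
#' @param graph An igraph object.
#' @export
write_graphml <- function(graph, path) {
  igraph::write_graph(graph, path, format = "graphml")
  invisible(path)
}

#' Read a node-annotation table
#'
#' A CSV with columns `node,label` mapping node ids to one categorical label
#' per node (ganglion, functional group, contactome stratum, an external
#' partition, ...).
#'
#' @param path Path to the CSV.
#' @param name Annotation-set name (defaults to the file name).
#' @return A tibble with columns `node`, `label` and attribute `name`.
#' @export
read_annotation <- function(path, name = NULL) {
  df <- readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()))
  if (ncol(df) < 2L) abort("annotation file needs two columns: node,label")
  out <- tibble(node = as.character(df[[1]]), label = as.character(df[[2]]))
  attr(out, "name") <- name %||% basename(path)
  out
}

#' Read / write a partition as `node,cluster` CSV
#'
#' Cluster labels are 1-based integers.
#'
#' @param path File path.
#' @return `read_partition()` returns a tibble with columns `node` (character)
#'   and `cluster` (integer).
#' @export
read_partition <- function(path) {
  df <- readr::read_csv(path, col_types = readr::cols(
    node = readr::col_character(), cluster = readr::col_integer()))
  tibble(node = df$node, cluster = df$cluster)
}

#' @rdname read_partition
#' @param partition A partition (see [as_partition()]).
#' @export
write_partition <- function(partition, path) {
  readr::write_csv(as_partition(partition), path)
  invisible(path)
}

#' Remove isolated (degree-0) vertices
#'
#' Isolated vertices have undefined non-backtracking flow and take no part in
#' spectral clustering; they are dropped before any operator is built.
#' Idempotent. The removed names are recorded in the graph's preprocessing
#' log (see [preprocess_report()]).
#'
#' @param graph An igraph object.
#' @return The graph without degree-0 vertices.
#' @export
remove_isolated <- function(graph) {
  iso <- graph_nodes(graph)[igraph::degree(graph) == 0L]
  out <- igraph::delete_vertices(graph, iso)
  log_stage(out, "remove_isolated", removed = iso)
}

#' Induced subgraph on the largest connected component
#'
#' Ties between equal-sized components are broken towards the component
#' containing the lexicographically smallest vertex name.
#'
#' @param graph A non-empty igraph object.
#' @return The induced subgraph on the largest component.
#' @export
largest_component <- function(graph) {
  if (igraph::vcount(graph) == 0L) abort("largest_component: empty graph")
  comp <- igraph::components(graph)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    firsts <- vapply(best, function(b) {
      min(graph_nodes(graph)[comp$membership == b])
    }, character(1))
    best <- best[order(firsts, method = "radix")[1]]
  }
  keep <- graph_nodes(graph)[comp$membership == best]
  out <- igraph::induced_subgraph(graph, keep)
  log_stage(out, "largest_component",
            n_components = comp$no, component_sizes = sort(comp$csize, decreasing = TRUE))
}

#' 2-core of a graph
#'
#' Iteratively peels degree <= 1 vertices until every remaining vertex has
#' degree >= 2. The flow matrix divides by `d - 1` and the non-backtracking
#' operator ignores hanging trees by construction, so edge operators are built
#' on the 2-core; peeled vertices are re-attached to clusters afterwards (see
#' [spectral_cluster()]).
#'
#' @param graph An igraph object.
#' @return A list with elements `graph` (the 2-core) and `pruned` (vertex
#'   names in removal order; within a peeling round, lexicographic order).
#' @export
two_core <- function(graph) {
  g <- graph
  pruned <- character()
  repeat {
    deg <- igraph::degree(g)
    leaves <- sort(graph_nodes(g)[deg <= 1L], method = "radix")
    if (length(leaves) == 0L) break
    pruned <- c(pruned, leaves)
    g <- igraph::delete_vertices(g, leaves)
  }
  g <- log_stage(g, "two_core", pruned = pruned)
  list(graph = g, pruned = pruned)
}

# --- preprocessing log ------------------------------------------------------

log_stage <- function(graph, stage, ...) {
  log <- graph_attr_or(graph, "nbflow_log", list())
  log[[length(log) + 1L]] <- c(list(stage = stage, n_nodes = igraph::vcount(graph),
                                    n_edges = igraph::ecount(graph)), list(...))
  igraph::graph_attr(graph, "nbflow_log") <- log
  graph
}

graph_attr_or <- function(graph, name, default) {
  if (name %in% igraph::graph_attr_names(graph)) igraph::graph_attr(graph, name) else default
}

#' Preprocessing report for a graph
#'
#' Collects the per-stage counts recorded by [remove_isolated()],
#' [largest_component()] and [two_core()].
#'
#' @param graph An igraph object that has passed through preprocessing stages.
#' @return A tibble with one row per stage: `stage`, `n_nodes`, `n_edges`,
#'   `n_removed`, `detail` (comma-separated removed names, truncated).
#' @export
preprocess_report <- function(graph) {
  log <- graph_attr_or(graph, "nbflow_log", list())
  purrr::map_dfr(log, function(st) {
    removed <- st$removed %||% st$pruned %||% character()
    tibble(
      stage = st$stage, n_nodes = st$n_nodes, n_edges = st$n_edges,
      n_removed = length(removed),
      detail = paste(utils::head(removed, 25L), collapse = ",")
    )
  })
}

#' Standard preprocessing pipeline
#'
#' Applies the default preparation for community detection: optional edge-type
#' filter (done at read time), isolated-vertex removal, then restriction to
#' the largest connected component.
#'
#' @param graph An igraph object.
#' @return The preprocessed graph, with a retrievable [preprocess_report()].
#' @export
preprocess_graph <- function(graph) {
  graph |> remove_isolated() |> largest_component()
}
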