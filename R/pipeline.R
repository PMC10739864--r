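#' Run the full community-detection workflow on an edge list
#'
#' End-to-end orchestration: read and preprocess the graph (edge-type filter,
#' isolated-vertex removal, largest component), compute the flow spectrum and
#' count isolated eigenvalues, cluster for every `k` in range, select `k_max`
#' by the detectability condition, score partitions (Q for every requested
#' operator), and compare against any provided annotations (AMI and
#' hypergeometric enrichment). All tables are written as CSV into `out_dir`
#' together with the resolved configuration and a structured stage log.
#'
#' @param edges Path to an edge-list file, or an igraph object.
#' @param out_dir Output directory (created if needed).
#' @param edge_type Optional edge-type filter applied at read time.
#' @param operator Primary operator for clustering and `k_max` selection.
#' @param q_operators Operators for the comparative Q-score table.
#' @param k_range Cluster counts to scan; `NULL` means `2 : n_isolated`.
#' @param seed Integer seed used for every stochastic stage.
#' @param annotations Named list of annotation tibbles or file paths.
#' @return Invisibly, a list with `graph`, `spectrum`, `kmax`, `partitions`,
#'   `q_table`, `ami_table`, `enrichment`, `out_dir`.
#' @export
run_full <- function(edges, out_dir, edge_type = NULL, operator = "flow",
                     q_operators = c("flow", "norm_laplacian", "laplacian",
                                     "modularity"),
                     k_range = NULL, seed = 1L, annotations = list()) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_lines <- character()
  say <- function(...) {
    line <- sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), paste0(...))
    log_lines <<- c(log_lines, line)
    inform(line)
  }

  say("stage: preprocess")
  g <- if (inherits(edges, "igraph")) edges else
    read_edge_list(edges, edge_type = edge_type)
  if (igraph::ecount(g) == 0L) abort("preprocess: input graph has no edges")
  g <- preprocess_graph(g)
  if (igraph::ecount(g) == 0L) abort("preprocess: graph is edgeless after preprocessing")
  readr::write_csv(preprocess_report(g), file.path(out_dir, "preprocess_report.csv"))
  say("  N = ", igraph::vcount(g), ", C = ", igraph::ecount(g))

  say("stage: spectrum (operator = flow, seed = ", seed, ")")
  spec <- nb_spectrum(g, kind = "flow", seed = seed)
  readr::write_csv(tidy(spec), file.path(out_dir, "eigenvalues.csv"))
  n_iso <- length(spec$isolated)
  say("  bulk radius = ", format(spec$bulk_radius, digits = 5),
      ", isolated eigenvalues = ", n_iso)

  if (is.null(k_range)) k_range <- seq(2L, max(n_iso, 2L))
  say("stage: kmax scan over k = ", min(k_range), "..", max(k_range))
  km <- select_kmax(g, k_range = k_range, operator = operator, seed = seed)
  readr::write_csv(km$table, file.path(out_dir, "kmax_table.csv"))
  say("  k_max = ", km$k_max)

  say("stage: partitions and Q-scores")
  partitions <- list()
  q_rows <- list()
  for (k in k_range) {
    for (op in q_operators) {
      fit <- tryCatch(spectral_cluster(g, operator = op, k = k, seed = seed),
                      error = function(e) NULL)
      if (is.null(fit)) next
      q_rows[[length(q_rows) + 1L]] <-
        tibble(operator = op, k = k, q = q_score(g, fit))
      if (op == operator) {
        partitions[[as.character(k)]] <- fit$partition
        write_partition(fit, file.path(out_dir, sprintf("partition_k%02d.csv", k)))
      }
    }
  }
  q_table <- dplyr::bind_rows(q_rows)
  readr::write_csv(q_table, file.path(out_dir, "q_scores.csv"))

  ami_table <- NULL
  enrichment <- NULL
  if (length(annotations) > 0L) {
    say("stage: annotation comparison")
    anns <- purrr::imap(annotations, function(a, nm) {
      if (is.character(a)) read_annotation(a, name = nm) else a
    })
    best <- partitions[[as.character(km$k_max)]] %||%
      partitions[[length(partitions)]]
    ami_table <- purrr::imap_dfr(anns, function(a, nm) {
      ann_part <- tibble(node = a$node, cluster = as.integer(factor(a$label)))
      common <- intersect(best$node, ann_part$node)
      tibble(annotation = nm, k = km$k_max,
             ami = adjusted_mutual_information(
               dplyr::filter(best, .data$node %in% common),
               dplyr::filter(ann_part, .data$node %in% common)),
             n_common = length(common))
    })
    readr::write_csv(ami_table, file.path(out_dir, "annotation_ami.csv"))
    enrichment <- purrr::imap_dfr(anns, function(a, nm) {
      dplyr::mutate(overlap_enrichment(best, a), annotation = nm,
                    .before = 1)
    })
    readr::write_csv(enrichment, file.path(out_dir, "enrichment.csv"))
  }

  cfg <- c(
    paste0("edges=", if (is.character(edges)) edges else "<igraph>"),
    paste0("edge_type=", edge_type %||% ""),
    paste0("operator=", operator),
    paste0("k_range=", paste(range(k_range), collapse = ":")),
    paste0("seed=", seed),
    paste0("k_max=", km$k_max),
    paste0("n_isolated=", n_iso)
  )
  writeLines(cfg, file.path(out_dir, "config.txt"))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))

  invisible(list(graph = g, spectrum = spec, kmax = km,
                 partitions = partitions, q_table = q_table,
                 ami_table = ami_table, enrichment = enrichment,
                 out_dir = out_dir))
}

#' Write deterministic test fixtures to disk
#'
#' Small edge-list (+ ground-truth) files used by the test-suite and CLI:
#' `cliques` (two K5 cliques joined by two bridge edges), `sbm_easy`
#' (N = 300, k = 3, far above the detectability threshold), `sbm_threshold`
#' (connectome-sized blocks at intermediate cluster strength) and
#' `path_tree` (a tree whose 2-core is empty, exercising leaf handling).
#'
#' @param kind One of `"cliques"`, `"sbm_easy"`, `"sbm_threshold"`,
#'   `"path_tree"`.
#' @param dir Output directory.
#' @param seed Integer seed for the stochastic fixtures.
#' @return Invisibly, a named list of the files written (`edges`, and
#'   `truth` where a planted partition exists).
#' @export
make_fixture <- function(kind = c("cliques", "sbm_easy", "sbm_threshold",
                                  "path_tree"),
                         dir = ".", seed = 1L) {
  kind <- match.arg(kind)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  edges_path <- file.path(dir, paste0(kind, "_edges.csv"))
  truth_path <- file.path(dir, paste0(kind, "_truth.csv"))

  if (kind == "cliques") {
    g <- two_cliques_graph()
    write_edge_list(g, edges_path)
    truth <- tibble(node = graph_nodes(g),
                    cluster = ifelse(graph_nodes(g) < "f", 1L, 2L))
    write_partition(truth, truth_path)
    return(invisible(list(edges = edges_path, truth = truth_path)))
  }
  if (kind == "path_tree") {
    edges <- tibble(source = c("a", "b", "c", "c"),
                    target = c("b", "c", "d", "e"))
    g <- graph_from_edges(edges)
    write_edge_list(g, edges_path)
    return(invisible(list(edges = edges_path)))
  }
  sbm <- if (kind == "sbm_easy") {
    generate_sbm(c(100L, 100L, 100L), w_in = 0.1, w_out = 5 / 300, seed = seed)
  } else {
    generate_sbm(connectome_sizes(), w_in = 0.22, w_out = 0.05, seed = seed)
  }
  write_edge_list(sbm$graph, edges_path)
  write_partition(sbm$partition, truth_path)
  invisible(list(edges = edges_path, truth = truth_path))
}

# two K5 cliques {a..e}, {f..j} bridged by a-f and b-g: the canonical
# two-community toy graph; its flow spectrum has exactly one isolated real
# eigenvalue besides the trivial one
two_cliques_graph <- function() {
  cl <- function(v) t(utils::combn(v, 2))
  el <- rbind(cl(letters[1:5]), cl(letters[6:10]), c("a", "f"), c("b", "g"))
  graph_from_edges(tibble(source = el[, 1], target = el[, 2]))
}
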