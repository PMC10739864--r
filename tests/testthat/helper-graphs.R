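# small graphs used across the suite, built in code

edges_df <- function(from, to) tibble::tibble(source = from, target = to)

make_path <- function(nodes = c("a", "b", "c")) {
  n <- length(nodes)
  graph_from_edges(edges_df(nodes[-n], nodes[-1]))
}

make_cycle <- function(n, prefix = "v") {
  nodes <- sprintf("%s%02d", prefix, seq_len(n))
  graph_from_edges(edges_df(nodes, nodes[c(2:n, 1)]))
}

make_complete <- function(nodes) {
  el <- t(utils::combn(nodes, 2))
  graph_from_edges(edges_df(el[, 1], el[, 2]))
}

# two K5 cliques {a..e}, {f..j} bridged by a-f and b-g
make_two_cliques <- function() {
  cl <- function(v) t(utils::combn(v, 2))
  el <- rbind(cl(letters[1:5]), cl(letters[6:10]), c("a", "f"), c("b", "g"))
  graph_from_edges(edges_df(el[, 1], el[, 2]))
}

clique_truth <- function() {
  tibble::tibble(node = letters[1:10], cluster = rep(1:2, each = 5))
}

# Erdos-Renyi sample with named vertices in canonical order
make_gnp <- function(n, p, seed) {
  g <- withr::with_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("n%02d", seq_len(n))
  graph_from_edges(
    {
      el <- igraph::as_edgelist(g)
      if (nrow(el) == 0L) edges_df(character(), character()) else
        edges_df(el[, 1], el[, 2])
    },
    nodes = igraph::V(g)$name
  )
}

write_tmp_lines <- function(lines) {
  f <- withr::local_tempfile(fileext = ".csv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}
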