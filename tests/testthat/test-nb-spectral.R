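test_that("a cycle's flow spectrum sits on the unit circle with no outliers", {
  g <- make_cycle(6)
  sp <- nb_spectrum(g, kind = "flow", n_eig = 12, seed = 1)
  expect_equal(Re(sp$values[1]), 1, tolerance = 1e-10)
  expect_equal(sp$bulk_radius, 1)
  expect_true(all(Mod(sp$values) <= 1 + 1e-8))
  expect_identical(sp$isolated, 1L)           # only the trivial one
})

test_that("two bridged cliques show exactly one extra isolated eigenvalue", {
  g <- make_two_cliques()
  sp <- nb_spectrum(g, kind = "flow", n_eig = 12, seed = 1)
  expect_length(sp$isolated, 2L)
  expect_lt(abs(Im(sp$values[2])), 1e-8)
  expect_gt(Re(sp$values[2]), sp$bulk_radius)
  # its node projection separates the cliques by sign
  U <- edge_to_node(sp, which = 2L)
  s <- sign(U[, 1])
  expect_equal(length(unique(s[letters[1:5]])), 1L)
  expect_equal(length(unique(s[letters[6:10]])), 1L)
  expect_equal(unique(s[letters[1:5]]), -unique(s[letters[6:10]]))
})

test_that("isolated-eigenvalue rule follows the radius and imaginary margins", {
  sp <- structure(list(
    values = complex(real = c(1, 0.62, 0.4, 0.4), imaginary = c(0, 0, 0.3, -0.3)),
    bulk_radius = 0.5), class = "nb_spectrum")
  expect_identical(find_isolated(sp, imag_tol = 1e-6, margin = 0.02), c(1L, 2L))
  # trivial index is kept even when it touches the circle
  sp2 <- structure(list(values = as.complex(c(1, 0.3)), bulk_radius = 1),
                   class = "nb_spectrum")
  expect_identical(find_isolated(sp2), 1L)
})

test_that("projecting the uniform edge vector returns the degree vector", {
  g <- make_two_cliques()
  sp <- nb_spectrum(g, kind = "flow", n_eig = 6, seed = 1)
  sp$vectors[, 1] <- 1 + 0i                    # Perron vector, unnormalised
  U <- edge_to_node(sp, which = 1L)
  expect_equal(U[, 1], igraph::degree(g)[rownames(U)], ignore_attr = TRUE)
  # linearity in the eigenvector
  sp$vectors[, 1] <- 2.5 + 0i
  expect_equal(edge_to_node(sp, which = 1L)[, 1], 2.5 * U[, 1])
})

test_that("edge_to_node refuses non-isolated indices", {
  g <- make_two_cliques()
  sp <- nb_spectrum(g, kind = "flow", n_eig = 8, seed = 1)
  non_iso <- setdiff(seq_along(sp$values), sp$isolated)[1]
  expect_error(edge_to_node(sp, which = non_iso), "not isolated")
  expect_silent(edge_to_node(sp, which = non_iso, check_isolated = FALSE))
})

test_that("sparse and dense eigensolves agree on isolated eigenvalues", {
  # large enough to take the sparse Arnoldi path
  sbm <- generate_sbm(c(30, 30), w_in = 0.5, w_out = 0.08, seed = 5)
  g <- two_core(largest_component(remove_isolated(sbm$graph)))$graph
  op <- build_flow(g)
  expect_gt(nrow(op), 400)                     # sparse path engaged
  sp <- nb_spectrum(g, kind = "flow", n_eig = 12, seed = 3)
  dense <- eigen(as.matrix(op))
  dvals <- dense$values[order(-Re(dense$values))]
  for (i in sp$isolated) {
    expect_equal(Re(sp$values[i]), Re(dvals[i]), tolerance = 1e-8)
  }
})

test_that("spectral clustering separates bridged cliques for every operator", {
  g <- make_two_cliques()
  truth <- clique_truth()
  for (op in c("flow", "hashimoto", "norm_laplacian", "laplacian",
               "modularity")) {
    fit <- spectral_cluster(g, operator = op, k = 2, seed = 1)
    expect_equal(adjusted_mutual_information(fit, truth), 1,
                 tolerance = 1e-12, label = op)
    expect_equal(sort(fit$sizes), c(5L, 5L))
  }
})

test_that("identical graph and seed give identical partitions", {
  sbm <- generate_sbm(c(40, 40), 0.3, 0.05, seed = 8)
  g <- largest_component(remove_isolated(sbm$graph))
  f1 <- spectral_cluster(g, "flow", k = 2, seed = 11)
  f2 <- spectral_cluster(g, "flow", k = 2, seed = 11)
  expect_identical(f1$partition, f2$partition)
})

test_that("vertices outside the 2-core are attached to a neighbour cluster", {
  # clique pair with a pendant path hanging off clique 1
  base <- make_two_cliques()
  el <- igraph::as_edgelist(base)
  g <- graph_from_edges(dplyr::bind_rows(
    edges_df(el[, 1], el[, 2]),
    edges_df(c("c", "p1", "p2"), c("p1", "p2", "p3"))))
  fit <- spectral_cluster(g, "flow", k = 2, seed = 2)
  expect_setequal(fit$pruned, c("p1", "p2", "p3"))
  lab <- stats::setNames(fit$partition$cluster, fit$partition$node)
  expect_equal(unname(lab[c("p1", "p2", "p3")]), rep(unname(lab["c"]), 3))
})

test_that("clustering preconditions are enforced", {
  g <- make_two_cliques()
  expect_error(spectral_cluster(g, "flow", k = 1), "at least 2")
  disc <- graph_from_edges(edges_df(c("a", "c"), c("b", "d")))
  expect_error(spectral_cluster(disc, "modularity", k = 2), "connected")
  pt <- make_path(letters[1:4])
  expect_error(spectral_cluster(pt, "flow", k = 2), "2-core")
})

test_that("recovery improves monotonically with cluster strength", {
  w_grid <- c(0.08, 0.2, 0.35, 0.5)
  means <- vapply(seq_along(w_grid), function(i) {
    amis <- vapply(1:4, function(s) {
      sbm <- generate_sbm(c(40, 40, 40), w_in = w_grid[i], w_out = 0.05,
                          seed = 100 * i + s)
      g <- largest_component(remove_isolated(sbm$graph))
      fit <- spectral_cluster(g, "flow", k = 3, seed = s)
      adjusted_mutual_information(
        nbflow:::complete_partition(fit$partition, sbm$partition$node),
        sbm$partition)
    }, numeric(1))
    mean(amis)
  }, numeric(1))
  expect_gt(suppressWarnings(cor(means, seq_along(means), method = "spearman")),
            0.9)
})
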