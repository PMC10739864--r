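test_that("directed edge index is a paired bijection over 2C edges", {
  g <- make_two_cliques()
  idx <- directed_edge_index(g)
  expect_equal(nrow(idx), 2L * igraph::ecount(g))
  expect_identical(idx$rev[idx$rev], idx$idx)        # rev is an involution
  expect_identical(idx$from, idx$to[idx$rev])        # rev really reverses
  # orientation pairs are adjacent, min->max first
  odd <- seq(1, nrow(idx), by = 2)
  expect_true(all(idx$from[odd] < idx$to[odd]))
  expect_identical(idx$rev[odd], idx$idx[odd] + 1L)
})

test_that("Hashimoto matrix of a path has the two end-to-end walks only", {
  g <- make_path(c("a", "b", "c"))
  B <- build_hashimoto(g)
  idx <- attr(B, "edge_index")
  lab <- paste(idx$from, idx$to, sep = ">")
  nz <- which(as.matrix(B) == 1, arr.ind = TRUE)
  hops <- paste(lab[nz[, 1]], lab[nz[, 2]])
  expect_setequal(hops, c("a>b b>c", "c>b b>a"))
  expect_equal(sum(as.matrix(B %*% B)), 0)           # B^2 vanishes on a path
})

test_that("Hashimoto matrix of a triangle is a permutation with two 3-cycles", {
  g <- make_complete(c("a", "b", "c"))
  B <- as.matrix(build_hashimoto(g))
  expect_true(all(rowSums(B) == 1) && all(colSums(B) == 1))
  expect_equal(B %*% B %*% B, diag(6), ignore_attr = TRUE)
  expect_false(isTRUE(all.equal(B, diag(6), check.attributes = FALSE)))
})

test_that("Hashimoto rows of a star reflect dead-end and return walks", {
  g <- graph_from_edges(edges_df(c("hub", "hub", "hub"), c("x", "y", "z")))
  B <- as.matrix(build_hashimoto(g))
  idx <- attr(build_hashimoto(g), "edge_index")
  to_leaf <- which(idx$from == "hub")
  to_hub <- which(idx$to == "hub")
  expect_true(all(rowSums(B)[to_leaf] == 0))         # leaf rows are dead ends
  expect_true(all(rowSums(B)[to_hub] == 2))          # back to any other leaf
})

test_that("powers of B count non-backtracking walks (enumeration oracle)", {
  for (s in 1:12) {
    g <- make_gnp(7, 0.45, seed = 100 + s)
    if (igraph::ecount(g) < 2) next
    B <- build_hashimoto(g)
    idx <- attr(B, "edge_index")
    P <- diag(nrow(B))
    for (p in 1:3) {
      P <- P %*% B
      expect_equal(as.matrix(P), count_nb_walks(g, p, idx),
                   ignore_attr = TRUE)
    }
  }
})

test_that("flow matrix is row-stochastic with entries 1/(d-1)", {
  g <- make_complete(letters[1:4])                   # K4: d = 3 everywhere
  F_ <- build_flow(g)
  expect_equal(unique(F_@x), 0.5)
  expect_equal(unname(Matrix::rowSums(F_ != 0)), rep(2, nrow(F_)))
  expect_equal(unname(Matrix::rowSums(F_)), rep(1, nrow(F_)), tolerance = 1e-12)

  tri <- make_complete(c("a", "b", "c"))             # d-1 = 1: F equals B
  expect_equal(as.matrix(build_flow(tri)), as.matrix(build_hashimoto(tri)),
               ignore_attr = TRUE)
})

test_that("flow matrix refuses vertices of degree below 2, naming them", {
  g <- make_path(c("a", "b", "c"))
  expect_error(build_flow(g), "a")
  expect_error(build_flow(g), "two_core")
})

test_that("bulk radius matches its closed forms", {
  expect_equal(bulk_radius(make_cycle(7)), 1)                    # 2-regular
  expect_equal(bulk_radius(make_complete(letters[1:4])), 1 / sqrt(2))
  g <- graph_from_edges(edges_df(c("a", "a", "b", "c", "b"),
                                 c("b", "c", "c", "d", "d")))
  expect_equal(sort(unname(igraph::degree(g))), c(2, 2, 3, 3))
  expect_equal(bulk_radius(g), sqrt(0.7))
  expect_error(bulk_radius(make_path(c("a", "b", "c"))), "degree")
})

test_that("modularity matrix has vanishing row sums and exact small cases", {
  se <- graph_from_edges(edges_df("a", "b"))
  expect_equal(build_modularity(se),
               matrix(c(-0.5, 0.5, 0.5, -0.5), 2,
                      dimnames = list(c("a", "b"), c("a", "b"))))
  k3 <- make_complete(c("a", "b", "c"))
  M <- build_modularity(k3)
  expect_equal(unname(diag(M)), rep(-2 / 3, 3))   # d_i d_j / 2C = 4/6
  expect_equal(M[1, 2], 1 / 3)
  g <- make_gnp(12, 0.4, seed = 9)
  expect_equal(unname(rowSums(build_modularity(g))), rep(0, 12),
               tolerance = 1e-12)
  expect_error(build_modularity(graph_from_edges(edges_df(character(),
                                                          character()),
                                                 nodes = c("a", "b"))),
               "edgeless")
})

test_that("Laplacians are PSD with the expected small-case spectra", {
  se <- graph_from_edges(edges_df("a", "b"))
  L <- build_laplacian(se)
  expect_equal(unname(L), matrix(c(1, -1, -1, 1), 2))
  expect_equal(eigen(L, symmetric = TRUE)$values, c(2, 0))

  k3 <- make_complete(c("a", "b", "c"))
  ln <- build_laplacian(k3, normalized = TRUE)
  expect_equal(eigen(ln, symmetric = TRUE)$values, c(1.5, 1.5, 0))

  for (s in 1:5) {
    g <- largest_component(make_gnp(15, 0.3, seed = s))
    expect_gte(min(eigen(build_laplacian(g), symmetric = TRUE)$values), -1e-10)
    expect_gte(min(eigen(build_laplacian(g, normalized = TRUE),
                         symmetric = TRUE)$values), -1e-10)
    expect_equal(unname(rowSums(build_laplacian(g))), rep(0, 15),
                 tolerance = 1e-12)
  }
})

test_that("operators export to Matrix Market and read back", {
  g <- make_two_cliques()
  f <- withr::local_tempfile(fileext = ".mtx")
  write_operator_mtx(build_flow(g), f)
  X <- Matrix::readMM(f)
  expect_equal(as.matrix(X), as.matrix(build_flow(g)), ignore_attr = TRUE)
})
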