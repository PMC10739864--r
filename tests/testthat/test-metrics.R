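two_triangles <- function() {
  graph_from_edges(edges_df(c("a", "b", "c", "d", "e", "f"),
                            c("b", "c", "a", "e", "f", "d")))
}

test_that("Q reproduces its exact small cases", {
  g <- two_triangles()
  split_p <- tibble::tibble(node = letters[1:6], cluster = rep(1:2, each = 3))
  expect_equal(q_score(g, split_p), 0.5)
  one_p <- tibble::tibble(node = letters[1:6], cluster = rep(1L, 6))
  expect_equal(q_score(g, one_p), 0)
  se <- graph_from_edges(edges_df("a", "b"))
  expect_equal(q_score(se, tibble::tibble(node = c("a", "b"), cluster = 1:2)),
               -0.5)
})

test_that("Q agrees with the literal double sum and with igraph", {
  for (s in 1:5) {
    sbm <- generate_sbm(c(15, 15), 0.4, 0.1, seed = s)
    g <- largest_component(remove_isolated(sbm$graph))
    p <- tibble::tibble(node = graph_nodes(g),
                        cluster = withr::with_seed(s,
                          sample(1:3, igraph::vcount(g), replace = TRUE)))
    q <- q_score(g, p)
    expect_equal(q, q_direct_oracle(g, p), tolerance = 1e-12)
    expect_equal(q, igraph::modularity(g, p$cluster), tolerance = 1e-12)
  }
})

test_that("mutual information matches hand-computable tables", {
  U <- tibble::tibble(node = letters[1:4], cluster = c(1L, 1L, 2L, 2L))
  V <- tibble::tibble(node = letters[1:4], cluster = c(1L, 2L, 1L, 2L))
  expect_equal(mutual_information(U, V), 0)
  expect_equal(mutual_information(U, U), log(2))
  W <- tibble::tibble(node = letters[1:4], cluster = rep(1L, 4))
  expect_equal(mutual_information(U, W), 0)
  expect_error(mutual_information(U,
    tibble::tibble(node = c("x", "y"), cluster = 1:2)), "no nodes")
})

test_that("MI is bounded by the partition entropies on random cases", {
  for (s in 1:20) {
    lab <- withr::with_seed(s, list(u = sample(1:3, 8, TRUE),
                                    v = sample(1:4, 8, TRUE)))
    U <- tibble::tibble(node = letters[1:8], cluster = lab$u)
    V <- tibble::tibble(node = letters[1:8], cluster = lab$v)
    mi <- mutual_information(U, V)
    h <- function(x) { p <- table(x) / 8; -sum(p * log(p)) }
    expect_gte(mi, -1e-12)
    expect_lte(mi, min(h(lab$u), h(lab$v)) + 1e-12)
    expect_equal(mi, mutual_information(V, U), tolerance = 1e-12)
  }
})

test_that("AMI identities: self is 1, chance centres at 0, symmetry holds", {
  U <- tibble::tibble(node = letters[1:8], cluster = rep(1:2, each = 4))
  expect_equal(adjusted_mutual_information(U, U), 1)

  rand_amis <- vapply(1:400, function(s) {
    V <- tibble::tibble(node = letters[1:8],
                        cluster = withr::with_seed(s, sample(rep(1:2, each = 4))))
    adjusted_mutual_information(U, V)
  }, numeric(1))
  expect_lt(abs(mean(rand_amis)), 0.02)

  V <- tibble::tibble(node = letters[1:8], cluster = c(1, 1, 2, 2, 2, 3, 3, 3))
  expect_equal(adjusted_mutual_information(U, V),
               adjusted_mutual_information(V, U), tolerance = 1e-12)

  triv <- tibble::tibble(node = letters[1:8], cluster = rep(1L, 8))
  expect_equal(adjusted_mutual_information(triv, triv), 1)
})

test_that("AMI matches the exhaustive permutation oracle", {
  # 6 nodes, marginals (3,3) x (2,4), overlap matrix [[2,1],[0,3]]
  U <- tibble::tibble(node = letters[1:6], cluster = c(1L, 1L, 1L, 2L, 2L, 2L))
  V <- tibble::tibble(node = letters[1:6], cluster = c(1L, 1L, 2L, 2L, 2L, 2L))
  expect_identical(unclass(unname(nbflow:::contingency(U, V))),
                   matrix(c(2L, 0L, 1L, 3L), 2))
  expect_equal(adjusted_mutual_information(U, V),
               ami_permutation_oracle(U, V), tolerance = 1e-10)
  # a second, asymmetric table
  U2 <- tibble::tibble(node = letters[1:7], cluster = c(1, 1, 1, 1, 2, 2, 3))
  V2 <- tibble::tibble(node = letters[1:7], cluster = c(1, 2, 1, 2, 2, 1, 2))
  expect_equal(adjusted_mutual_information(U2, V2),
               ami_permutation_oracle(U2, V2), tolerance = 1e-10)
})

test_that("metrics are invariant to cluster relabelling", {
  g <- make_two_cliques()
  p <- tibble::tibble(node = letters[1:10], cluster = rep(1:2, each = 5))
  truth <- clique_truth()
  for (s in 1:5) {
    perm <- withr::with_seed(s, sample(1:2))
    q <- tibble::tibble(node = p$node, cluster = perm[p$cluster])
    expect_equal(q_score(g, q), q_score(g, p))
    expect_equal(adjusted_mutual_information(q, truth),
                 adjusted_mutual_information(p, truth))
    expect_equal(mutual_information(q, truth), mutual_information(p, truth))
  }
})

test_that("enrichment p-values are exact hypergeometric tails", {
  # cluster identical to its category: p = 1 / choose(n, m)
  part <- tibble::tibble(node = sprintf("n%02d", 1:10),
                         cluster = rep(1:2, each = 5))
  ann <- tibble::tibble(node = sprintf("n%02d", 1:10),
                        label = rep(c("A", "B"), each = 5))
  res <- overlap_enrichment(part, ann)
  pAA <- res$p_value[res$cluster == 1 & res$category == "A"]
  expect_equal(pAA, 1 / choose(10, 5))

  # fixed toy: universe 20, cluster 5, category 5, overlap 4
  part2 <- tibble::tibble(node = sprintf("n%02d", 1:20),
                          cluster = c(rep(1L, 5), rep(2L, 15)))
  ann2 <- tibble::tibble(node = sprintf("n%02d", 1:20),
                         label = c(rep("X", 4), "Y", "X", rep("Y", 14)))
  res2 <- overlap_enrichment(part2, ann2)
  row <- res2[res2$cluster == 1 & res2$category == "X", ]
  expect_equal(row$overlap, 4L)
  expect_equal(row$p_value, hyper_tail_oracle(4, 5, 20, 5), tolerance = 1e-12)

  # uniformly spread category is unenriched
  ann3 <- tibble::tibble(node = sprintf("n%02d", 1:20),
                         label = rep(c("X", "Y"), 10))
  res3 <- overlap_enrichment(part2, ann3)
  expect_gt(min(res3$p_value[res3$category == "X"]), 0.3)
})

test_that("cluster cosine similarity counts shared members", {
  U <- tibble::tibble(node = sprintf("n%02d", 1:8), cluster = rep(1:2, each = 4))
  expect_equal(partition_cosine(U, U)$cosine, c(1, 0, 0, 1))

  V <- tibble::tibble(node = sprintf("n%02d", 3:10), cluster = rep(1:2, each = 4))
  cs <- partition_cosine(U, V)
  expect_equal(cs$cosine[cs$cluster_u == "1" & cs$cluster_v == "1"], 0.5)

  # merging clusters into compartments first
  cs2 <- partition_cosine(U, U, groups_u = c(`1` = "W", `2` = "W"),
                          groups_v = c(`1` = "W", `2` = "W"))
  expect_equal(cs2$cosine, 1)
})
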