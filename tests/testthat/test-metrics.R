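test_that("strengths follow the row/column orientation convention", {
  w <- matrix(0, 2, 2)
  w[2, 1] <- 0.4   # edge 0 -> 1 in 0-based terms: source column 1, target row 2
  conn <- connectome(w)
  expect_equal(unname(node_strengths(conn, "in")), c(0, 0.4))
  expect_equal(unname(node_strengths(conn, "out")), c(0.4, 0))
  expect_equal(unname(node_strengths(conn, "total")), c(0.4, 0.4))

  sym <- random_connectome(8, seed = 2)
  sym$weights <- (sym$weights + t(sym$weights)) / 2
  expect_equal(node_strengths(sym, "in"), node_strengths(sym, "out"))

  for (seed in 1:5) {
    conn <- random_connectome(7, seed = seed)
    brute <- sapply(seq_len(7), function(i) {
      sum(conn$weights[i, ]) + sum(conn$weights[, i])
    })
    expect_equal(unname(node_strengths(conn, "total")), brute)
  }
})

test_that("k-core handles the canonical graphs", {
  # complete graph on 5 nodes: everyone survives to k = 4
  w <- matrix(1, 5, 5); diag(w) <- 0
  kc <- k_core_decomposition(connectome(w))
  expect_equal(unname(kc$node_coreness), rep(4, 5))
  expect_equal(kc$max_core_level, 4)
  expect_length(kc$max_core_members, 5)

  # star: hub falls together with its degree-1 leaves
  w <- matrix(0, 7, 7)
  w[1, 2:7] <- 1; w[2:7, 1] <- 1
  kc <- k_core_decomposition(connectome(w))
  expect_equal(unname(kc$node_coreness), rep(1, 7))
  expect_equal(kc$max_core_level, 1)
})

test_that("k-coreness matches the exhaustive-subgraph oracle and igraph", {
  for (seed in 1:8) {
    conn <- random_connectome(8, density = 0.45, seed = seed)
    kc <- k_core_decomposition(conn)
    expect_equal(unname(kc$node_coreness), oracle_k_coreness(conn),
                 label = paste("seed", seed))
    a <- (conn$weights > 0 | t(conn$weights) > 0) * 1
    ig <- igraph::coreness(igraph::graph_from_adjacency_matrix(
      a, mode = "undirected"))
    expect_equal(unname(kc$node_coreness), unname(ig))
  }
})

test_that("s-core uses within-subgraph total strength", {
  # symmetric triangle, every directed entry w: each node keeps 2 in- and
  # 2 out-links inside the subgraph, so coreness = 4w for all three
  w <- matrix(0.3, 3, 3); diag(w) <- 0
  sc <- s_core_decomposition(connectome(w))
  expect_equal(unname(sc$node_coreness), rep(1.2, 3))
  expect_equal(sc$max_core_level, 1.2)
  expect_length(sc$max_core_members, 3)
})

test_that("s-coreness matches the brute-force subset oracle", {
  for (seed in 1:8) {
    conn <- random_connectome(8, density = 0.45, seed = seed)
    sc <- s_core_decomposition(conn)
    expect_equal(unname(sc$node_coreness), oracle_s_coreness(conn),
                 tolerance = 1e-12, label = paste("seed", seed))
  }
})

test_that("s-core on a unit-weight symmetric graph reproduces 2x the k-core", {
  for (seed in 1:5) {
    conn <- random_connectome(9, density = 0.4, seed = seed)
    a <- (conn$weights > 0 | t(conn$weights) > 0) * 1
    diag(a) <- 0
    sym <- connectome(a)
    expect_equal(unname(s_core_decomposition(sym)$node_coreness),
                 2 * unname(k_core_decomposition(sym)$node_coreness))
  }
})

test_that("s-coreness scales exactly with a global weight factor", {
  conn <- random_connectome(10, seed = 4)
  base <- s_core_decomposition(conn)
  for (c_fac in c(0.1, 3.7)) {
    scaled <- connectome(conn$weights * c_fac)
    got <- s_core_decomposition(scaled)
    expect_equal(unname(got$node_coreness),
                 c_fac * unname(base$node_coreness), tolerance = 1e-12)
    expect_equal(got$max_core_level, c_fac * base$max_core_level,
                 tolerance = 1e-12)
  }
})

test_that("cores are nested at every level for both decompositions", {
  for (seed in 1:5) {
    conn <- random_connectome(12, density = 0.35, seed = seed)
    for (dec in list(k_core_decomposition(conn),
                     s_core_decomposition(conn))) {
      cn <- dec$node_coreness
      lvls <- sort(unique(cn))
      prev <- seq_along(cn)
      for (l in lvls) {
        members <- which(cn >= l)
        expect_true(all(members %in% prev))
        prev <- members
      }
      expect_gt(length(dec$max_core_members), 0)
      expect_equal(sort(unlist(dec$shells, use.names = FALSE)),
                   seq_along(cn))
    }
  }
})

test_that("sigma is 1 for a complete graph and ~1 for an ER graph", {
  w <- matrix(1, 8, 8); diag(w) <- 0
  sw <- small_world_sigma(connectome(w), n_random = 5, seed = 1)
  expect_equal(sw$sigma, 1)
  expect_equal(sw$gamma_ratio, 1)
  expect_equal(sw$lambda_ratio, 1)

  set.seed(3)
  g <- igraph::sample_gnm(40, 160)
  a <- igraph::as_adjacency_matrix(g, sparse = FALSE)
  dimnames(a) <- NULL
  sw <- small_world_sigma(connectome(a), n_random = 50, seed = 9)
  # one realization scatters at the single-reference scale, i.e. the
  # across-reference SD (= dispersion * sqrt(n_random)), not the SE
  expect_lt(abs(sw$sigma - 1), 3 * sw$dispersion * sqrt(sw$n_random))
})

test_that("sigma errors on disconnected input and tiny ensembles", {
  w <- matrix(0, 4, 4)
  w[1, 2] <- w[2, 1] <- 1   # nodes 3, 4 isolated
  expect_error(small_world_sigma(connectome(w)), "disconnected")
  w2 <- matrix(1, 4, 4); diag(w2) <- 0
  expect_error(small_world_sigma(connectome(w2), n_random = 1), "n_random")
})
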