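test_that("homogenization keeps support and defaults to the mean weight", {
  conn <- random_connectome(12, density = 0.3, seed = 1)
  hw <- homogenize_weights(conn)
  expect_identical(hw$weights > 0, conn$weights > 0)
  nz <- hw$weights[hw$weights > 0]
  expect_equal(stats::var(nz), 0)
  expect_equal(nz[1], mean(conn$weights[conn$weights > 0]))
  hw2 <- homogenize_weights(conn, value = 0.5)
  expect_true(all(hw2$weights[hw2$weights > 0] == 0.5))
})

test_that("degree-preserving rewiring preserves the degree sequence exactly", {
  g <- planted_core_connectome(30, 240, core_size = 5, seed = 2)$connectome
  hw <- homogenize_weights(g)
  for (seed in 1:5) {
    dpr <- degree_preserving_randomize(hw, seed = seed)
    expect_identical(node_degrees(dpr), node_degrees(hw))
    expect_equal(sum(dpr$weights > 0), sum(hw$weights > 0))
    nz <- dpr$weights[dpr$weights > 0]
    expect_equal(stats::var(nz), 0)
  }
})

test_that("rewiring genuinely randomises the wiring (Jaccard < 0.7)", {
  g <- hagmann_like_connectome(seed = 3)
  hw <- homogenize_weights(g$connectome)
  ref_edges <- which(hw$weights > 0)
  hits <- 0
  for (seed in 1:20) {
    dpr <- degree_preserving_randomize(hw, swaps_per_edge = 10, seed = seed)
    new_edges <- which(dpr$weights > 0)
    jac <- length(intersect(ref_edges, new_edges)) /
      length(union(ref_edges, new_edges))
    if (jac < 0.7) hits <- hits + 1
  }
  expect_gte(hits, 19)
})

test_that("weight permutation preserves multiset and support exactly", {
  g <- hagmann_like_connectome(seed = 4)$connectome
  rw <- permute_weights(g, g, seed = 5)
  expect_identical(rw$weights > 0, g$weights > 0)
  expect_identical(sort(rw$weights[rw$weights > 0]),
                   sort(g$weights[g$weights > 0]))
  # strengths are scrambled in essentially every permutation
  changed <- 0
  for (seed in 1:20) {
    rw <- permute_weights(g, g, seed = seed)
    if (!isTRUE(all.equal(node_strengths(rw), node_strengths(g)))) {
      changed <- changed + 1
    }
  }
  expect_gte(changed, 20)
  small <- connectome(matrix(c(0, 1, 0, 0), 2, 2))
  expect_error(permute_weights(g, small), "link-count mismatch")
})

test_that("small-world ensemble selection is optimal by construction", {
  ens <- small_world_ensemble(n = 40, edge_count = 160, sigma_target = 1.5,
                              n_generate = 30, n_select = 8,
                              value = 0.01, n_random = 8, seed = 6)
  expect_length(ens$members, 8)
  expect_equal(ens$kind, "sw_hw")
  for (m in ens$members) {
    expect_silent(validate_connectome(m))
    nz <- m$weights[m$weights > 0]
    expect_true(all(nz == 0.01))
  }
  # selected sigmas bracket the target at least as well as the median candidate
  expect_lt(mean(abs(ens$sigma - 1.5)), 0.35)
})

test_that("build_ensemble composes the six kinds with their invariants", {
  g <- planted_core_connectome(30, 240, core_size = 5, seed = 9)$connectome

  dpr_hw <- build_ensemble("dpr_hw", g, size = 5, seed = 11)
  expect_length(dpr_hw$members, 5)
  for (m in dpr_hw$members) {
    expect_identical(node_degrees(m), node_degrees(g))
    expect_equal(stats::var(m$weights[m$weights > 0]), 0)
  }

  hrw <- build_ensemble("human_rw", g, size = 4, seed = 12)
  ref_sorted <- sort(g$weights[g$weights > 0])
  for (m in hrw$members) {
    expect_identical(m$weights > 0, g$weights > 0)
    expect_identical(sort(m$weights[m$weights > 0]), ref_sorted)
  }

  drw <- build_ensemble("dpr_rw", g, size = 4, seed = 13)
  for (m in drw$members) {
    expect_identical(node_degrees(m), node_degrees(g))
    expect_identical(sort(m$weights[m$weights > 0]), ref_sorted)
  }

  hhw <- build_ensemble("human_hw", g, seed = 14)
  expect_length(hhw$members, 1)
  expect_identical(hhw$members[[1]]$weights > 0, g$weights > 0)
})

test_that("ensembles regenerate bit-exactly from the master seed", {
  g <- planted_core_connectome(24, 160, core_size = 4, seed = 20)$connectome
  for (kind in c("dpr_hw", "human_rw", "dpr_rw")) {
    e1 <- build_ensemble(kind, g, size = 3, seed = 77)
    e2 <- build_ensemble(kind, g, size = 3, seed = 77)
    for (k in seq_along(e1$members)) {
      expect_identical(e1$members[[k]]$weights, e2$members[[k]]$weights,
                       label = kind)
    }
  }
})
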