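cfg <- metric_config(rng_seed = 123)

test_that("toy skeletons reproduce hand-derived metric values exactly", {
  toys <- toy_skeletons()

  g <- build_graph(toys$line3)
  m <- compute_all_metrics(g, cfg)
  expect_identical(m$n_nodes, 3L)
  expect_identical(m$n_edges, 2L)
  expect_equal(m$avg_degree, 4 / 3)
  expect_equal(m$avg_clustering, 0)
  expect_equal(m$global_efficiency, 5 / 6)
  expect_equal(m$avg_betweenness, 1 / 3)
  expect_equal(m$avg_tortuosity, 1)
  expect_identical(m$n_components, 1L)
  expect_identical(m$largest_component_size, 3L)
  expect_equal(m$connectivity_index, 1)
  expect_equal(m$network_density, 2 / 3)

  g2 <- build_graph(toys$l_triangle)
  expect_equal(average_degree(g2), 2)
  expect_equal(average_clustering(g2), 1)
  expect_equal(network_density(g2), 1)
  expect_equal(average_betweenness(g2, cfg), 0)
  expect_equal(average_tortuosity(g2, cfg), 1)  # diagonal edge = Euclidean

  # U-shaped 5-pixel path: the corner pixels (1,0) and (2,1) are diagonally
  # 8-adjacent, so the shortest path across the bend is 1 + sqrt(2) + 1 and
  # the forced-pair tortuosity is (2 + sqrt(2)) / (2 * sqrt(2))
  u <- matrix(FALSE, 4, 4)
  u[cbind(c(1, 2, 3, 3, 3), c(1, 1, 1, 2, 3))] <- TRUE
  gu <- build_graph(u)
  co <- node_coords(gu)
  a <- which(co$row == 0 & co$col == 0)
  b <- which(co$row == 2 & co$col == 2)
  expect_equal(average_tortuosity(gu, cfg, pairs = cbind(a, b)),
               (2 + sqrt(2)) / (2 * sqrt(2)))

  # straight line: every sampled pair has tortuosity exactly 1
  gl <- build_graph(toys$line9)
  expect_equal(average_tortuosity(gl, metric_config(rng_seed = 77)), 1)
})

test_that("component statistics and density handle fragmentation and degenerate graphs", {
  frag <- matrix(FALSE, 6, 10)
  frag[2, 2:4] <- TRUE    # 3-px line
  frag[5, 8] <- TRUE      # isolated pixel
  cs <- component_stats(build_graph(frag))
  expect_identical(cs$n_components, 2L)
  expect_identical(cs$largest_component_size, 3L)
  expect_equal(cs$connectivity_index, 0.75)

  gi <- build_graph(toy_skeletons()$isolated)
  csi <- component_stats(gi)
  expect_identical(csi$n_components, 8L)
  expect_equal(csi$connectivity_index, 1 / 8)
  expect_equal(network_density(gi), 0)
  expect_equal(global_efficiency(gi, cfg), 0)
  expect_error(average_tortuosity(gi, cfg), "fragmented")

  single <- matrix(FALSE, 3, 3); single[2, 2] <- TRUE
  gs <- build_graph(single)
  expect_equal(average_degree(gs), 0)
  expect_error(network_density(gs), "at least 2")
  expect_error(global_efficiency(gs, cfg), "at least 2")
  expect_warning(ms <- compute_all_metrics(gs, cfg), "undefined")
  expect_true(is.na(ms$global_efficiency))
  expect_true(is.na(ms$avg_tortuosity))
  expect_identical(ms$n_nodes, 1L)

  expect_error(compute_all_metrics(build_graph(matrix(FALSE, 2, 2)), cfg),
               "at least 1")
})

test_that("efficiency, clustering and betweenness match brute-force oracles on random graphs", {
  withr::with_seed(2024, {
    for (i in 1:40) {
      g <- random_weighted_graph(sample(4:12, 1), p = 0.35)
      if (igraph::vcount(g) < 3) next
      expect_equal(global_efficiency(g, cfg), oracle_efficiency(g),
                   tolerance = 1e-9)
      expect_equal(average_clustering(g), oracle_clustering(g),
                   tolerance = 1e-9)
      expect_equal(average_betweenness(g, cfg), oracle_betweenness(g),
                   tolerance = 1e-9)
    }
  })
  # pixel graphs with {1, sqrt(2)} weights: tie-free quantities vs oracles
  withr::with_seed(31, {
    for (i in 1:10) {
      g <- build_graph(random_mask(9, 9, 0.3))
      if (igraph::vcount(g) < 2) next
      expect_equal(global_efficiency(g, cfg), oracle_efficiency(g),
                   tolerance = 1e-9)
      expect_equal(average_clustering(g), oracle_clustering(g),
                   tolerance = 1e-9)
    }
  })
})

test_that("metric record invariants hold and sampling is seeded and exact when exhaustive", {
  syn <- generate_mesh_image(synthetic_config(image_size = c(160, 160),
                                              n_seeds = 12, rng_seed = 4))
  g <- build_graph(skeletonize(preprocess_image(syn$image)))
  m1 <- compute_all_metrics(g, metric_config(rng_seed = 5))
  m2 <- compute_all_metrics(g, metric_config(rng_seed = 5))
  expect_identical(m1, m2)   # seeded determinism incl. tortuosity
  expect_equal(m1$avg_degree, 2 * m1$n_edges / m1$n_nodes)
  expect_gte(m1$avg_tortuosity, 1 - 1e-9)
  expect_true(m1$avg_clustering >= 0 && m1$avg_clustering <= 1)
  expect_true(m1$network_density >= 0 && m1$network_density <= 1)

  # sample >= all pairs equals the exact all-pairs mean
  gl <- build_graph(toy_skeletons()$cross)
  n <- igraph::vcount(gl)
  all_pairs <- t(utils::combn(seq_len(n), 2))
  exact <- average_tortuosity(gl, cfg, pairs = all_pairs)
  sampled <- average_tortuosity(gl, metric_config(
    tortuosity_sample_pairs = n * (n - 1) / 2 + 10, rng_seed = 1))
  expect_equal(sampled, exact, tolerance = 1e-12)

  # metrics invariant under translation of the skeleton
  sk <- toy_skeletons()$ring
  big <- matrix(FALSE, 30, 30); big[10:22, 12:24] <- sk
  ma <- compute_all_metrics(build_graph(sk), metric_config(rng_seed = 2))
  mb <- compute_all_metrics(build_graph(big), metric_config(rng_seed = 2))
  for (nm in setdiff(metric_names(), "avg_tortuosity"))
    expect_equal(ma[[nm]], mb[[nm]])
  # tortuosity compared on identical (translated) forced pairs
  expect_equal(average_tortuosity(build_graph(sk), cfg, pairs = cbind(1, 5)),
               average_tortuosity(build_graph(big), cfg, pairs = cbind(1, 5)))
})

test_that("connectivity index never decreases when a bridging edge is added", {
  withr::with_seed(99, {
    for (i in 1:20) {
      g <- random_weighted_graph(10, p = 0.15)
      comp <- igraph::components(g)
      if (comp$no < 2) next
      ci0 <- component_stats(g)$connectivity_index
      v1 <- which(comp$membership == 1)[1]
      v2 <- which(comp$membership == 2)[1]
      g2 <- igraph::add_edges(g, c(v1, v2), attr = list(weight = 1))
      expect_gte(component_stats(g2)$connectivity_index, ci0)
    }
  })
})
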