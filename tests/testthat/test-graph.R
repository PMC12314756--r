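test_that("graph construction conserves vertices and edges", {
  g <- build_semantic_graph(diag(2))
  expect_equal(n_vertices(g), 4)
  expect_equal(n_edges(g), 2)

  g0 <- build_semantic_graph(matrix(0, 3, 4))
  expect_equal(n_vertices(g0), 7)
  expect_equal(n_edges(g0), 0)

  coh <- simulate_cohort(cohort_config(seed = 1))
  gg <- build_semantic_graph(coh$Z, coh$labels)
  expect_equal(n_vertices(gg), 904)
  expect_equal(n_edges(gg), sum(coh$Z))
  expect_error(build_semantic_graph(matrix(2, 2, 2)), "binary")
})

test_that("normalized adjacency follows D^-1/2 A D^-1/2 with zero-degree safety", {
  # two vertices, one edge
  a <- adjacency(build_semantic_graph(matrix(1, 1, 1)))
  expect_equal(as.numeric(a$A_hat[1, 2]), 1)

  # star: one feature linked to 4 images
  star <- build_semantic_graph(matrix(1, 4, 1))
  ah <- adjacency(star)$A_hat
  expect_equal(as.numeric(ah[5, 1]), 0.5)
  expect_equal(as.numeric(ah[1, 5]), 0.5)

  # isolated vertex: zero row/column, no division error
  Z <- rbind(c(1, 0), c(0, 0))
  g <- build_semantic_graph(Z)
  ah <- adjacency(g)$A_hat
  expect_true(all(ah[2, ] == 0) && all(ah[, 2] == 0))

  # symmetry and diagonal convention
  coh <- simulate_cohort(tiny_cohort_config(seed = 2))
  g <- build_semantic_graph(coh$Z)
  pair <- adjacency(g)
  expect_lt(max(abs(pair$A_hat - Matrix::t(pair$A_hat))), 1e-12)
  expect_true(all(Matrix::diag(pair$A) == 0))
  with_loops <- adjacency(g, self_loops = TRUE)
  expect_true(all(Matrix::diag(with_loops$A) == 1))
})

test_that("spectral radius of the normalized adjacency is at most 1", {
  set.seed(9)
  for (i in 1:10) {
    Z <- matrix(rbinom(6 * 4, 1, 0.5), 6, 4)
    ah <- as.matrix(adjacency(build_semantic_graph(Z))$A_hat)
    expect_lte(max(abs(eigen(ah, only.values = TRUE)$values)), 1 + 1e-10)
  }
})

test_that("graph density follows the undirected simple-graph convention", {
  k22 <- build_semantic_graph(matrix(1, 2, 2))
  expect_equal(graph_density(k22), 4 / 6)
  expect_equal(graph_density(build_semantic_graph(matrix(0, 3, 3))), 0)
  expect_error(graph_density(build_semantic_graph(matrix(0, 1, 0))), "2 vertices")
})

test_that("drop_edges keeps the exact count and the bipartite invariants", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 3))
  g <- build_semantic_graph(coh$Z)
  expect_identical(drop_edges(g, 1.0, seed = 1)$edges, g$edges)

  m100 <- build_semantic_graph(matrix(rbinom(500, 1, 0.2), 25, 20))
  g80 <- drop_edges(m100, 0.8, seed = 4)
  expect_equal(n_edges(g80), round(0.8 * n_edges(m100)))
  expect_error(drop_edges(g, 0))

  for (s in 1:50) {
    gk <- drop_edges(g, runif(1, 0.3, 1), seed = s)
    expect_equal(n_vertices(gk), n_vertices(g))
    key <- paste(gk$edges[, 1], gk$edges[, 2])
    expect_false(any(duplicated(key)))
    expect_true(all(key %in% paste(g$edges[, 1], g$edges[, 2])))
  }
})

test_that("removing a feature class matches rebuilding from column-deleted Z", {
  cat98 <- build_feature_catalog()
  coh <- simulate_cohort(cohort_config(seed = 4))
  g <- build_semantic_graph(coh$Z, coh$labels)

  g_lf <- remove_feature_class(g, cat98, "leaf and flower")
  expect_equal(length(g_lf$feature_ids), 95)
  g_can <- remove_feature_class(g, cat98, "canopy")
  expect_equal(length(g_can$feature_ids), 79)
  expect_error(remove_feature_class(g, cat98, "nonexistent"), "unknown")

  keep <- cat98$class_name != "canopy"
  rebuilt <- build_semantic_graph(coh$Z[, keep], coh$labels)
  expect_equal(g_can$feature_ids, rebuilt$feature_ids)
  expect_equal(g_can$edges, rebuilt$edges)
  expect_equal(g_can$image_ids, rebuilt$image_ids)
})

test_that("split_nodes uses round() and produces a partition", {
  s <- split_nodes(806, 0.8, seed = 1)
  expect_equal(sum(s$train), 645)
  expect_equal(sum(s$test), 161)
  expect_equal(sum(split_nodes(10, 0.8, seed = 1)$train), 8)
  expect_error(split_nodes(10, 0.01), "degenerate")

  set.seed(6)
  for (i in 1:20) {
    n <- sample(10:500, 1)
    f <- runif(1, 0.2, 0.9)
    sp <- split_nodes(n, f, seed = i)
    expect_equal(sum(sp$train) + sum(sp$test), n)
    expect_false(any(sp$train & sp$test))
    expect_equal(sum(sp$train), round(f * n))
  }
})

test_that("subset_training uses floor() matching the published subset sizes", {
  mask <- split_nodes(806, 0.8, seed = 1)$train
  sizes <- vapply(
    c(0.9, 0.8, 0.7, 0.6, 0.5),
    function(f) sum(subset_training(mask, f, seed = 2)),
    numeric(1)
  )
  expect_equal(sizes, c(580, 516, 451, 387, 322))
  expect_identical(subset_training(mask, 1.0, seed = 2), mask)
  kept <- subset_training(mask, 0.5, seed = 3)
  expect_true(all(mask[kept]))
})

test_that("graph serialization round-trips", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 5))
  g <- build_semantic_graph(coh$Z, coh$labels)
  ep <- withr::local_tempfile(fileext = ".tsv")
  vp <- withr::local_tempfile(fileext = ".csv")
  write_graph(g, ep, vp)
  back <- read_graph(ep, vp)
  expect_equal(back$image_ids, g$image_ids)
  expect_equal(back$feature_ids, g$feature_ids)
  expect_equal(back$labels, g$labels)
  expect_equal(
    back$edges[order(back$edges[, 1], back$edges[, 2]), ],
    g$edges
  )
})
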