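test_that("forward pass matches hand-computed propagation", {
  # 2-vertex single-edge graph, 1-dim inputs, single identity-weight layer
  g <- build_semantic_graph(matrix(1, 1, 1))
  ah <- adjacency(g)$A_hat
  params <- gcn_params(1, hidden_dims = 1, seed = 1)
  params$conv_weights[[1]] <- matrix(1)
  H <- gcn_forward(matrix(c(1, 2), 2, 1), ah, params)
  expect_equal(as.numeric(H), c(2, 1))

  # zero input with no conv bias stays zero through any depth
  coh <- simulate_cohort(tiny_cohort_config(seed = 20))
  gg <- build_semantic_graph(coh$Z)
  ah2 <- adjacency(gg)$A_hat
  p2 <- gcn_params(8, hidden_dims = c(5, 4), seed = 2)
  H2 <- gcn_forward(matrix(0, n_vertices(gg), 8), ah2, p2)
  expect_true(all(H2 == 0))
  expect_equal(p2$L, 2)
  expect_error(gcn_forward(matrix(0, n_vertices(gg), 3), ah2, p2), "mismatch")
})

test_that("softmax head probabilities and tie rule behave as specified", {
  params <- gcn_params(2, hidden_dims = 2, seed = 3)
  params$head_weight <- diag(2)
  params$head_bias <- c(0, 0)
  out <- classify_nodes(matrix(c(0, 0, 0, log(3)), 2, 2, byrow = TRUE), params)
  expect_equal(out$p_high[1], 0.5)
  expect_equal(out$hard_label[1], 0L) # tie goes to class 0
  expect_equal(out$p_high[2], 0.75)
  expect_equal(out$hard_label[2], 1L)

  set.seed(4)
  H <- matrix(rnorm(20), 10, 2)
  probs <- classify_nodes(H, params)
  expect_true(all(probs$p_high >= 0 & probs$p_high <= 1))
})

test_that("detection loss follows the one-sided weighted cross-entropy", {
  expect_equal(detection_loss(0.5, 1, w_c = 7), 7 * log(2))
  expect_equal(detection_loss(c(0.9, 0.1), c(1, 0), w_c = 1),
               -mean(log(c(0.9, 0.9))))
  expect_lt(detection_loss(c(1, 0), c(1, 0), w_c = 7), 1e-9)
  expect_error(detection_loss(numeric(0), numeric(0)), "empty")
  # weight multiplies only the positive term
  yhat <- c(0.3, 0.3)
  y <- c(1, 0)
  expect_equal(
    detection_loss(yhat, y, w_c = 5),
    -mean(c(5 * log(0.3), log(0.7)))
  )
})

test_that("analytic GCN gradients match central finite differences", {
  # 6-vertex fixture: 4 images x 2 features
  set.seed(5)
  Z <- matrix(rbinom(8, 1, 0.6), 4, 2)
  Z[1, 1] <- 1L # ensure at least one edge
  y <- c(1L, 0L, 0L, 1L)
  g <- build_semantic_graph(Z, y)
  ah <- adjacency(g)$A_hat
  X <- matrix(rnorm(6 * 3), 6, 3)
  params <- gcn_params(3, hidden_dims = c(4, 3), seed = 6)
  train_rows <- 1:4
  w_c <- 7

  loss_of <- function(pp) {
    H <- gcn_forward(X, ah, pp)
    logits <- sweep(H %*% t(pp$head_weight), 2, pp$head_bias, `+`)
    p1 <- exp(logits[, 2]) / (exp(logits[, 1]) + exp(logits[, 2]))
    detection_loss(p1[train_rows], y, w_c)
  }
  fwd <- tdtgraph:::.gcn_forward_full(X, ah, params)
  fwd$A_hat_t <- ah
  logits <- sweep(fwd$H_L %*% t(params$head_weight), 2, params$head_bias, `+`)
  p <- tdtgraph:::.softmax2(logits)
  g_an <- tdtgraph:::.gcn_gradients(params, fwd, p, train_rows, y, w_c)

  h <- 1e-5
  check_block <- function(get, set, grad) {
    b <- get(params)
    for (idx in seq_along(b)) {
      bp <- b; bp[idx] <- bp[idx] + h
      bm <- b; bm[idx] <- bm[idx] - h
      num <- (loss_of(set(params, bp)) - loss_of(set(params, bm))) / (2 * h)
      if (abs(num) > 1e-8) {
        expect_equal(grad[idx], num, tolerance = 1e-4)
      } else {
        expect_lt(abs(grad[idx] - num), 1e-6)
      }
    }
  }
  check_block(
    function(p) p$conv_weights[[1]],
    function(p, v) { p$conv_weights[[1]] <- matrix(v, nrow(p$conv_weights[[1]])); p },
    g_an$conv[[1]]
  )
  check_block(
    function(p) p$conv_weights[[2]],
    function(p, v) { p$conv_weights[[2]] <- matrix(v, nrow(p$conv_weights[[2]])); p },
    g_an$conv[[2]]
  )
  check_block(
    function(p) p$head_weight,
    function(p, v) { p$head_weight <- matrix(v, 2); p },
    g_an$head_w
  )
  check_block(
    function(p) p$head_bias,
    function(p, v) { p$head_bias <- v; p },
    g_an$head_b
  )
})

test_that("without self-loops, layer-1 image rows depend only on feature inputs", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 21))
  g <- build_semantic_graph(coh$Z)
  ah <- adjacency(g, self_loops = FALSE)$A_hat
  M <- length(g$image_ids)
  params <- gcn_params(6, hidden_dims = 5, seed = 7)
  set.seed(8)
  X <- matrix(rnorm(n_vertices(g) * 6), ncol = 6)
  X0 <- X
  X0[seq_len(M), ] <- 0 # zero all image inputs
  H1 <- gcn_forward(X, ah, params)
  H1z <- gcn_forward(X0, ah, params)
  expect_equal(H1[seq_len(M), ], H1z[seq_len(M), ])
})

test_that("predictions are equivariant to consistent vertex permutations", {
  set.seed(9)
  Z <- matrix(rbinom(5 * 3, 1, 0.5), 5, 3)
  y <- rbinom(5, 1, 0.5)
  perm_img <- sample(5)
  perm_feat <- sample(3)
  g1 <- build_semantic_graph(Z, y)
  g2 <- build_semantic_graph(Z[perm_img, perm_feat], y[perm_img])
  X <- matrix(rnorm(8 * 4), 8, 4)
  Xp <- X[c(perm_img, 5 + perm_feat), ]
  params <- gcn_params(4, hidden_dims = c(4, 3), seed = 10)
  c1 <- classify_nodes(gcn_forward(X, adjacency(g1)$A_hat, params), params)
  c2 <- classify_nodes(gcn_forward(Xp, adjacency(g2)$A_hat, params), params)
  expect_equal(c2$p_high[1:5], c1$p_high[perm_img])
  expect_equal(c2$p_high[6:8], c1$p_high[5 + perm_feat])
})

test_that("training is deterministic, converges, and exposes tidy summaries", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 22, effect_size = 3))
  g <- build_semantic_graph(coh$Z, coh$labels)
  sp <- split_nodes(nrow(coh$Z), 0.8, seed = 22)
  cfg <- embedding_config(
    k = 16, walks_per_node = 3, walk_length = 20, window = 3, epochs = 1,
    seed = 22
  )
  emb <- embed_graph(g, cfg)
  tcfg <- train_config(epochs = 120, patience = 120, seed = 22)
  fit <- train_detector(g, emb, sp$train, tcfg)
  fit2 <- train_detector(g, emb, sp$train, tcfg)
  expect_identical(fit$params, fit2$params)
  expect_identical(predict(fit), predict(fit2))

  # smoothed loss trace is non-increasing
  sm <- stats::filter(fit$loss_trace, rep(1 / 10, 10), sides = 1)
  sm <- sm[!is.na(sm)]
  expect_true(all(diff(sm) < 0.02))
  expect_lt(tail(sm, 1), sm[1])

  td <- tidy(fit)
  expect_equal(nrow(td), nrow(coh$Z))
  expect_setequal(unique(td$set), c("train", "test"))
  gl <- glance(fit)
  expect_equal(gl$layers, 2)
  expect_equal(gl$w_c, 7)

  # checkpoint round-trip preserves parameters to full precision
  path <- withr::local_tempfile(fileext = ".txt")
  write_checkpoint(fit$params, path)
  back <- read_checkpoint(path)
  expect_equal(back$conv_weights, fit$params$conv_weights)
  expect_equal(back$head_weight, fit$params$head_weight)
  expect_equal(back$head_bias, fit$params$head_bias)
})
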