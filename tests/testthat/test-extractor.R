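test_that("multi-label cross-entropy matches the brute-force double loop", {
  # single cell, z = 1, zhat = 0.5
  expect_equal(feature_ce_loss(matrix(0.5), matrix(1)), log(2))
  # perfect prediction (clipped)
  z <- matrix(rbinom(20, 1, 0.5), 5, 4)
  expect_lt(feature_ce_loss(z, z), 1e-10)
  expect_error(feature_ce_loss(matrix(0.5, 2, 2), matrix(1, 3, 2)), "shape")

  set.seed(3)
  for (i in 1:20) {
    z <- matrix(rbinom(20, 1, 0.5), 5, 4)
    p <- matrix(runif(20), 5, 4)
    expect_equal(feature_ce_loss(p, z), oracle_feature_ce(p, z))
  }
})

test_that("cost-sensitive loss weights the minority-class term only", {
  cfg1 <- extraction_loss_config(w_f = 1)
  cfg4 <- extraction_loss_config(w_f = 4, minority_direction = "presence")
  # single cell, presence minority, z = 1, zhat = 0.5
  expect_equal(feature_ce_loss_weighted(matrix(0.5), matrix(1), cfg4), 4 * log(2))
  # with absence minority the presence term stays unweighted
  cfg4a <- extraction_loss_config(w_f = 4, minority_direction = "absence")
  expect_equal(feature_ce_loss_weighted(matrix(0.5), matrix(1), cfg4a), log(2))

  set.seed(4)
  for (i in 1:20) {
    z <- matrix(rbinom(24, 1, 0.4), 6, 4)
    p <- matrix(runif(24, 0.05, 0.95), 6, 4)
    # w_f = 1 reduces exactly to the unweighted loss
    expect_equal(feature_ce_loss_weighted(p, z, cfg1), feature_ce_loss(p, z))
    # oracle with explicit per-side weights
    md <- minority_direction(z)
    w1 <- ifelse(md == "presence", 4, 1)
    w0 <- ifelse(md == "absence", 4, 1)
    cfg <- extraction_loss_config(w_f = 4, minority_direction = md)
    expect_equal(
      feature_ce_loss_weighted(p, z, cfg),
      oracle_feature_ce(p, z, w1, w0)
    )
    # extra mass on imperfect minority predictions
    expect_gte(feature_ce_loss_weighted(p, z, cfg), feature_ce_loss(p, z))
  }
})

test_that("training gradient matches central finite differences", {
  set.seed(5)
  coh <- simulate_cohort(tiny_cohort_config(seed = 5))
  keep <- 1:40
  S <- coh$signals[keep, 1:6]
  Z <- coh$Z[keep, 1:6]
  sub <- coh
  sub$signals <- S
  sub$Z <- Z
  # recover the implementation's first gradient step: with plain GD,
  # a_1 = a_0 - lr * g_a, and a_0 = 0, so g = -a_1 / lr
  lr <- 1e-3
  m1 <- train_extractor(
    sub, extractor_config(learning_rate = lr, epochs = 1, weight_decay = 0)
  )
  ga <- unname(-m1$slope / lr)
  gb <- unname(-m1$intercept / lr)

  md <- minority_direction(Z)
  cfg <- extraction_loss_config(4.0, md)
  lossat <- function(a, b) {
    eta <- sweep(sweep(S, 2, a, `*`), 2, b, `+`)
    feature_ce_loss_weighted(stats::plogis(eta), Z, cfg)
  }
  h <- 1e-5
  for (j in seq_len(ncol(Z))) {
    ea <- numeric(ncol(Z)); ea[j] <- h
    num_a <- (lossat(ea, numeric(6)) - lossat(-ea, numeric(6))) / (2 * h)
    num_b <- (lossat(numeric(6), ea) - lossat(numeric(6), -ea)) / (2 * h)
    # the total loss averages over features, the per-feature scorer gradient
    # is N times the derivative of the mean loss
    expect_equal(ga[j], num_a * ncol(Z), tolerance = 1e-5)
    expect_equal(gb[j], num_b * ncol(Z), tolerance = 1e-5)
  }
})

test_that("extractor recovers features on a near-separable cohort", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 6, signal_noise_sd = 0.1))
  sp <- split_nodes(nrow(coh$Z), 0.8, seed = 6)
  model <- train_extractor(coh, extractor_config(), train_mask = sp$train)
  Z_hat <- extract_features(model, coh$signals)
  acc <- colMeans(Z_hat[sp$test, ] == coh$Z[sp$test, ])
  expect_gt(mean(acc), 0.95)
  # Hamming distance below 5% of cells
  expect_lt(mean(Z_hat != coh$Z), 0.05)
})

test_that("larger w_f does not hurt minority-class recall", {
  recall_at <- function(w_f) {
    mean(sapply(1:10, function(s) {
      coh <- simulate_cohort(
        tiny_cohort_config(seed = s, signal_noise_sd = 0.8)
      )
      model <- train_extractor(coh, extractor_config(w_f = w_f, seed = s))
      Z_hat <- extract_features(model, coh$signals)
      # minority-class recall averaged over features
      md <- minority_direction(coh$Z)
      mean(vapply(seq_len(ncol(coh$Z)), function(j) {
        minority_val <- if (md[j] == "presence") 1L else 0L
        rows <- coh$Z[, j] == minority_val
        if (!any(rows)) return(NA_real_)
        mean(Z_hat[rows, j] == minority_val)
      }, numeric(1)), na.rm = TRUE)
    }))
  }
  recalls <- vapply(c(1, 2, 4), recall_at, numeric(1))
  # non-decreasing, allowing one small inversion
  expect_true(sum(diff(recalls) < -0.005) <= 1)
  expect_gt(recalls[3], recalls[1])
})

test_that("degenerate inputs are handled without crashing", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 7))
  # zero-variance signal column with rare presence: majority (absence) wins
  coh$signals[, 1] <- 0
  coh$Z[, 1] <- 0L
  coh$Z[1:3, 1] <- 1L
  model <- train_extractor(coh, extractor_config(seed = 7))
  Z_hat <- extract_features(model, coh$signals)
  expect_true(all(Z_hat[, 1] == 0L))

  # tie at exactly 0.5 predicts presence
  tie <- model
  tie$slope[] <- 0
  tie$intercept[] <- 0
  expect_true(all(extract_features(tie, coh$signals) == 1L))

  # high probabilities give an all-ones row
  hi <- model
  hi$slope[] <- 0
  hi$intercept[] <- stats::qlogis(0.9)
  expect_true(all(extract_features(hi, coh$signals) == 1L))
})

test_that("extractor tidiers expose per-feature scorers", {
  coh <- simulate_cohort(tiny_cohort_config(seed = 8))
  model <- train_extractor(coh, extractor_config(epochs = 20))
  td <- tidy(model)
  expect_equal(nrow(td), 98)
  expect_true(all(c("feature_name", "slope", "intercept", "minority") %in% names(td)))
  gl <- glance(model)
  expect_equal(gl$n_features, 98)
  expect_equal(gl$w_f, 4)
})
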