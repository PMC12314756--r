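# Shared fixtures and independent oracles.

# small cohort + lightweight configs for fast experiment-level tests
tiny_cohort_config <- function(seed = 1, ...) {
  cohort_config(n_subjects = 150L, n_high = 18L, seed = seed, ...)
}

tiny_run_config <- function(seed = 1, n_seeds = 1, ...) {
  run_config(
    cohort = tiny_cohort_config(seed = seed),
    embedding = embedding_config(
      k = 16L, walks_per_node = 3L, walk_length = 20L, window = 3L,
      epochs = 1L
    ),
    train = train_config(epochs = 60L, patience = 60L),
    extractor = extractor_config(epochs = 60L),
    n_seeds = n_seeds, seed = seed, ...
  )
}

# the study-scale harness configuration used by the heavier recovery tests
study_run_config <- function(seed = 1, n_seeds = 2, ...) {
  run_config(n_seeds = n_seeds, seed = seed, ...)
}

# independent metric oracle: direct transcription of the defining formulas,
# computed without the package's report()
oracle_metrics <- function(TP, TN, FP, FN) {
  div <- function(a, b) if (b == 0) 0 else a / b
  precision_0 <- div(TN, TN + FN)
  recall_0 <- div(TN, TN + FP)
  precision_1 <- div(TP, TP + FP)
  recall_1 <- div(TP, TP + FN)
  f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)
  list(
    precision_0 = precision_0, recall_0 = recall_0,
    precision_1 = precision_1, recall_1 = recall_1,
    F1_0 = f1(precision_0, recall_0), F1_1 = f1(precision_1, recall_1),
    macro_F1 = (f1(precision_0, recall_0) + f1(precision_1, recall_1)) / 2,
    G_mean = sqrt(recall_1 * recall_0),
    FPR = div(FP, FP + TN)
  )
}

# brute-force double-loop multi-label cross-entropy (the printed form)
oracle_feature_ce <- function(zhat, z, w1 = rep(1, ncol(z)), w0 = rep(1, ncol(z))) {
  eps <- 1e-12
  N <- ncol(z); M <- nrow(z)
  tot <- 0
  for (i in seq_len(N)) {
    li <- 0
    for (j in seq_len(M)) {
      p <- min(max(zhat[j, i], eps), 1 - eps)
      li <- li + w1[i] * z[j, i] * log(p) + w0[i] * (1 - z[j, i]) * log(1 - p)
    }
    tot <- tot + (-li / M)
  }
  tot / N
}

# brute-force node2vec transition distribution over neighbours of cur
oracle_transition <- function(adj, prev, cur, p, q) {
  nb <- sort(adj[[cur]])
  w <- vapply(nb, function(x) {
    if (is.na(prev)) 1
    else if (x == prev) 1 / p
    else if (x %in% adj[[prev]]) 1
    else 1 / q
  }, numeric(1))
  stats::setNames(w / sum(w), nb)
}

# adjacency list (1-based) of a semantic graph, images first
graph_adj_list <- function(graph) {
  M <- length(graph$image_ids)
  nv <- n_vertices(graph)
  adj <- lapply(seq_len(nv), function(i) integer(0))
  for (k in seq_len(n_edges(graph))) {
    i <- graph$edges[k, 1]
    j <- M + graph$edges[k, 2]
    adj[[i]] <- c(adj[[i]], j)
    adj[[j]] <- c(adj[[j]], i)
  }
  adj
}

# Table of published comparison results used as a regression fixture:
# printed precision_0 / recall_1 / macro-F1 / G-mean / FPR percentages for a
# test set of 19 positives and 142 negatives.
published_rows <- function() {
  tibble::tribble(
    ~model, ~precision_0, ~recall_1, ~macro_F1, ~G_mean, ~FPR,
    "LR", 89.36, 21.05, 54.78, 43.22, 11.27,
    "DT", 89.58, 21.05, 56.22, 43.73, 9.15,
    "SVM", 88.96, 10.53, 53.98, 31.87, 3.52,
    "RF", 88.96, 10.53, 53.98, 31.87, 3.52,
    "AlexNet", 88.17, 42.11, 44.09, 49.31, 42.25,
    "VGG16", 86.89, 57.89, 35.35, 46.49, 62.68,
    "Inception", 86.44, 57.89, 34.46, 45.60, 64.08,
    "ResNet", 85.29, 47.37, 35.65, 43.99, 59.15,
    "GAT", 89.74, 57.89, 42.60, 53.42, 50.70,
    "HAN", 87.95, 47.37, 41.72, 49.35, 48.59,
    "S-HGN", 88.76, 47.37, 44.09, 51.34, 44.37,
    "GCN", 90.59, 57.89, 45.50, 56.03, 45.77,
    "LR*", 89.93, 26.32, 56.68, 48.13, 11.97,
    "DT*", 89.15, 26.32, 52.24, 46.17, 19.01,
    "SVM*", 90.13, 21.05, 60.88, 45.07, 3.52,
    "RF*", 89.03, 10.53, 54.46, 31.98, 2.82,
    "GAT*", 91.09, 52.63, 50.52, 58.39, 35.21,
    "HAN*", 90.72, 52.63, 48.87, 57.11, 38.03,
    "S-HGN*", 90.00, 42.11, 50.71, 54.18, 30.28,
    "GCN*", 92.68, 52.63, 60.56, 65.00, 19.72
  )
}
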