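# Experiment protocols: model comparison, feature-class ablation,
# hyperparameter sensitivity (w_c, w_f, layer count) and stability under
# training-set shrinkage and edge dropout. Every experiment runs n_seeds
# independent replicates (fresh cohort, split, embedding and fit per seed)
# and reports seed-averaged metrics in the shared nine-metric schema.

.METRIC_COLS <- c(
  "precision_0", "recall_0", "precision_1", "recall_1",
  "F1_0", "F1_1", "macro_F1", "G_mean", "FPR"
)

#' Experiment run configuration
#'
#' Bundles the sub-configurations of the full pipeline. The embedding
#' defaults here are lighter than [embedding_config()]'s reference settings
#' (64 dimensions, 5 walks of length 40, window 5, 3 epochs): the experiment
#' battery refits the whole pipeline dozens of times, and at the 806-drawing
#' scale these settings preserve the structural signal while keeping a full
#' battery within minutes.
#'
#' @param cohort A [cohort_config()].
#' @param embedding An [embedding_config()].
#' @param train A [train_config()].
#' @param extractor An [extractor_config()].
#' @param train_fraction Image-vertex training fraction (default 0.8).
#' @param self_loops Adjacency convention, see [adjacency()].
#' @param hidden_dims GCN layer widths (default `c(64, 64)`).
#' @param flip_01,flip_10 Bit-flip rates used to produce the corrupted
#'   feature source in [run_comparison()] (defaults 0.02 and 0.10).
#' @param n_seeds Replicates per condition (default 5).
#' @param seed Base seed; replicate r uses `seed + 7919 * (r - 1)`.
#' @return A list of class `run_config`.
#' @export
run_config <- function(cohort = cohort_config(),
                       embedding = embedding_config(
                         k = 64L, walks_per_node = 5L, walk_length = 40L,
                         window = 5L, epochs = 3L
                       ),
                       train = train_config(),
                       extractor = extractor_config(),
                       train_fraction = 0.8,
                       self_loops = FALSE,
                       hidden_dims = c(64L, 64L),
                       flip_01 = 0.02, flip_10 = 0.10,
                       n_seeds = 5L, seed = 1L) {
  structure(
    list(
      cohort = cohort, embedding = embedding, train = train,
      extractor = extractor, train_fraction = train_fraction,
      self_loops = self_loops, hidden_dims = hidden_dims,
      flip_01 = flip_01, flip_10 = flip_10,
      n_seeds = as.integer(n_seeds), seed = as.integer(seed)
    ),
    class = "run_config"
  )
}

# per-replicate derived seed, kept well below 2^31
.rep_seed <- function(cfg, r) as.integer(cfg$seed + 7919L * (r - 1L))

# cheap deterministic fingerprint of a binary matrix (for config echoes)
.z_fingerprint <- function(Z) {
  v <- c(dim(Z), sum(Z), sum(colSums(Z) * seq_len(ncol(Z))) %% 1e9,
         sum(rowSums(Z) * seq_len(nrow(Z))) %% 1e9)
  paste(v, collapse = "-")
}

# simulate cohort + split for replicate r
.rep_inputs <- function(cfg, r) {
  s <- .rep_seed(cfg, r)
  ccfg <- cfg$cohort
  ccfg$seed <- s
  cohort <- simulate_cohort(ccfg)
  split <- split_nodes(cfg$cohort$n_subjects, cfg$train_fraction, seed = s)
  list(cohort = cohort, split = split, seed = s)
}

# embed + train + evaluate one graph; returns the one-row test report
.fit_eval_gcn <- function(graph, train_mask, test_mask, cfg, seed,
                          emb = NULL, w_c = NULL, hidden_dims = NULL) {
  ecfg <- cfg$embedding
  ecfg$seed <- seed
  if (is.null(emb)) emb <- embed_graph(graph, ecfg)
  tcfg <- cfg$train
  tcfg$seed <- seed
  if (!is.null(w_c)) tcfg$w_c <- w_c
  hd <- if (is.null(hidden_dims)) cfg$hidden_dims else hidden_dims
  fit <- train_detector(graph, emb, train_mask, tcfg,
    self_loops = cfg$self_loops, hidden_dims = hd
  )
  evaluate_detector(fit, test_mask)
}

.aggregate_rows <- function(rows, key_cols) {
  rows |>
    dplyr::group_by(dplyr::across(dplyr::all_of(key_cols))) |>
    dplyr::summarise(
      dplyr::across(dplyr::all_of(.METRIC_COLS), mean),
      macro_F1_sd = stats::sd(.data$macro_F1),
      G_mean_sd = stats::sd(.data$G_mean),
      n_seeds = dplyr::n(),
      .groups = "drop"
    )
}

.as_experiment <- function(tbl, name, cfg, fingerprints) {
  attr(tbl, "experiment") <- name
  attr(tbl, "config_echo") <- cfg
  attr(tbl, "cohort_fingerprint") <- fingerprints
  class(tbl) <- c("tdt_experiment", class(tbl))
  tbl
}

#' Model comparison on true versus corrupted feature codes
#'
#' Evaluates the GCN and the four ML baselines on the same seeded cohorts
#' and splits, once on the true binary codes and once on codes degraded by
#' random bit flips (the automatic-extraction analogue).
#'
#' @param cfg A [run_config()].
#' @return A `tdt_experiment` tibble: one row per model x feature source
#'   with seed-averaged metrics.
#' @export
run_comparison <- function(cfg = run_config()) {
  rows <- list()
  fps <- character(0)
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    sources <- list(
      true = inp$cohort$Z,
      corrupted = corrupt_features(
        inp$cohort$Z, cfg$flip_01, cfg$flip_10, seed = inp$seed
      )
    )
    for (src in names(sources)) {
      Z <- sources[[src]]
      y <- inp$cohort$labels
      graph <- build_semantic_graph(Z, y)
      rep_gcn <- .fit_eval_gcn(
        graph, inp$split$train, inp$split$test, cfg, inp$seed
      )
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(model = "GCN", feature_source = src, rep = r), rep_gcn
      )
      for (bl in c("LR", "DT", "SVM", "RF")) {
        spec <- baseline_spec(bl, cost_sensitive = TRUE, seed = inp$seed)
        fit <- fit_baseline(
          spec, Z[inp$split$train, , drop = FALSE], y[inp$split$train]
        )
        pred <- predict_baseline(fit, Z[inp$split$test, , drop = FALSE])
        rows[[length(rows) + 1]] <- dplyr::bind_cols(
          tibble::tibble(model = bl, feature_source = src, rep = r),
          evaluate_predictions(y[inp$split$test], pred)
        )
      }
    }
  }
  out <- .aggregate_rows(dplyr::bind_rows(rows), c("model", "feature_source"))
  out <- out |>
    dplyr::arrange(
      factor(.data$model, c("GCN", "LR", "DT", "SVM", "RF")),
      dplyr::desc(.data$feature_source)
    )
  .as_experiment(out, "comparison", cfg, fps)
}

#' Feature-class ablation
#'
#' Retrains the full pipeline after removing each of the 12 feature classes
#' in turn (plus a "none" row retaining all features).
#'
#' @param cfg A [run_config()].
#' @param catalog Feature catalog (default [build_feature_catalog()]).
#' @return A `tdt_experiment` tibble with 13 rows keyed by `removed_class`.
#' @export
run_ablation <- function(cfg = run_config(),
                         catalog = build_feature_catalog()) {
  arms <- c("none", catalog_classes(catalog))
  rows <- list()
  fps <- character(0)
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    full <- build_semantic_graph(inp$cohort$Z, inp$cohort$labels)
    for (arm in arms) {
      graph <- if (arm == "none") full else remove_feature_class(full, catalog, arm)
      res <- .fit_eval_gcn(graph, inp$split$train, inp$split$test, cfg, inp$seed)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(removed_class = arm, rep = r), res
      )
    }
  }
  out <- .aggregate_rows(dplyr::bind_rows(rows), "removed_class")
  out <- dplyr::arrange(out, factor(.data$removed_class, arms))
  .as_experiment(out, "ablation", cfg, fps)
}

#' Sensitivity to the detection class weight w_c
#'
#' Sweeps `w_c` over 1..16 (step 1) with the cohort, split and embedding
#' held fixed within each replicate.
#'
#' @param cfg A [run_config()].
#' @param grid Integer grid of weights (default `1:16`).
#' @return A `tdt_experiment` tibble keyed by `w_c`.
#' @export
run_sensitivity_wc <- function(cfg = run_config(), grid = 1:16) {
  rows <- list()
  fps <- character(0)
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    graph <- build_semantic_graph(inp$cohort$Z, inp$cohort$labels)
    ecfg <- cfg$embedding
    ecfg$seed <- inp$seed
    emb <- embed_graph(graph, ecfg)
    for (w in grid) {
      res <- .fit_eval_gcn(
        graph, inp$split$train, inp$split$test, cfg, inp$seed,
        emb = emb, w_c = w
      )
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(w_c = w, rep = r), res
      )
    }
  }
  out <- .aggregate_rows(dplyr::bind_rows(rows), "w_c")
  .as_experiment(out, "sensitivity_wc", cfg, fps)
}

#' Sensitivity to the extractor minority weight w_f
#'
#' For each weight in the grid, retrains the surrogate extractor on the
#' training rows, re-extracts the feature codes for all drawings, rebuilds
#' the semantic graph from the predictions and retrains the detector.
#'
#' @param cfg A [run_config()].
#' @param grid Weights (default `c(1, 2, 4, 8, 16)`).
#' @return A `tdt_experiment` tibble keyed by `w_f`.
#' @export
run_sensitivity_wf <- function(cfg = run_config(), grid = c(1, 2, 4, 8, 16)) {
  rows <- list()
  fps <- character(0)
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    for (w in grid) {
      xcfg <- cfg$extractor
      xcfg$w_f <- w
      xcfg$seed <- inp$seed
      model <- train_extractor(inp$cohort, xcfg, train_mask = inp$split$train)
      Z_hat <- extract_features(model, inp$cohort$signals)
      graph <- build_semantic_graph(Z_hat, inp$cohort$labels)
      res <- .fit_eval_gcn(graph, inp$split$train, inp$split$test, cfg, inp$seed)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(w_f = w, rep = r), res
      )
    }
  }
  out <- .aggregate_rows(dplyr::bind_rows(rows), "w_f")
  .as_experiment(out, "sensitivity_wf", cfg, fps)
}

#' Sensitivity to GCN depth
#'
#' Sweeps the layer count (default 1..4, each layer 64-dimensional) with
#' cohort, split and embedding fixed within a replicate.
#'
#' @param cfg A [run_config()].
#' @param layers Integer vector of depths (default `1:4`).
#' @return A `tdt_experiment` tibble keyed by `layers`.
#' @export
run_layer_sweep <- function(cfg = run_config(), layers = 1:4) {
  rows <- list()
  fps <- character(0)
  width <- cfg$hidden_dims[1]
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    graph <- build_semantic_graph(inp$cohort$Z, inp$cohort$labels)
    ecfg <- cfg$embedding
    ecfg$seed <- inp$seed
    emb <- embed_graph(graph, ecfg)
    for (L in layers) {
      res <- .fit_eval_gcn(
        graph, inp$split$train, inp$split$test, cfg, inp$seed,
        emb = emb, hidden_dims = rep(width, L)
      )
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(layers = L, rep = r), res
      )
    }
  }
  out <- .aggregate_rows(dplyr::bind_rows(rows), "layers")
  .as_experiment(out, "layer_sweep", cfg, fps)
}

#' Stability under training-set shrinkage
#'
#' Keeps the test vertices fixed and retains 100%..50% of the training
#' vertices (floor rule); removed training drawings are excluded from the
#' graph entirely, so the graph is rebuilt per condition.
#'
#' @param cfg A [run_config()].
#' @param fractions Retained training fractions
#'   (default `c(1, 0.9, 0.8, 0.7, 0.6, 0.5)`).
#' @param keep_in_graph If `TRUE`, removed training vertices stay in the
#'   graph (pure label removal) instead of being dropped (default `FALSE`).
#' @return A `tdt_experiment` tibble keyed by `train_fraction_kept` with a
#'   `n_train` column of realized training sizes.
#' @export
run_stability_train_size <- function(cfg = run_config(),
                                     fractions = c(1, 0.9, 0.8, 0.7, 0.6, 0.5),
                                     keep_in_graph = FALSE) {
  rows <- list()
  fps <- character(0)
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    for (f in fractions) {
      tmask <- if (f == 1) inp$split$train else {
        subset_training(inp$split$train, f, seed = inp$seed)
      }
      if (keep_in_graph) {
        graph <- build_semantic_graph(inp$cohort$Z, inp$cohort$labels)
        res <- .fit_eval_gcn(graph, tmask, inp$split$test, cfg, inp$seed)
      } else {
        keep_rows <- tmask | inp$split$test
        Z <- inp$cohort$Z[keep_rows, , drop = FALSE]
        y <- inp$cohort$labels[keep_rows]
        graph <- build_semantic_graph(Z, y)
        res <- .fit_eval_gcn(
          graph, tmask[keep_rows], inp$split$test[keep_rows], cfg, inp$seed
        )
      }
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(train_fraction_kept = f, n_train = sum(tmask), rep = r),
        res
      )
    }
  }
  out <- .aggregate_rows(
    dplyr::bind_rows(rows), c("train_fraction_kept", "n_train")
  )
  out <- dplyr::arrange(out, dplyr::desc(.data$train_fraction_kept))
  .as_experiment(out, "stability_train_size", cfg, fps)
}

#' Stability under edge dropout
#'
#' Randomly retains 100%..50% of the image-feature edges and retrains the
#' pipeline on each perturbed graph.
#'
#' @param cfg A [run_config()].
#' @param keep_fractions Retained edge fractions
#'   (default `c(1, 0.9, 0.8, 0.7, 0.6, 0.5)`).
#' @return A `tdt_experiment` tibble keyed by `keep_fraction`.
#' @export
run_stability_edges <- function(cfg = run_config(),
                                keep_fractions = c(1, 0.9, 0.8, 0.7, 0.6, 0.5)) {
  rows <- list()
  fps <- character(0)
  for (r in seq_len(cfg$n_seeds)) {
    inp <- .rep_inputs(cfg, r)
    fps[r] <- .z_fingerprint(inp$cohort$Z)
    full <- build_semantic_graph(inp$cohort$Z, inp$cohort$labels)
    for (f in keep_fractions) {
      graph <- drop_edges(full, f, seed = inp$seed)
      res <- .fit_eval_gcn(graph, inp$split$train, inp$split$test, cfg, inp$seed)
      rows[[length(rows) + 1]] <- dplyr::bind_cols(
        tibble::tibble(keep_fraction = f, rep = r), res
      )
    }
  }
  out <- .aggregate_rows(dplyr::bind_rows(rows), "keep_fraction")
  out <- dplyr::arrange(out, dplyr::desc(.data$keep_fraction))
  .as_experiment(out, "stability_edges", cfg, fps)
}

#' Write an experiment table with its config echo
#'
#' Writes `<name>.csv` (the report), `<name>_config.txt` (all resolved
#' configuration values) and the per-replicate cohort fingerprints, so a
#' rerun with the same config can be checked for bit-identity.
#'
#' @param tbl A `tdt_experiment`.
#' @param dir Output directory (created if needed).
#' @return The report CSV path, invisibly.
#' @export
write_experiment <- function(tbl, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  name <- attr(tbl, "experiment") %||% "experiment"
  csv <- file.path(dir, paste0(name, ".csv"))
  readr::write_csv(tibble::as_tibble(tbl), csv)
  cfg <- attr(tbl, "config_echo")
  echo <- utils::capture.output(utils::str(cfg, give.attr = FALSE))
  writeLines(
    c(echo, "", paste0("cohort_fingerprint: ",
                       paste(attr(tbl, "cohort_fingerprint"), collapse = " "))),
    file.path(dir, paste0(name, "_config.txt"))
  )
  invisible(csv)
}
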