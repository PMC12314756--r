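# broom-style accessors for fitted objects.

#' Tidy a fitted GCN detector
#'
#' One row per image vertex with its predicted probability, hard label,
#' true label (where known) and split membership.
#'
#' @param x A `tdt_gcn`.
#' @param ... Unused.
#' @return A tibble with columns `image_id`, `p_high`, `hard_label`,
#'   `label`, `set` (`"train"`/`"test"`).
#' @export
tidy.tdt_gcn <- function(x, ...) {
  pred <- predict(x)
  pred$label <- x$graph$labels
  pred$set <- ifelse(x$train_mask, "train", "test")
  pred
}

#' Summarize a fitted GCN detector
#'
#' @param x A `tdt_gcn`.
#' @param ... Unused.
#' @return A one-row tibble: graph size, depth, class weight, epochs run
#'   and best training loss.
#' @export
glance.tdt_gcn <- function(x, ...) {
  tibble::tibble(
    n_vertices = n_vertices(x$graph),
    n_edges = n_edges(x$graph),
    layers = x$params$L,
    w_c = x$config$w_c,
    epochs_run = x$epochs_run,
    best_epoch = x$best_epoch,
    train_loss = min(x$loss_trace)
  )
}

#' Tidy a trained surrogate extractor
#'
#' @param x A `tdt_extractor`.
#' @param ... Unused.
#' @return One row per feature: `feature_name`, `slope`, `intercept`,
#'   `minority`.
#' @export
tidy.tdt_extractor <- function(x, ...) {
  tibble::tibble(
    feature_name = x$feature_names %||% sprintf("feat_%03d", seq_along(x$slope)),
    slope = x$slope,
    intercept = x$intercept,
    minority = x$minority
  )
}

#' Summarize a trained surrogate extractor
#'
#' @param x A `tdt_extractor`.
#' @param ... Unused.
#' @return One-row tibble: feature count, `w_f`, epochs and final loss.
#' @export
glance.tdt_extractor <- function(x, ...) {
  tibble::tibble(
    n_features = length(x$slope),
    w_f = x$config$w_f,
    epochs = x$config$epochs,
    final_loss = x$loss_trace[length(x$loss_trace)]
  )
}
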