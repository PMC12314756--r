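# Cost-sensitive two-layer GCN node classifier.
#
# Forward model: H^(0) = X, H^(l+1) = relu(A_hat H^(l) W^(l)) for L layers
# (no bias inside the convolutions), then a 2-logit softmax head
# y = softmax(W H^(L) + b) on every vertex. Training minimizes a weighted
# binary cross-entropy over the labelled training image vertices only, with
# the weight w_c multiplying the positive-class log term alone (an
# asymmetric weighting: negatives always weigh 1). All vertices, including
# test images and feature vertices, participate in message passing.

#' GCN parameters
#'
#' Weight matrices are initialized symmetric-uniform scaled by fan-in
#' (`U(-s, s)`, `s = 1/sqrt(d_in)`), seeded.
#'
#' @param input_dim Dimension of the input embeddings (d_0).
#' @param hidden_dims Integer vector of per-layer output dimensions; its
#'   length is the number of GCN layers L (default `c(64, 64)`, a two-layer
#'   model).
#' @param activation Activation name; `"relu"` (default) or `"identity"`.
#' @param seed Integer seed for the initialization.
#' @return A list of class `gcn_params` with `conv_weights` (list of L
#'   matrices), `head_weight` (2 x d_L), `head_bias` (length 2),
#'   `activation`, `L`.
#' @export
gcn_params <- function(input_dim, hidden_dims = c(64L, 64L),
                       activation = "relu", seed = 1L) {
  stopifnot(length(hidden_dims) >= 1, all(hidden_dims >= 1),
            activation %in% c("relu", "identity"))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(seed)
  dims <- c(input_dim, hidden_dims)
  L <- length(hidden_dims)
  conv <- vector("list", L)
  for (l in seq_len(L)) {
    s <- 1 / sqrt(dims[l])
    conv[[l]] <- matrix(stats::runif(dims[l] * dims[l + 1], -s, s), dims[l])
  }
  s <- 1 / sqrt(dims[L + 1])
  structure(
    list(
      conv_weights = conv,
      head_weight = matrix(stats::runif(2 * dims[L + 1], -s, s), 2),
      head_bias = numeric(2),
      activation = activation, L = L
    ),
    class = "gcn_params"
  )
}

.act <- function(x, activation) if (activation == "relu") pmax(x, 0) else x

# forward pass keeping intermediates for backprop
.gcn_forward_full <- function(X, A_hat, params) {
  H <- X
  pre <- vector("list", params$L)  # pre-activation A_l
  agg <- vector("list", params$L)  # Z_l = A_hat %*% H_{l-1}
  hs <- vector("list", params$L + 1)
  hs[[1]] <- H
  for (l in seq_len(params$L)) {
    agg[[l]] <- as.matrix(A_hat %*% H)
    pre[[l]] <- agg[[l]] %*% params$conv_weights[[l]]
    H <- .act(pre[[l]], params$activation)
    hs[[l + 1]] <- H
  }
  list(H_L = H, pre = pre, agg = agg, hs = hs)
}

#' GCN forward pass
#'
#' @param X Input representation matrix (|V| x d_0), e.g. `$X` of
#'   [embed_graph()].
#' @param A_hat Normalized adjacency from [adjacency()] (the `A_hat` field).
#' @param params A [gcn_params()].
#' @return The last-layer representation H^(L) (|V| x d_L).
#' @export
gcn_forward <- function(X, A_hat, params) {
  if (ncol(X) != nrow(params$conv_weights[[1]])) stop("dimension mismatch")
  .gcn_forward_full(X, A_hat, params)$H_L
}

.softmax2 <- function(logits) {
  m <- pmax(logits[, 1], logits[, 2])
  e0 <- exp(logits[, 1] - m)
  e1 <- exp(logits[, 2] - m)
  cbind(e0 / (e0 + e1), e1 / (e0 + e1))
}

#' Classify vertices from last-layer representations
#'
#' Applies the 2-logit softmax head. The hard label is the argmax with ties
#' broken towards class 0 (a vertex needs strictly more than half the
#' probability mass to be flagged).
#'
#' @param H_L Last-layer representations (|V| x d_L).
#' @param params A [gcn_params()].
#' @return A tibble with columns `vertex`, `p_high` (probability of class
#'   1) and `hard_label`.
#' @export
classify_nodes <- function(H_L, params) {
  logits <- H_L %*% t(params$head_weight)
  logits <- sweep(logits, 2, params$head_bias, `+`)
  if (any(!is.finite(logits))) stop("non-finite logits")
  p <- .softmax2(logits)
  tibble::tibble(
    vertex = seq_len(nrow(p)),
    p_high = p[, 2],
    hard_label = as.integer(p[, 2] > 0.5)
  )
}

#' Cost-sensitive detection loss
#'
#' Weighted binary cross-entropy over the training vertices:
#' `-(1/T) sum(w_c y log(yhat) + (1 - y) log(1 - yhat))`. Only the positive
#' log term is weighted; `w_c = 1` recovers the plain cross-entropy.
#'
#' @param yhat Predicted probabilities of class 1 over training vertices.
#' @param y Binary labels.
#' @param w_c Positive-class weight (>= 1).
#' @return Nonnegative scalar.
#' @export
detection_loss <- function(yhat, y, w_c = 7.0) {
  if (length(yhat) == 0) stop("empty training set")
  p <- .clip01(yhat)
  -mean(w_c * y * log(p) + (1 - y) * log(1 - p))
}

#' Detector training configuration
#'
#' @param learning_rate Adam step size (default 0.01).
#' @param weight_decay Decoupled L2 decay on weight matrices (default
#'   0.001; biases are not decayed).
#' @param w_c Positive-class weight in the loss (default 7.0).
#' @param epochs Maximum training epochs (default 600; at the default
#'   learning rate the loss is still falling well past 200 epochs on
#'   cohort-scale graphs).
#' @param patience Early-stopping patience on the training loss (default
#'   50); the best-loss parameters are restored.
#' @param seed Integer seed (parameter initialization).
#' @return A list of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.01, weight_decay = 0.001,
                         w_c = 7.0, epochs = 600L, patience = 50L,
                         seed = 1L) {
  stopifnot(learning_rate > 0, weight_decay >= 0, w_c >= 1, epochs >= 1)
  structure(
    list(
      learning_rate = learning_rate, weight_decay = weight_decay,
      w_c = w_c, epochs = as.integer(epochs),
      patience = as.integer(patience), seed = as.integer(seed)
    ),
    class = "train_config"
  )
}

# analytic gradients of the detection loss through the GCN, given the
# forward intermediates and the softmax probabilities p (|V| x 2)
.gcn_gradients <- function(params, fwd, p, train_rows, y, w_c) {
  T_n <- length(train_rows)
  dlogits <- matrix(0, nrow(p), 2)
  w <- ifelse(y == 1, w_c, 1)
  onehot <- cbind(1 - y, y)
  dlogits[train_rows, ] <- (w / T_n) * (p[train_rows, , drop = FALSE] - onehot)
  g_head_w <- t(dlogits) %*% fwd$H_L
  g_head_b <- colSums(dlogits)
  dH <- dlogits %*% params$head_weight
  g_conv <- vector("list", params$L)
  for (l in rev(seq_len(params$L))) {
    dA <- if (params$activation == "relu") dH * (fwd$pre[[l]] > 0) else dH
    g_conv[[l]] <- t(fwd$agg[[l]]) %*% dA
    if (l > 1) dH <- as.matrix(fwd$A_hat_t %*% (dA %*% t(params$conv_weights[[l]])))
  }
  list(conv = g_conv, head_w = g_head_w, head_b = g_head_b)
}

#' Train the GCN detector
#'
#' Minimizes [detection_loss()] over the training image vertices by Adam
#' with decoupled L2 weight decay, early stopping on the training loss.
#' Message passing uses the whole graph; the loss touches only training
#' image vertices (feature vertices carry no labels and are excluded from
#' loss and evaluation).
#'
#' @param graph A `semantic_graph` with labels on (at least) the training
#'   image vertices.
#' @param X Input representations: a `node_embeddings` or a |V| x d matrix.
#' @param train_mask Logical mask over image vertices.
#' @param cfg A [train_config()].
#' @param params Optional initial [gcn_params()]; defaults to a fresh
#'   two-layer initialization seeded from `cfg$seed`.
#' @param self_loops Adjacency convention flag, see [adjacency()].
#' @param hidden_dims Passed to [gcn_params()] when `params` is `NULL`.
#' @return A list of class `tdt_gcn`: `params`, `loss_trace`, `config`,
#'   `graph`, `X`, `A_hat`, `train_mask`, `epochs_run`.
#' @export
train_detector <- function(graph, X, train_mask, cfg = train_config(),
                           params = NULL, self_loops = FALSE,
                           hidden_dims = c(64L, 64L)) {
  if (inherits(X, "node_embeddings")) X <- X$X
  M <- length(graph$image_ids)
  stopifnot(length(train_mask) == M, nrow(X) == n_vertices(graph))
  train_rows <- which(train_mask)
  y <- graph$labels[train_rows]
  if (anyNA(y)) stop("training vertices must be labelled")
  if (is.null(params)) {
    params <- gcn_params(ncol(X), hidden_dims = hidden_dims, seed = cfg$seed)
  }
  adj <- adjacency(graph, self_loops = self_loops)
  A_hat <- adj$A_hat

  shapes <- c(params$conv_weights, list(params$head_weight, params$head_bias))
  m_t <- lapply(shapes, function(x) x * 0)
  v_t <- lapply(shapes, function(x) x * 0)
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  lr <- cfg$learning_rate; wd <- cfg$weight_decay

  best <- list(loss = Inf, params = params, epoch = 0L)
  trace <- numeric(cfg$epochs)
  step <- 0L
  for (ep in seq_len(cfg$epochs)) {
    fwd <- .gcn_forward_full(X, A_hat, params)
    fwd$A_hat_t <- A_hat # symmetric
    cls <- fwd$H_L %*% t(params$head_weight)
    cls <- sweep(cls, 2, params$head_bias, `+`)
    p <- .softmax2(cls)
    trace[ep] <- detection_loss(p[train_rows, 2], y, cfg$w_c)
    if (!is.finite(trace[ep])) {
      stop("detector training diverged (non-finite loss at epoch ", ep, ")")
    }
    if (trace[ep] < best$loss - 1e-12) {
      best <- list(loss = trace[ep], params = params, epoch = ep)
    } else if (ep - best$epoch >= cfg$patience) {
      trace <- trace[seq_len(ep)]
      break
    }
    g <- .gcn_gradients(params, fwd, p, train_rows, y, cfg$w_c)
    grads <- c(g$conv, list(g$head_w, g$head_b))
    step <- step + 1L
    upd <- vector("list", length(grads))
    for (i in seq_along(grads)) {
      m_t[[i]] <- b1 * m_t[[i]] + (1 - b1) * grads[[i]]
      v_t[[i]] <- b2 * v_t[[i]] + (1 - b2) * grads[[i]]^2
      mhat <- m_t[[i]] / (1 - b1^step)
      vhat <- v_t[[i]] / (1 - b2^step)
      upd[[i]] <- lr * mhat / (sqrt(vhat) + eps)
    }
    L <- params$L
    for (l in seq_len(L)) {
      params$conv_weights[[l]] <- params$conv_weights[[l]] * (1 - lr * wd) - upd[[l]]
    }
    params$head_weight <- params$head_weight * (1 - lr * wd) - upd[[L + 1]]
    params$head_bias <- params$head_bias - upd[[L + 2]] # bias: no decay
  }
  structure(
    list(
      params = best$params, loss_trace = trace, config = cfg,
      graph = graph, X = X, A_hat = A_hat, train_mask = train_mask,
      epochs_run = length(trace), best_epoch = best$epoch,
      self_loops = self_loops
    ),
    class = "tdt_gcn"
  )
}

#' @export
print.tdt_gcn <- function(x, ...) {
  cat(sprintf(
    "<tdt_gcn> %d-layer GCN, w_c=%.1f, %d epochs (best %d), train loss %.4f\n",
    x$params$L, x$config$w_c, x$epochs_run, x$best_epoch,
    min(x$loss_trace)
  ))
  invisible(x)
}

#' Predict ideation probabilities for image vertices
#'
#' @param object A fitted `tdt_gcn`.
#' @param ... Unused.
#' @return A tibble over image vertices: `image_id`, `p_high`,
#'   `hard_label`.
#' @export
predict.tdt_gcn <- function(object, ...) {
  H_L <- gcn_forward(object$X, object$A_hat, object$params)
  cls <- classify_nodes(H_L, object$params)
  M <- length(object$graph$image_ids)
  tibble::tibble(
    image_id = object$graph$image_ids,
    p_high = cls$p_high[seq_len(M)],
    hard_label = cls$hard_label[seq_len(M)]
  )
}

#' Evaluate a fitted detector on a set of image vertices
#'
#' @param fit A `tdt_gcn`.
#' @param mask Logical mask over image vertices (e.g. the test mask).
#' @return One-row metric tibble as in [report()].
#' @export
evaluate_detector <- function(fit, mask) {
  pred <- predict(fit)
  y <- fit$graph$labels[mask]
  if (anyNA(y)) stop("evaluation vertices must be labelled")
  evaluate_predictions(y, pred$hard_label[mask])
}

#' Export per-vertex predictions as CSV
#'
#' @param fit A `tdt_gcn`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_predictions <- function(fit, path) {
  readr::write_csv(predict(fit), path)
  invisible(path)
}
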