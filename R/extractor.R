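# Surrogate automatic feature extraction.
#
# One independent logistic scorer per catalog feature, trained on the
# cohort's latent signals with the cost-sensitive multi-label cross-entropy:
# the per-feature loss is mean binary cross-entropy with an extra weight w_f
# on the minority-class term of that feature (presence term when presence is
# the minority coding, absence term otherwise), and the total loss is the
# mean over the 98 features. Any scorer producing per-feature probabilities
# could be substituted; the losses are the fixed part of the contract.

.EPS <- 1e-12

.clip01 <- function(p) pmin(pmax(p, .EPS), 1 - .EPS)

#' Cost-sensitive extraction loss configuration
#'
#' @param w_f Weight (>= 1) applied to the minority-class term of each
#'   feature (default 4.0).
#' @param minority_direction Optional character vector over features,
#'   `"presence"`/`"absence"`; normally derived from the training split via
#'   [minority_direction()].
#' @return A list of class `extraction_loss_config`.
#' @export
extraction_loss_config <- function(w_f = 4.0, minority_direction = NULL) {
  stopifnot(w_f >= 1)
  structure(
    list(w_f = w_f, minority_direction = minority_direction),
    class = "extraction_loss_config"
  )
}

#' Minority coding direction per feature
#'
#' A feature's minority class is presence when its training prevalence is
#' at most 1/2 and absence otherwise. Computed on training rows only.
#'
#' @param Z Binary matrix (training rows x features).
#' @return Character vector (`"presence"`/`"absence"`), one per feature.
#' @export
minority_direction <- function(Z) {
  ifelse(colMeans(Z) <= 0.5, "presence", "absence")
}

#' Multi-label cross-entropy loss
#'
#' Mean over features of the per-feature mean binary cross-entropy between
#' predicted presence probabilities and binary codes.
#'
#' @param zhat Probability matrix (M x N), clipped internally to
#'   (1e-12, 1 - 1e-12).
#' @param z Binary matrix of the same shape.
#' @return Nonnegative scalar.
#' @export
feature_ce_loss <- function(zhat, z) {
  if (!all(dim(zhat) == dim(z))) stop("shape mismatch")
  p <- .clip01(zhat)
  -mean(colMeans(z * log(p) + (1 - z) * log(1 - p)))
}

#' Cost-sensitive multi-label cross-entropy loss
#'
#' As [feature_ce_loss()] but with the configured `w_f` multiplying the
#' minority-class term of each feature: the `z log(zhat)` term where
#' presence is the minority coding, the `(1 - z) log(1 - zhat)` term where
#' absence is. With `w_f = 1` it reduces exactly to the unweighted loss.
#'
#' @inheritParams feature_ce_loss
#' @param cfg An [extraction_loss_config()] whose `minority_direction` has
#'   length N.
#' @return Nonnegative scalar.
#' @export
feature_ce_loss_weighted <- function(zhat, z, cfg) {
  if (!all(dim(zhat) == dim(z))) stop("shape mismatch")
  md <- cfg$minority_direction
  if (is.null(md)) md <- minority_direction(z)
  stopifnot(length(md) == ncol(z))
  p <- .clip01(zhat)
  w1 <- ifelse(md == "presence", cfg$w_f, 1) # weight on the presence term
  w0 <- ifelse(md == "absence", cfg$w_f, 1)  # weight on the absence term
  terms <- sweep(z * log(p), 2, w1, `*`) + sweep((1 - z) * log(1 - p), 2, w0, `*`)
  -mean(colMeans(terms))
}

#' Extractor training configuration
#'
#' @param learning_rate Gradient-descent step size (default 0.5; the
#'   per-feature scorers are tiny, so large steps are stable).
#' @param epochs Full-batch gradient steps (default 300).
#' @param weight_decay L2 penalty on the slope (default 1e-6).
#' @param w_f Minority-class weight for the training loss (default 4.0).
#' @param seed Integer seed.
#' @return A list of class `extractor_config`.
#' @export
extractor_config <- function(learning_rate = 0.5, epochs = 300L,
                             weight_decay = 1e-6, w_f = 4.0, seed = 1L) {
  stopifnot(learning_rate > 0, epochs >= 1, weight_decay >= 0, w_f >= 1)
  structure(
    list(
      learning_rate = learning_rate, epochs = as.integer(epochs),
      weight_decay = weight_decay, w_f = w_f, seed = as.integer(seed)
    ),
    class = "extractor_config"
  )
}

#' Train the surrogate feature extractor
#'
#' Fits one logistic scorer per feature (slope and intercept on that
#' feature's latent signal) by full-batch gradient descent on the
#' cost-sensitive multi-label cross-entropy. Minority directions are
#' computed on the training rows only.
#'
#' @param cohort A `tdt_cohort` (uses `signals` as inputs and `Z` as
#'   targets).
#' @param cfg An [extractor_config()].
#' @param train_mask Optional logical mask over drawings; defaults to all.
#' @return A list of class `tdt_extractor` with `slope`, `intercept`
#'   (length-N vectors), `minority`, `loss_trace`, `config`.
#' @export
train_extractor <- function(cohort, cfg = extractor_config(),
                            train_mask = NULL) {
  S <- cohort$signals
  Z <- cohort$Z
  if (is.null(train_mask)) train_mask <- rep(TRUE, nrow(Z))
  S <- S[train_mask, , drop = FALSE]
  Z <- Z[train_mask, , drop = FALSE]
  M <- nrow(Z)
  N <- ncol(Z)
  md <- minority_direction(Z)
  w1 <- ifelse(md == "presence", cfg$w_f, 1)
  w0 <- ifelse(md == "absence", cfg$w_f, 1)

  a <- numeric(N) # slope per feature
  b <- numeric(N) # intercept per feature
  trace <- numeric(cfg$epochs)
  lcfg <- extraction_loss_config(cfg$w_f, md)
  for (ep in seq_len(cfg$epochs)) {
    eta <- sweep(S, 2, a, `*`)
    eta <- sweep(eta, 2, b, `+`)
    p <- .clip01(stats::plogis(eta))
    trace[ep] <- feature_ce_loss_weighted(p, Z, lcfg)
    if (!is.finite(trace[ep])) {
      stop("non-finite extractor loss at epoch ", ep, "; lower the learning rate")
    }
    # d(loss)/d(logit) for the one-sided weighted cross-entropy
    g <- sweep((1 - Z) * p, 2, w0, `*`) - sweep(Z * (1 - p), 2, w1, `*`)
    ga <- colMeans(g * S) + cfg$weight_decay * a
    gb <- colMeans(g)
    a <- a - cfg$learning_rate * ga
    b <- b - cfg$learning_rate * gb
  }
  structure(
    list(
      slope = a, intercept = b, minority = md,
      loss_trace = trace, config = cfg,
      feature_names = colnames(cohort$Z)
    ),
    class = "tdt_extractor"
  )
}

#' Per-feature presence probabilities from a trained extractor
#'
#' @param model A `tdt_extractor`.
#' @param signals Latent signal matrix (M x N).
#' @return Probability matrix (M x N).
#' @export
extractor_probs <- function(model, signals) {
  stopifnot(inherits(model, "tdt_extractor"))
  if (ncol(signals) != length(model$slope)) stop("dimension mismatch")
  eta <- sweep(signals, 2, model$slope, `*`)
  eta <- sweep(eta, 2, model$intercept, `+`)
  stats::plogis(eta)
}

#' Predict binary feature codes
#'
#' Thresholds the per-feature probabilities at 0.5, ties broken towards
#' presence (probability exactly 0.5 predicts 1).
#'
#' @inheritParams extractor_probs
#' @return Binary integer matrix (M x N) with the signal matrix's dimnames.
#' @export
extract_features <- function(model, signals) {
  p <- extractor_probs(model, signals)
  out <- matrix(as.integer(p >= 0.5), nrow = nrow(p))
  dimnames(out) <- dimnames(signals)
  out
}
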