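# Classic ML comparators on the 98-dimensional feature vectors: logistic
# regression, decision tree, SVM and random forest, as thin wrappers over
# the standard implementations, with optional cost-sensitive class weights.

#' Baseline model specification
#'
#' @param name One of `"LR"`, `"DT"`, `"SVM"`, `"RF"`.
#' @param cost_sensitive Logical: weight the positive class by
#'   `weight_scale` times the inverse prevalence ratio `n0/n1` of the
#'   training labels (default `FALSE`).
#' @param weight_scale Multiplier on the inverse-prevalence weight
#'   (default 1).
#' @param seed Integer seed.
#' @return A list of class `baseline_spec`.
#' @export
baseline_spec <- function(name, cost_sensitive = FALSE, weight_scale = 1,
                          seed = 1L) {
  if (!name %in% c("LR", "DT", "SVM", "RF")) {
    stop("unknown baseline: ", name, " (expected LR, DT, SVM or RF)")
  }
  structure(
    list(
      name = name, cost_sensitive = isTRUE(cost_sensitive),
      weight_scale = weight_scale, seed = as.integer(seed)
    ),
    class = "baseline_spec"
  )
}

#' Fit a baseline classifier
#'
#' @param spec A [baseline_spec()].
#' @param Z_train Binary feature matrix of training drawings.
#' @param y_train Binary labels.
#' @return A list of class `tdt_baseline` wrapping the fitted model.
#' @export
fit_baseline <- function(spec, Z_train, y_train) {
  stopifnot(inherits(spec, "baseline_spec"), nrow(Z_train) == length(y_train))
  if (length(unique(y_train)) < 2) {
    stop("single-class training labels: cannot fit ", spec$name)
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(spec$seed)
  df <- as.data.frame(Z_train)
  colnames(df) <- sprintf("f%03d", seq_len(ncol(Z_train)))
  w1 <- if (spec$cost_sensitive) {
    spec$weight_scale * sum(y_train == 0) / sum(y_train == 1)
  } else {
    1
  }
  case_w <- ifelse(y_train == 1, w1, 1)
  fit <- switch(spec$name,
    LR = suppressWarnings(stats::glm(
      y ~ ., data = cbind(df, y = y_train),
      family = stats::binomial(), weights = case_w
    )),
    DT = rpart::rpart(
      y ~ ., data = cbind(df, y = factor(y_train)),
      weights = case_w, method = "class"
    ),
    SVM = e1071::svm(
      x = as.matrix(df), y = factor(y_train),
      class.weights = c("0" = 1, "1" = w1), kernel = "radial"
    ),
    RF = randomForest::randomForest(
      x = df, y = factor(y_train),
      classwt = c("0" = 1, "1" = w1)
    )
  )
  structure(
    list(spec = spec, fit = fit, n_features = ncol(Z_train)),
    class = "tdt_baseline"
  )
}

#' Predict binary labels from a fitted baseline
#'
#' Hard labels by each model's 0.5 rule (probability threshold for LR/DT,
#' decision function sign for SVM, majority vote for RF).
#'
#' @param model A `tdt_baseline`.
#' @param Z_test Binary feature matrix.
#' @return Integer 0/1 predictions, one per row of `Z_test`.
#' @export
predict_baseline <- function(model, Z_test) {
  stopifnot(inherits(model, "tdt_baseline"))
  if (ncol(Z_test) != model$n_features) stop("dimension mismatch")
  df <- as.data.frame(Z_test)
  colnames(df) <- sprintf("f%03d", seq_len(ncol(Z_test)))
  out <- switch(model$spec$name,
    LR = as.integer(stats::predict(model$fit, df, type = "response") > 0.5),
    DT = as.integer(stats::predict(model$fit, df, type = "class") == "1"),
    SVM = as.integer(stats::predict(model$fit, as.matrix(df)) == "1"),
    RF = as.integer(stats::predict(model$fit, df) == "1")
  )
  unname(out)
}
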