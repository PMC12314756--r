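# Synthetic TDT cohort generation.
#
# The generator emulates the statistical structure of the screening study the
# package is designed around: 806 drawings coded on 98 binary features, Beck
# scale scores (0-90) with mean 17.19 and SD 7.01, and 94 subjects above the
# mean-plus-SD cut-off. Per-feature prevalence is class-dependent and
# calibrated so a drawing carries ~19 features on average (hence ~15.4k
# image-feature edges over 806 x 98).

# Default per-class marginal prevalence of feature presence. Weighted by the
# Table-of-features class sizes these give ~19.6 expected features per image.
.default_base_prevalence <- c(
  "overall" = 0.15, "line" = 0.20, "special mark" = 0.10,
  "special tree type" = 0.12, "canopy" = 0.22, "branch" = 0.20,
  "leaf and flower" = 0.35, "trunk" = 0.20, "junction" = 0.18,
  "root" = 0.15, "ground" = 0.25, "attachment" = 0.25
)

#' Configuration for the synthetic cohort generator
#'
#' Defaults reproduce the study conditions the package targets: 806 subjects
#' of whom 94 are in the high-ideation group (a 7.57:1 imbalance), scale
#' scores with mean 17.19 and SD 7.01 on the 0-90 scale, and 98 binary
#' drawing features with class-dependent prevalence. A group-level signal is
#' planted, by default in the "leaf and flower" feature class, as a shift of
#' `effect_size` on the log-odds of feature presence for high-ideation
#' subjects; every other feature receives a small random log-odds
#' perturbation (`jitter_sd`) so that no feature class is perfectly inert.
#'
#' @param n_subjects Number of drawings (default 806).
#' @param n_high Number of high-ideation subjects (default 94).
#' @param score_mean,score_sd Target mean and SD of scale scores in points
#'   (defaults 17.19 and 7.01).
#' @param base_prevalence Named vector of per-class feature prevalences in
#'   (0,1), one entry per catalog class.
#' @param effect_size Log-odds shift of feature presence for high-ideation
#'   subjects, applied to features in `signal_classes` (default 2.0).
#' @param signal_classes Character vector of catalog classes carrying the
#'   planted signal (default `"leaf and flower"`).
#' @param jitter_sd SD of the per-feature Gaussian log-odds perturbation
#'   applied to the high-ideation group across all features (default 0.35),
#'   so that every feature class carries some group signal and removing any
#'   class degrades detection slightly.
#' @param signal_noise_sd SD of the Gaussian noise added to the binary codes
#'   to form the latent evidence consumed by the surrogate extractor
#'   (default 0.3; must be > 0).
#' @param seed Integer seed; the cohort is bit-reproducible given the config.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(n_subjects = 806L, n_high = 94L,
                          score_mean = 17.19, score_sd = 7.01,
                          base_prevalence = .default_base_prevalence,
                          effect_size = 2.0,
                          signal_classes = "leaf and flower",
                          jitter_sd = 0.35,
                          signal_noise_sd = 0.3,
                          seed = 1L) {
  stopifnot(
    n_subjects >= 2, n_high >= 1, n_high < n_subjects,
    score_sd > 0, all(base_prevalence > 0), all(base_prevalence < 1),
    jitter_sd >= 0, signal_noise_sd > 0
  )
  structure(
    list(
      n_subjects = as.integer(n_subjects), n_high = as.integer(n_high),
      score_mean = score_mean, score_sd = score_sd,
      base_prevalence = base_prevalence, effect_size = effect_size,
      signal_classes = signal_classes, jitter_sd = jitter_sd,
      signal_noise_sd = signal_noise_sd, seed = as.integer(seed)
    ),
    class = "cohort_config"
  )
}

# scores from a normal truncated to [0, 90] by rejection
.rtruncnorm_scores <- function(n, mean, sd, lo = 0, hi = 90) {
  out <- numeric(0)
  while (length(out) < n) {
    x <- stats::rnorm(n, mean, sd)
    out <- c(out, x[x >= lo & x <= hi])
  }
  out[seq_len(n)]
}

#' Simulate a synthetic tree-drawing cohort
#'
#' Draws a seeded cohort under a [cohort_config()]: binary feature codes `Z`
#' (subjects x features, feature-wise Bernoulli with class-dependent
#' prevalence shifted on the log-odds scale for the high-ideation group on
#' signal-class features), scale scores from a truncated normal on \[0, 90\],
#' binary labels with exactly `n_high` positives, and latent `signals`
#' (`Z` plus Gaussian noise) standing in for the raster drawings consumed by
#' the surrogate feature extractor. Scores and labels are made mutually
#' consistent by rank assignment: the `n_high` largest scores go to the
#' label-1 subjects, so the mean-plus-SD threshold rule and the configured
#' group sizes agree by construction.
#'
#' @param config A [cohort_config()].
#' @param catalog Feature catalog tibble (default [build_feature_catalog()]).
#' @return A list of class `tdt_cohort` with elements `Z` (M x N binary
#'   matrix, dimnames `img_0001`... x feature names), `scores`, `labels`,
#'   `signals`, `catalog`, `config`, `seed`.
#' @examples
#' coh <- simulate_cohort(cohort_config(seed = 7))
#' sum(coh$labels)   # 94
#' dim(coh$Z)        # 806 x 98
#' @export
simulate_cohort <- function(config = cohort_config(),
                            catalog = build_feature_catalog()) {
  stopifnot(inherits(config, "cohort_config"))
  missing_cls <- setdiff(catalog$class_name, names(config$base_prevalence))
  if (length(missing_cls) > 0) {
    stop("base_prevalence missing classes: ", paste(missing_cls, collapse = ", "))
  }
  if (!all(config$signal_classes %in% catalog$class_name)) {
    stop("signal_classes must be catalog classes")
  }
  M <- config$n_subjects
  N <- nrow(catalog)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(config$seed)

  labels <- integer(M)
  labels[sample.int(M, config$n_high)] <- 1L

  scores <- .rtruncnorm_scores(M, config$score_mean, config$score_sd)
  ord <- order(scores, decreasing = TRUE)
  top <- ord[seq_len(config$n_high)]
  rest <- ord[-seq_len(config$n_high)]
  out_scores <- numeric(M)
  out_scores[labels == 1L] <- scores[sample(top)]
  out_scores[labels == 0L] <- scores[sample(rest)]

  p0 <- config$base_prevalence[catalog$class_name] # length N
  delta <- stats::rnorm(N, 0, config$jitter_sd)
  delta[catalog$class_name %in% config$signal_classes] <-
    delta[catalog$class_name %in% config$signal_classes] + config$effect_size
  logit0 <- stats::qlogis(p0)
  p_mat <- matrix(rep(p0, each = M), nrow = M) # low-group prevalence
  p_hi <- stats::plogis(matrix(rep(logit0 + delta, each = M), nrow = M))
  hi <- labels == 1L
  p_mat[hi, ] <- p_hi[hi, ]
  Z <- matrix(as.integer(stats::runif(M * N) < p_mat), nrow = M)
  dimnames(Z) <- list(sprintf("img_%04d", seq_len(M)), catalog$feature_name)

  signals <- Z + matrix(stats::rnorm(M * N, 0, config$signal_noise_sd), nrow = M)
  dimnames(signals) <- dimnames(Z)

  structure(
    list(
      Z = Z, scores = out_scores, labels = labels, signals = signals,
      catalog = catalog, config = config, seed = config$seed
    ),
    class = "tdt_cohort"
  )
}

#' @export
print.tdt_cohort <- function(x, ...) {
  cat(sprintf(
    "<tdt_cohort> %d drawings x %d features, %d high / %d low ideation (seed %d)\n",
    nrow(x$Z), ncol(x$Z), sum(x$labels == 1L), sum(x$labels == 0L), x$seed
  ))
  invisible(x)
}

#' Binarize scale scores at mean plus SD
#'
#' Applies the screening cut-off used to define the high-ideation group:
#' a subject is labelled 1 when its score is at or above the sample mean plus
#' one sample standard deviation (denominator M-1). The boundary is inclusive
#' by default; set `inclusive = FALSE` for a strict cut.
#'
#' @param scores Numeric vector of scale scores (length >= 2).
#' @param inclusive Logical; label 1 when `score >= threshold` (default) or
#'   strictly above.
#' @return Integer 0/1 vector. Emits a warning when the scores are constant
#'   (SD 0, a degenerate threshold).
#' @examples
#' threshold_labels(c(10, 20, 30)) # threshold 30 -> 0 0 1
#' @export
threshold_labels <- function(scores, inclusive = TRUE) {
  if (length(scores) < 2) stop("need at least 2 scores to compute an SD")
  s <- stats::sd(scores)
  if (s == 0) {
    warning("constant scores: SD is 0, threshold degenerates to the mean")
  }
  thr <- mean(scores) + s
  if (inclusive) as.integer(scores >= thr) else as.integer(scores > thr)
}

#' Randomly corrupt a binary feature matrix
#'
#' Simulates imperfect automatic feature extraction by independent bit flips:
#' each 0 becomes 1 with probability `flip_01` and each 1 becomes 0 with
#' probability `flip_10`.
#'
#' @param Z Binary matrix.
#' @param flip_01,flip_10 Flip probabilities in \[0, 1\].
#' @param seed Integer seed.
#' @return Binary matrix of the same shape and dimnames.
#' @export
corrupt_features <- function(Z, flip_01, flip_10, seed = 1L) {
  stopifnot(
    is.matrix(Z), all(Z %in% c(0L, 1L)),
    flip_01 >= 0, flip_01 <= 1, flip_10 >= 0, flip_10 <= 1
  )
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(.seed_stream(seed, 4000003))
  u <- matrix(stats::runif(length(Z)), nrow = nrow(Z))
  out <- Z
  out[Z == 0L & u < flip_01] <- 1L
  out[Z == 1L & u < flip_10] <- 0L
  storage.mode(out) <- "integer"
  dimnames(out) <- dimnames(Z)
  out
}

#' Convert a cohort to a tibble, or write/read it as CSV
#'
#' The tabular form has one row per drawing with an `image_id` column, one
#' 0/1 column per catalog feature, plus `score` and `label`.
#'
#' @param cohort A `tdt_cohort`.
#' @param path File path for the CSV form.
#' @return `cohort_table()` a tibble; `write_cohort()` `path`, invisibly;
#'   `read_cohort()` a list with `Z`, `scores`, `labels`.
#' @export
cohort_table <- function(cohort) {
  tibble::as_tibble(as.data.frame(cohort$Z), .name_repair = "minimal") |>
    tibble::add_column(image_id = rownames(cohort$Z), .before = 1) |>
    tibble::add_column(score = cohort$scores, label = cohort$labels)
}

#' @rdname cohort_table
#' @export
write_cohort <- function(cohort, path) {
  readr::write_csv(cohort_table(cohort), path)
  invisible(path)
}

#' @rdname cohort_table
#' @export
read_cohort <- function(path) {
  tab <- readr::read_csv(path, col_types = readr::cols(), progress = FALSE)
  feat_cols <- setdiff(names(tab), c("image_id", "score", "label"))
  Z <- as.matrix(tab[feat_cols])
  storage.mode(Z) <- "integer"
  rownames(Z) <- tab$image_id
  list(Z = Z, scores = tab$score, labels = as.integer(tab$label))
}
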