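# Feature catalog: the 98 coded tree-drawing characteristics in 12 classes.

.tdt_catalog_classes <- list(
  "overall" = c(
    "huge tree", "small tree", "tree above", "tree below", "tree on the left",
    "tree on the right", "tilted trunk or crown",
    "cut at the edge of the tree and paper", "cut above", "cut on the left",
    "cut on the right", "cut below"
  ),
  "line" = c(
    "thick lines", "light lines", "obvious differences in strength",
    "sloppy lines", "mainly short lines", "mainly long lines",
    "mainly trembling wavy lines"
  ),
  "special mark" = c("snakelike", "symmetrical"),
  "special tree type" = c(
    "dead tree", "simplified tree", "pine tree", "theme loss", "multiple trees"
  ),
  "canopy" = c(
    "closed canopy", "open canopy", "zoned canopy", "large canopy",
    "small canopy", "squashed canopy", "full canopy",
    "emphasized canopy lines", "light canopy lines",
    "multi-layered canopy lines", "cloud-like canopy lines",
    "ringed canopy line", "quivering shaped canopy lines",
    "circular canopy lines", "black shadows in the canopy",
    "chaos in the canopy", "blank canopy", "detailed depicted canopy",
    "short wavy lines drawn in the canopy"
  ),
  "branch" = c(
    "broken branches", "crossing branches", "vigorously growing branches",
    "drooping branches", "patchwork branches", "single-line branches",
    "parallel branches", "open branch ends", "sharp branch ends"
  ),
  "leaf and flower" = c("fruits or flowers in the canopy", "leaves", "fallen leaves"),
  "trunk" = c(
    "small trunk", "long trunk", "parallel trunk",
    "wide at the top and narrow at the bottom",
    "wide at the bottom of the trunk", "scars on the trunk",
    "black shadow on the trunk", "depiction of bark",
    "completely blank trunk", "emphasis on trunk edge lines",
    "light trunk edge lines", "trunk with small twigs"
  ),
  "junction" = c(
    "trunk sealed at the top", "trunk open at the top",
    "trunk forms a 'M' shape at the top", "trunk sealed at the bottom",
    "trunk transitionally sealed at the bottom (drawing whisker-like roots)",
    "trunk open at the bottom",
    "trunk directly connects to the branches and the junction is hollow"
  ),
  "root" = c(
    "drawn roots", "fibrous roots", "sharp roots", "crossing roots",
    "overly drawn roots", "exposed roots"
  ),
  "ground" = c(
    "drawn ground line", "sloping ground line", "wavy ground line",
    "hilly ground line", "emphasized ground",
    "paper's base as ground line (only if depicted flowers and plants)",
    "ground line through the trunk"
  ),
  "attachment" = c(
    "drawn attachments", "sun", "clouds", "flowers under the tree",
    "grass under the tree", "birds or bird's nests", "houses or people",
    "words", "wind and rain"
  )
)

#' Catalog of tree-drawing test features
#'
#' Returns the standard coding scheme used throughout the package: 98 named
#' binary tree-drawing features partitioned into 12 classes (overall form,
#' line quality, canopy, branch, trunk, roots, attachments, ...). Drawings
#' are coded 1 when a feature is present and 0 otherwise; the catalog fixes
#' both the feature order (columns of every feature matrix) and the class
#' membership used by the ablation experiments.
#'
#' @return A tibble with one row per feature and columns `feature_name` and
#'   `class_name`, in catalog order. The 12 class names, in order, are stored
#'   in the `"classes"` attribute.
#' @examples
#' cat98 <- build_feature_catalog()
#' nrow(cat98)                        # 98
#' dplyr::count(cat98, class_name)    # per-class feature counts
#' @export
build_feature_catalog <- function() {
  out <- tibble::tibble(
    feature_name = unlist(.tdt_catalog_classes, use.names = FALSE),
    class_name = rep(names(.tdt_catalog_classes),
      vapply(.tdt_catalog_classes, length, integer(1))
    )
  )
  attr(out, "classes") <- names(.tdt_catalog_classes)
  out
}

#' Class names of the feature catalog
#'
#' @param catalog A catalog tibble from [build_feature_catalog()].
#' @return Character vector of the 12 class names in catalog order.
#' @export
catalog_classes <- function(catalog = build_feature_catalog()) {
  cls <- attr(catalog, "classes")
  if (is.null(cls)) cls <- unique(catalog$class_name)
  cls
}

#' Write or read a feature catalog as CSV
#'
#' Two-column CSV (`feature_name`, `class_name`), one row per feature.
#'
#' @param catalog A catalog tibble.
#' @param path File path.
#' @return `write_catalog()` returns `path` invisibly; `read_catalog()`
#'   returns a catalog tibble.
#' @export
write_catalog <- function(catalog, path) {
  readr::write_csv(catalog[c("feature_name", "class_name")], path)
  invisible(path)
}

#' @rdname write_catalog
#' @export
read_catalog <- function(path) {
  out <- readr::read_csv(path,
    col_types = readr::cols(
      feature_name = readr::col_character(),
      class_name = readr::col_character()
    )
  )
  out <- tibble::as_tibble(out)
  attr(out, "classes") <- unique(out$class_name)
  out
}

# Internal: decorrelated seed streams. Different stochastic operations applied
# at the same user-level seed must not share an RNG prefix (e.g. the cohort's
# label placement and the train/test split both start from sample.int(M, .)),
# so each operation offsets the seed by its own constant.
.seed_stream <- function(seed, offset) {
  as.integer((as.numeric(seed) + offset) %% 2147483647)
}
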