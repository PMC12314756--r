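# Bipartite image-feature semantic graph.
#
# Vertices are the drawings (V_I) followed by the catalog features (V_F);
# an edge joins image i and feature j exactly when drawing i was coded 1 on
# feature j, so |E| equals the popcount of the coding matrix. The vertex
# order (images first, then features) is fixed and shared by the adjacency,
# the embeddings and the GCN.

#' Build the image-feature semantic graph from a binary coding matrix
#'
#' @param Z Binary M x N matrix (drawings x features). Dimnames, when
#'   present, become the vertex identifiers.
#' @param labels Optional 0/1 vector over drawings; `NA` marks unlabeled
#'   image vertices. Feature vertices are always unlabeled.
#' @return A list of class `semantic_graph` with `image_ids`, `feature_ids`,
#'   `edges` (two-column integer matrix of image/feature indices), `labels`.
#'   Isolated vertices are retained.
#' @examples
#' g <- build_semantic_graph(diag(2))
#' n_vertices(g) # 4
#' n_edges(g)    # 2
#' @export
build_semantic_graph <- function(Z, labels = NULL) {
  stopifnot(is.matrix(Z))
  if (!all(Z %in% c(0, 1))) stop("Z must be binary")
  M <- nrow(Z)
  N <- ncol(Z)
  if (!is.null(labels)) {
    stopifnot(length(labels) == M, all(labels %in% c(0, 1, NA)))
  } else {
    labels <- rep(NA_integer_, M)
  }
  idx <- which(Z == 1, arr.ind = TRUE)
  edges <- cbind(image = as.integer(idx[, 1]), feature = as.integer(idx[, 2]))
  edges <- edges[order(edges[, 1], edges[, 2]), , drop = FALSE]
  image_ids <- rownames(Z)
  if (is.null(image_ids)) image_ids <- sprintf("img_%04d", seq_len(M))
  feature_ids <- colnames(Z)
  if (is.null(feature_ids)) feature_ids <- sprintf("feat_%03d", seq_len(N))
  structure(
    list(
      image_ids = image_ids, feature_ids = feature_ids,
      edges = edges, labels = as.integer(labels)
    ),
    class = "semantic_graph"
  )
}

#' @export
print.semantic_graph <- function(x, ...) {
  cat(sprintf(
    "<semantic_graph> %d image + %d feature vertices, %d edges (density %.4f)\n",
    length(x$image_ids), length(x$feature_ids), nrow(x$edges),
    graph_density(x)
  ))
  invisible(x)
}

#' Vertex and edge counts
#' @param graph A `semantic_graph`.
#' @return Integer count.
#' @export
n_vertices <- function(graph) length(graph$image_ids) + length(graph$feature_ids)

#' @rdname n_vertices
#' @export
n_edges <- function(graph) nrow(graph$edges)

#' Adjacency and symmetrically normalized adjacency
#'
#' Builds the |V| x |V| binary adjacency `A` of the semantic graph (images
#' first, then features) and its normalization
#' `A_hat = D^(-1/2) A D^(-1/2)` with `D` the degree diagonal. Degree-0
#' vertices get a zero row/column rather than a division error. With
#' `self_loops = TRUE` the identity is added to `A` before normalization
#' (the renormalization-trick variant); the default follows the plain
#' formula.
#'
#' @param graph A `semantic_graph`.
#' @param self_loops Logical flag (default `FALSE`).
#' @return A list of class `adjacency_pair` with sparse matrices `A`,
#'   `A_hat` (from the Matrix package) and the `self_loops` flag.
#' @export
adjacency <- function(graph, self_loops = FALSE) {
  M <- length(graph$image_ids)
  nv <- n_vertices(graph)
  i <- graph$edges[, 1]
  j <- M + graph$edges[, 2]
  A <- Matrix::sparseMatrix(
    i = c(i, j), j = c(j, i), x = 1, dims = c(nv, nv)
  )
  if (self_loops) A <- A + Matrix::Diagonal(nv)
  d <- Matrix::rowSums(A)
  dinv <- ifelse(d > 0, 1 / sqrt(d), 0)
  Dinv <- Matrix::Diagonal(nv, dinv)
  A_hat <- Dinv %*% A %*% Dinv
  structure(
    list(A = A, A_hat = A_hat, self_loops = self_loops),
    class = "adjacency_pair"
  )
}

#' Undirected edge density of the semantic graph
#'
#' `|E| / (|V| (|V|-1) / 2)`, the simple undirected-graph convention.
#'
#' @param graph A `semantic_graph` with at least 2 vertices.
#' @return Density in \[0, 1\].
#' @export
graph_density <- function(graph) {
  nv <- n_vertices(graph)
  if (nv < 2) stop("density needs at least 2 vertices")
  n_edges(graph) / (nv * (nv - 1) / 2)
}

#' Randomly retain a fraction of edges
#'
#' Simulates missing image-feature links (features the extractor failed to
#' recover): keeps `round(keep_fraction * |E|)` edges sampled uniformly
#' without replacement. Vertices are unchanged.
#'
#' @param graph A `semantic_graph`.
#' @param keep_fraction Fraction of edges to keep, in (0, 1].
#' @param seed Integer seed.
#' @return A `semantic_graph`.
#' @export
drop_edges <- function(graph, keep_fraction, seed = 1L) {
  stopifnot(keep_fraction > 0, keep_fraction <= 1)
  m <- n_edges(graph)
  keep <- as.integer(round(keep_fraction * m))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(.seed_stream(seed, 3000003))
  sel <- sort(sample.int(m, keep))
  out <- graph
  out$edges <- graph$edges[sel, , drop = FALSE]
  out
}

#' Remove one feature class from the graph
#'
#' Ablation operation: deletes all feature vertices belonging to
#' `class_name` (per the catalog) together with their incident edges; image
#' vertices are untouched and remaining features are re-indexed in catalog
#' order.
#'
#' @param graph A `semantic_graph` whose feature vertices are catalog
#'   features.
#' @param catalog Feature catalog tibble.
#' @param class_name One of the catalog's class names.
#' @return A `semantic_graph`.
#' @export
remove_feature_class <- function(graph, catalog, class_name) {
  if (!class_name %in% catalog$class_name) {
    stop("unknown feature class: ", class_name)
  }
  drop_feats <- catalog$feature_name[catalog$class_name == class_name]
  keep <- !(graph$feature_ids %in% drop_feats)
  new_index <- cumsum(keep)
  keep_edge <- keep[graph$edges[, 2]]
  out <- graph
  out$feature_ids <- graph$feature_ids[keep]
  edges <- graph$edges[keep_edge, , drop = FALSE]
  edges[, 2] <- new_index[edges[, 2]]
  out$edges <- edges
  out
}

#' Train/test split of image vertices
#'
#' Uniform (unstratified) split: `round(train_fraction * n_images)` drawings
#' form the training set, the rest the test set.
#'
#' @param n_images Number of image vertices.
#' @param train_fraction Fraction in (0, 1) (default 0.8).
#' @param seed Integer seed.
#' @return A list with logical masks `train` and `test` over image vertices.
#' @examples
#' s <- split_nodes(806, 0.8, seed = 1)
#' sum(s$train) # 645
#' sum(s$test)  # 161
#' @export
split_nodes <- function(n_images, train_fraction = 0.8, seed = 1L) {
  stopifnot(train_fraction > 0, train_fraction < 1)
  n_train <- as.integer(round(train_fraction * n_images))
  if (n_train == 0 || n_train == n_images) {
    stop("degenerate split: train set would be empty or exhaustive")
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(.seed_stream(seed, 1000003))
  train <- logical(n_images)
  train[sample.int(n_images, n_train)] <- TRUE
  list(train = train, test = !train)
}

#' Randomly keep a fraction of the training mask
#'
#' Training-size stability protocol: retains `floor(fraction * n_train)`
#' training vertices uniformly at random (the floor rule matches the
#' printed subset sizes 580/516/451/387/322 out of 645). Test vertices are
#' untouched.
#'
#' @param train_mask Logical mask over image vertices.
#' @param fraction Fraction in (0, 1].
#' @param seed Integer seed.
#' @return Reduced logical mask.
#' @export
subset_training <- function(train_mask, fraction, seed = 1L) {
  stopifnot(fraction > 0, fraction <= 1)
  idx <- which(train_mask)
  n_keep <- as.integer(floor(fraction * length(idx)))
  if (n_keep == 0) stop("subset would be empty")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()), add = TRUE)
  set.seed(.seed_stream(seed, 2000003))
  keep <- sample(idx, n_keep)
  out <- logical(length(train_mask))
  out[keep] <- TRUE
  out
}

#' Serialize a semantic graph to plain text
#'
#' Writes a TSV edge list (`image_id`, `feature_id`) and a vertex table CSV
#' (`vertex_id`, `type`, `label`); `read_graph()` round-trips them.
#'
#' @param graph A `semantic_graph`.
#' @param edge_path Path of the TSV edge list.
#' @param vertex_path Path of the vertex CSV.
#' @return `write_graph()`: `edge_path` invisibly. `read_graph()`: a
#'   `semantic_graph`.
#' @export
write_graph <- function(graph, edge_path, vertex_path) {
  edges <- tibble::tibble(
    image_id = graph$image_ids[graph$edges[, 1]],
    feature_id = graph$feature_ids[graph$edges[, 2]]
  )
  readr::write_tsv(edges, edge_path)
  vertices <- tibble::tibble(
    vertex_id = c(graph$image_ids, graph$feature_ids),
    type = c(
      rep("image", length(graph$image_ids)),
      rep("feature", length(graph$feature_ids))
    ),
    label = c(graph$labels, rep(NA_integer_, length(graph$feature_ids)))
  )
  readr::write_csv(vertices, vertex_path)
  invisible(edge_path)
}

#' @rdname write_graph
#' @export
read_graph <- function(edge_path, vertex_path) {
  edges <- readr::read_tsv(edge_path, col_types = "cc", progress = FALSE)
  vertices <- readr::read_csv(vertex_path, col_types = "cci", progress = FALSE)
  image_ids <- vertices$vertex_id[vertices$type == "image"]
  feature_ids <- vertices$vertex_id[vertices$type == "feature"]
  structure(
    list(
      image_ids = image_ids, feature_ids = feature_ids,
      edges = cbind(
        image = match(edges$image_id, image_ids),
        feature = match(edges$feature_id, feature_ids)
      ),
      labels = vertices$label[vertices$type == "image"]
    ),
    class = "semantic_graph"
  )
}
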