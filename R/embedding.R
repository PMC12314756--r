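# Initial node representations: biased random walks + skip-gram.
#
# Walks are second-order ("node2vec") with return parameter p and in-out
# parameter q; the skip-gram is trained with negative sampling over the walk
# corpus. Both run in compiled code, single-threaded, seeded.

#' Embedding configuration
#'
#' Defaults follow the common node2vec reference settings; `p = q = 1`
#' (unbiased walks) since no walk tuning is assumed.
#'
#' @param k Embedding dimension (default 128).
#' @param p Return parameter (> 0, default 1).
#' @param q In-out parameter (> 0, default 1).
#' @param walks_per_node Walks started from each vertex (default 10).
#' @param walk_length Maximum walk length in vertices (default 80).
#' @param window Skip-gram context window (default 10).
#' @param negative_samples Negative samples per positive pair (default 5).
#' @param epochs Passes over the walk corpus (default 5).
#' @param alpha Initial skip-gram learning rate (default 0.025).
#' @param seed Integer seed.
#' @return A list of class `embedding_config`.
#' @export
embedding_config <- function(k = 128L, p = 1.0, q = 1.0,
                             walks_per_node = 10L, walk_length = 80L,
                             window = 10L, negative_samples = 5L,
                             epochs = 5L, alpha = 0.025, seed = 1L) {
  stopifnot(k >= 2, p > 0, q > 0, walks_per_node >= 1, walk_length >= 1,
            window >= 1, negative_samples >= 1, epochs >= 1, alpha > 0)
  structure(
    list(
      k = as.integer(k), p = p, q = q,
      walks_per_node = as.integer(walks_per_node),
      walk_length = as.integer(walk_length),
      window = as.integer(window),
      negative_samples = as.integer(negative_samples),
      epochs = as.integer(epochs), alpha = alpha, seed = as.integer(seed)
    ),
    class = "embedding_config"
  )
}

# 0-based adjacency list over the combined vertex set (images then features)
.adj_list <- function(graph) {
  M <- length(graph$image_ids)
  nv <- n_vertices(graph)
  i <- graph$edges[, 1]
  j <- M + graph$edges[, 2]
  adj <- vector("list", nv)
  nb <- split(c(j, i) - 1L, c(i, j))
  adj[as.integer(names(nb))] <- lapply(nb, as.integer)
  adj[vapply(adj, is.null, logical(1))] <- list(integer(0))
  adj
}

#' Generate biased random walks over the semantic graph
#'
#' Starts `walks_per_node` walks at every vertex; a walk terminates early at
#' a vertex with no neighbours, so an isolated vertex yields a length-1 walk.
#' Transitions after the first step are second-order biased: returning to the
#' previous vertex is weighted `1/p`, moving to a common neighbour of the
#' previous vertex `1`, and moving farther away `1/q` (on a bipartite graph
#' the middle case cannot occur).
#'
#' @param graph A `semantic_graph`.
#' @param cfg An [embedding_config()].
#' @return List of integer vertex-index sequences (1-based, images first
#'   then features).
#' @export
random_walks <- function(graph, cfg = embedding_config()) {
  adj <- .adj_list(graph)
  cpp_biased_walks(
    adj, cfg$p, cfg$q, cfg$walks_per_node, cfg$walk_length, cfg$seed
  )
}

#' Second-order transition probabilities (reference helper)
#'
#' Probability distribution over the neighbours of `cur` for a walk that
#' arrived from `prev` (`prev = NA` for the first step). Exposed mainly so
#' the walk bias can be inspected and checked against direct enumeration.
#'
#' @param graph A `semantic_graph`.
#' @param prev,cur Vertex indices (1-based, images first); `prev = NA` means
#'   no history.
#' @inheritParams random_walks
#' @return Named numeric vector of probabilities over the neighbours of
#'   `cur` (in sorted vertex order).
#' @export
transition_probs <- function(graph, prev, cur, cfg = embedding_config()) {
  adj <- .adj_list(graph)
  pr <- if (is.na(prev)) -1L else as.integer(prev) - 1L
  p <- cpp_transition_probs(adj, pr, as.integer(cur) - 1L, cfg$p, cfg$q)
  names(p) <- sort(adj[[cur]]) + 1L
  p
}

#' Train skip-gram embeddings on a walk corpus
#'
#' Skip-gram with negative sampling (unigram^0.75 noise distribution,
#' reduced context windows, linearly decaying learning rate). Vertices that
#' never co-occur with another vertex (isolated, walks of length 1) receive
#' zero vectors.
#'
#' @param walks List of integer vertex sequences from [random_walks()].
#' @param cfg An [embedding_config()].
#' @param n_vertices Total vertex count of the graph the walks came from.
#' @return A `node_embeddings` list with `X` (|V| x k matrix) and `config`.
#' @export
skipgram_embed <- function(walks, cfg, n_vertices) {
  if (length(walks) == 0) stop("empty walk corpus")
  X <- cpp_skipgram(
    walks, as.integer(n_vertices), cfg$k, cfg$window,
    cfg$negative_samples, cfg$epochs, cfg$alpha, cfg$seed
  )
  structure(list(X = X, config = cfg), class = "node_embeddings")
}

#' Walks + skip-gram in one call
#'
#' @inheritParams random_walks
#' @return A `node_embeddings` object whose rows align with the graph's
#'   vertex order (images first, then features).
#' @export
embed_graph <- function(graph, cfg = embedding_config()) {
  emb <- skipgram_embed(random_walks(graph, cfg), cfg, n_vertices(graph))
  rownames(emb$X) <- c(graph$image_ids, graph$feature_ids)
  emb
}

#' Write embeddings as CSV
#'
#' One row per vertex: `vertex_id` followed by the k coordinate columns.
#'
#' @param emb A `node_embeddings`.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_embeddings <- function(emb, path) {
  X <- emb$X
  tab <- tibble::as_tibble(as.data.frame(X), .name_repair = ~ sprintf("dim_%03d", seq_along(.x)))
  tab <- tibble::add_column(tab,
    vertex_id = rownames(X) %||% as.character(seq_len(nrow(X))),
    .before = 1
  )
  readr::write_csv(tab, path)
  invisible(path)
}
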