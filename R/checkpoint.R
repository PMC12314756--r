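# Text checkpoint for GCN parameters: a small versioned header followed by
# one flattened, dput-style numeric block per matrix. Plain text so
# checkpoints survive source-only distribution.

#' Save or load GCN parameters as a text checkpoint
#'
#' @param params A [gcn_params()].
#' @param path File path.
#' @return `write_checkpoint()`: `path` invisibly. `read_checkpoint()`: a
#'   `gcn_params`.
#' @export
write_checkpoint <- function(params, path) {
  con <- file(path, "w")
  on.exit(close(con))
  dims <- vapply(params$conv_weights, nrow, integer(1))
  writeLines(c(
    "tdtgraph-gcn-checkpoint v1",
    paste("L", params$L),
    paste("activation", params$activation)
  ), con)
  blocks <- c(params$conv_weights, list(params$head_weight, params$head_bias))
  names(blocks) <- c(sprintf("conv%d", seq_len(params$L)), "head_weight", "head_bias")
  for (nm in names(blocks)) {
    x <- blocks[[nm]]
    d <- if (is.matrix(x)) dim(x) else c(length(x), 0L)
    writeLines(paste("block", nm, d[1], d[2]), con)
    writeLines(paste(format(as.numeric(x), digits = 17), collapse = " "), con)
  }
  invisible(path)
}

#' @rdname write_checkpoint
#' @export
read_checkpoint <- function(path) {
  lines <- readLines(path)
  if (lines[1] != "tdtgraph-gcn-checkpoint v1") stop("unrecognized checkpoint format")
  L <- as.integer(strsplit(lines[2], " ")[[1]][2])
  activation <- strsplit(lines[3], " ")[[1]][2]
  i <- 4
  blocks <- list()
  while (i <= length(lines)) {
    hdr <- strsplit(lines[i], " ")[[1]]
    stopifnot(hdr[1] == "block")
    vals <- as.numeric(strsplit(trimws(lines[i + 1]), "\\s+")[[1]])
    nr <- as.integer(hdr[3]); nc <- as.integer(hdr[4])
    blocks[[hdr[2]]] <- if (nc > 0) matrix(vals, nr, nc) else vals
    i <- i + 2
  }
  structure(
    list(
      conv_weights = unname(blocks[sprintf("conv%d", seq_len(L))]),
      head_weight = blocks$head_weight,
      head_bias = blocks$head_bias,
      activation = activation, L = L
    ),
    class = "gcn_params"
  )
}
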