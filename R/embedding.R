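#' Construct a signed embedding
#'
#' Per-vertex coordinates together with a per-dimension sign signature. The
#' pair score is `score(i, j) = sum_r signature[r] * coords[i, r] *
#' coords[j, r]`. The signature lets a spectral factorization with negative
#' eigenvalues be carried as real coordinates while the score matrix still
#' reproduces the indefinite low-rank reconstruction; embeddings read from
#' node2vec-style files have an all-positive signature, so their score is the
#' plain dot product.
#'
#' @param coords Numeric matrix, one row per vertex.
#' @param signature Numeric vector of `+1`/`-1`, one per column of `coords`.
#'   Defaults to all `+1`.
#' @return An object of class `signed_embedding` with elements `coords`,
#'   `signature`, `n` and `d`.
#' @export
signed_embedding <- function(coords, signature = rep(1, ncol(coords))) {
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (length(signature) != ncol(coords)) {
    stop("`signature` length must equal the embedding dimension")
  }
  if (!all(signature %in% c(-1, 1))) {
    stop("`signature` entries must be +1 or -1")
  }
  structure(list(coords = coords, signature = as.numeric(signature),
                 n = nrow(coords), d = ncol(coords)),
            class = "signed_embedding")
}

#' @export
print.signed_embedding <- function(x, ...) {
  cat(sprintf("signed_embedding: n = %d, d = %d (%d negative dimensions)\n",
              x$n, x$d, sum(x$signature < 0)))
  invisible(x)
}

#' Spectral embedding of a graph's adjacency matrix
#'
#' Takes the `d` eigenpairs of the symmetric adjacency matrix `A` with the
#' largest eigenvalue magnitudes and returns coordinates
#' `x_i = (sqrt(|l_1|) psi_1[i], ..., sqrt(|l_d|) psi_d[i])` with signature
#' `sign(l_r)`, so that the score matrix equals the rank-`d` reconstruction
#' `A_d = Psi_d Lambda_d Psi_d^T`. Among eigenvalues of equal magnitude the
#' positive one is preferred; at `d = n` the score matrix reproduces `A`
#' to numerical precision.
#'
#' @param graph An `undirected_graph` with at least one vertex.
#' @param d Embedding dimension, `1 <= d <= n`.
#' @return A `signed_embedding`.
#' @export
spectral_embedding <- function(graph, d) {
  n <- graph$n
  if (d < 1 || d > n) stop("`d` must be between 1 and n")
  eig <- eigen(adjacency_matrix(graph), symmetric = TRUE)
  ord <- order(-abs(eig$values), -sign(eig$values))[seq_len(d)]
  vals <- eig$values[ord]
  vecs <- eig$vectors[, ord, drop = FALSE]
  # deterministic eigenvector orientation: largest-magnitude entry positive
  for (r in seq_len(d)) {
    piv <- which.max(abs(vecs[, r]))
    if (vecs[piv, r] < 0) vecs[, r] <- -vecs[, r]
  }
  signed_embedding(sweep(vecs, 2L, sqrt(abs(vals)), `*`),
                   ifelse(vals >= 0, 1, -1))
}

#' Signed pair score
#'
#' @param emb A `signed_embedding`.
#' @param i,j Vertex indices in `1..n`.
#' @return `sum_r signature[r] * x_i[r] * x_j[r]`; symmetric in `i, j`.
#' @export
pair_score <- function(emb, i, j) {
  if (any(c(i, j) < 1L) || any(c(i, j) > emb$n)) {
    stop("vertex index out of range")
  }
  sum(emb$signature * emb$coords[i, ] * emb$coords[j, ])
}

#' Score matrix (or row block) of an embedding
#'
#' @param emb A `signed_embedding`.
#' @param rows Optional vector of row indices; default all vertices.
#' @return `length(rows)` by `n` matrix of pair scores
#'   (`X diag(signature) X^T`).
#' @export
score_matrix <- function(emb, rows = NULL) {
  if (is.null(rows)) rows <- seq_len(emb$n)
  emb$coords[rows, , drop = FALSE] %*%
    (emb$signature * t(emb$coords))
}

#' Read a word2vec/node2vec-style embedding text file
#'
#' Expects a header line `n d` followed by `n` lines `id x1 ... xd`. Rows are
#' ordered by ascending id; when `graph` (with original-id labels) is
#' supplied, ids are matched through the graph's label map instead, so row
#' `i` of the result corresponds to graph vertex `i`. The signature is all
#' `+1` (plain dot-product scores).
#'
#' @param path Path to the embedding file.
#' @param graph Optional `undirected_graph` whose `labels` align file ids
#'   with vertices.
#' @return A `signed_embedding`.
#' @export
load_embedding_text <- function(path, graph = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop("empty embedding file")
  hdr <- suppressWarnings(as.integer(strsplit(trimws(lines[1L]), "\\s+")[[1L]]))
  if (length(hdr) != 2L || anyNA(hdr)) stop("malformed header (expected 'n d')")
  n <- hdr[1L]; d <- hdr[2L]
  body <- lines[-1L]
  if (length(body) != n) {
    stop(sprintf("expected %d embedding rows, found %d", n, length(body)))
  }
  toks <- strsplit(trimws(body), "\\s+")
  if (any(vapply(toks, length, 0L) != d + 1L)) {
    stop(sprintf("each row must have an id and %d coordinates", d))
  }
  ids <- suppressWarnings(as.numeric(vapply(toks, `[[`, "", 1L)))
  if (anyNA(ids)) stop("unparseable vertex id in embedding file")
  if (anyDuplicated(ids)) stop("duplicate vertex id in embedding file")
  coords <- matrix(as.numeric(unlist(lapply(toks, `[`, -1L))),
                   nrow = n, ncol = d, byrow = TRUE)
  if (anyNA(coords)) stop("unparseable coordinate in embedding file")
  if (!is.null(graph)) {
    if (is.null(graph$labels)) stop("`graph` has no label map")
    pos <- match(graph$labels, ids)
    if (anyNA(pos)) stop("embedding file is missing ids present in the graph")
    coords <- coords[pos, , drop = FALSE]
  } else {
    coords <- coords[order(ids), , drop = FALSE]
  }
  signed_embedding(coords)
}

#' Write an embedding in word2vec/node2vec text format
#'
#' Only all-positive-signature embeddings round-trip exactly, since the file
#' format carries no signature.
#'
#' @param emb A `signed_embedding`.
#' @param path Output path.
#' @param ids Optional vertex ids for the first column; default `0..n-1`.
#' @return Invisibly, `path`.
#' @export
write_embedding_text <- function(emb, path, ids = NULL) {
  if (is.null(ids)) ids <- seq_len(emb$n) - 1L
  rows <- apply(emb$coords, 1L, function(x)
    paste(format(x, digits = 17, trim = TRUE, scientific = FALSE),
          collapse = " "))
  writeLines(c(paste(emb$n, emb$d), paste(ids, rows)), path)
  invisible(path)
}
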