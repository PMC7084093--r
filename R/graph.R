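#' Construct a simple undirected graph
#'
#' Builds a simple undirected graph on vertices `1..n` from a two-column
#' edge matrix. Self-loops are dropped and duplicate edges (in either
#' orientation) are merged, so the result always satisfies the simple-graph
#' invariants: each unordered pair appears at most once and no vertex is
#' adjacent to itself.
#'
#' @param edges Two-column integer matrix (or data frame) of edges; each row
#'   is an unordered vertex pair. May have zero rows.
#' @param n Vertex count. Defaults to the largest endpoint observed (0 for an
#'   empty edge set). Must be at least the largest endpoint.
#' @param labels Optional vector of original vertex identifiers,
#'   `labels[i]` being the external name of internal vertex `i`. Length `n`.
#' @return An object of class `undirected_graph` with elements `n`,
#'   `edges` (two-column matrix, each row `i < j`, rows in lexicographic
#'   order) and `labels` (or `NULL`).
#' @export
undirected_graph <- function(edges, n = NULL, labels = NULL) {
  edges <- as.matrix(edges)
  if (length(edges) == 0L) {
    edges <- matrix(integer(0), ncol = 2L)
  }
  if (ncol(edges) != 2L) {
    stop("`edges` must have two columns")
  }
  storage.mode(edges) <- "integer"
  if (anyNA(edges)) stop("`edges` contains non-integer endpoints")
  edges <- edges[edges[, 1L] != edges[, 2L], , drop = FALSE]  # self-loops
  if (nrow(edges) > 0L) {
    edges <- cbind(pmin(edges[, 1L], edges[, 2L]),
                   pmax(edges[, 1L], edges[, 2L]))
    edges <- unique(edges)
    edges <- edges[order(edges[, 1L], edges[, 2L]), , drop = FALSE]
    if (min(edges) < 1L) stop("vertex indices must be >= 1")
  }
  max_end <- if (nrow(edges) > 0L) max(edges) else 0L
  if (is.null(n)) n <- max_end
  n <- as.integer(n)
  if (n < max_end) stop("`n` smaller than largest endpoint")
  if (!is.null(labels) && length(labels) != n) {
    stop("`labels` must have length n")
  }
  structure(list(n = n, edges = edges, labels = labels),
            class = "undirected_graph")
}

#' @export
print.undirected_graph <- function(x, ...) {
  cat(sprintf("undirected_graph: %d vertices, %d edges\n",
              x$n, nrow(x$edges)))
  invisible(x)
}

#' Number of vertices / edges of a graph
#'
#' @param graph An `undirected_graph`.
#' @return Integer count.
#' @export
graph_order <- function(graph) graph$n

#' @rdname graph_order
#' @export
graph_size <- function(graph) nrow(graph$edges)

#' Vertex degrees
#'
#' @param graph An `undirected_graph`.
#' @return Integer vector of length `n`; `degrees(g)[i]` is the number of
#'   edges incident to vertex `i`. The sum equals twice the edge count.
#' @export
degrees <- function(graph) {
  tabulate(c(graph$edges[, 1L], graph$edges[, 2L]), nbins = graph$n)
}

#' Dense adjacency matrix
#'
#' @param graph An `undirected_graph`.
#' @return Symmetric `n` by `n` 0/1 matrix with zero diagonal.
#' @export
adjacency_matrix <- function(graph) {
  A <- matrix(0, graph$n, graph$n)
  if (nrow(graph$edges) > 0L) {
    A[graph$edges] <- 1
    A[graph$edges[, c(2L, 1L), drop = FALSE]] <- 1
  }
  A
}

#' Read a whitespace-delimited edge list (SNAP dialect)
#'
#' Parses files with one `u v` pair per line; lines starting with `#` are
#' comments. Self-loops are dropped, duplicate and reversed-duplicate edges
#' merged, and vertex identifiers compacted to `1..n` (ascending original
#' order), with the original identifiers kept as labels. An empty file yields
#' the empty graph.
#'
#' @param path Path to the edge-list file.
#' @param n Optional explicit vertex count; the only way isolated vertices
#'   can be represented. When given, vertex identifiers must already be
#'   `0..n-1` or `1..n` (they are mapped onto `1..n` without compaction).
#' @return An `undirected_graph` with `labels` set to the original ids.
#' @export
read_edge_list <- function(path, n = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*(#|$)", lines)
  lines <- lines[keep]
  line_no <- which(keep)
  if (length(lines) == 0L) {
    return(undirected_graph(matrix(integer(0), ncol = 2L),
                            n = if (is.null(n)) 0L else n))
  }
  toks <- strsplit(trimws(lines), "\\s+")
  bad <- which(vapply(toks, length, 0L) < 2L)
  if (length(bad) > 0L) {
    stop(sprintf("line %d: expected two whitespace-separated integers",
                 line_no[bad[1L]]))
  }
  u <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 1L)))
  v <- suppressWarnings(as.integer(vapply(toks, `[[`, "", 2L)))
  bad <- which(is.na(u) | is.na(v))
  if (length(bad) > 0L) {
    stop(sprintf("line %d: unparseable vertex id", line_no[bad[1L]]))
  }
  if (is.null(n)) {
    ids <- sort(unique(c(u, v)))
    undirected_graph(cbind(match(u, ids), match(v, ids)),
                     n = length(ids), labels = ids)
  } else {
    off <- if (min(c(u, v)) == 0L) 1L else 0L
    undirected_graph(cbind(u + off, v + off), n = n)
  }
}

#' Write a graph as a whitespace-delimited edge list
#'
#' One `u v` line per edge with `u < v`, using original labels when present.
#' `read_edge_list(write_edge_list(g))` reproduces the graph structure.
#'
#' @param graph An `undirected_graph`.
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_edge_list <- function(graph, path) {
  e <- graph$edges
  if (!is.null(graph$labels)) {
    a <- graph$labels[e[, 1L]]
    b <- graph$labels[e[, 2L]]
    e <- cbind(pmin(a, b), pmax(a, b))
  }
  writeLines(if (nrow(e) > 0L) paste(e[, 1L], e[, 2L]) else character(0),
             path)
  invisible(path)
}
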