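# Triangle counting uses the degree-ordered forward algorithm: vertices are
# ranked by (degree, id); each edge is oriented toward the higher rank, and a
# triangle is found exactly once as a common forward neighbor of an edge's two
# endpoints. One pass also yields, per triangle, the maximum full-graph degree
# over its three corners, which is what the degree-triangle curve needs.

forward_adjacency <- function(graph) {
  deg <- degrees(graph)
  rank <- order(order(deg, seq_len(graph$n)))  # rank by (degree, id)
  e <- graph$edges
  lo <- ifelse(rank[e[, 1L]] < rank[e[, 2L]], e[, 1L], e[, 2L])
  hi <- ifelse(rank[e[, 1L]] < rank[e[, 2L]], e[, 2L], e[, 1L])
  fwd <- split(hi, factor(lo, levels = seq_len(graph$n)))
  list(fwd = fwd, lo = lo, hi = hi, deg = deg)
}

# For every triangle, the maximum degree of its three vertices (degrees taken
# in the full graph). Returns an integer vector with one entry per triangle.
triangle_max_degrees <- function(graph) {
  if (nrow(graph$edges) < 3L) return(integer(0))
  fa <- forward_adjacency(graph)
  out <- vector("list", length(fa$lo))
  for (k in seq_along(fa$lo)) {
    u <- fa$lo[k]; v <- fa$hi[k]
    nu <- fa$fwd[[u]]
    ws <- nu[nu %in% fa$fwd[[v]]]
    if (length(ws) > 0L) {
      out[[k]] <- pmax(fa$deg[u], fa$deg[v], fa$deg[ws])
    }
  }
  as.integer(unlist(out))
}

#' Count the triangles of a graph
#'
#' Exact number of unordered triangles (triples of mutually adjacent
#' vertices), computed by degree-ordered neighbor intersection so each
#' triangle is counted exactly once.
#'
#' @param graph An `undirected_graph`.
#' @return Non-negative integer triangle count.
#' @export
count_triangles <- function(graph) {
  if (nrow(graph$edges) < 3L) return(0L)
  fa <- forward_adjacency(graph)
  total <- 0L
  for (k in seq_along(fa$lo)) {
    nu <- fa$fwd[[fa$lo[k]]]
    total <- total + sum(nu %in% fa$fwd[[fa$hi[k]]])
  }
  as.integer(total)
}

#' Induced subgraph on a vertex subset
#'
#' @param graph An `undirected_graph`.
#' @param vertices Integer vector of vertex indices to keep.
#' @return An `undirected_graph` on `length(vertices)` vertices containing
#'   exactly the edges of `graph` with both endpoints in `vertices`.
#' @export
induced_subgraph <- function(graph, vertices) {
  vertices <- sort(unique(as.integer(vertices)))
  if (length(vertices) > 0L &&
      (min(vertices) < 1L || max(vertices) > graph$n)) {
    stop("vertex index out of range")
  }
  keep <- graph$edges[, 1L] %in% vertices & graph$edges[, 2L] %in% vertices
  e <- graph$edges[keep, , drop = FALSE]
  undirected_graph(cbind(match(e[, 1L], vertices), match(e[, 2L], vertices)),
                   n = length(vertices),
                   labels = if (is.null(graph$labels)) NULL
                            else graph$labels[vertices])
}

#' Triangle foundation at a degree threshold
#'
#' The (c, Delta)-triangle foundation statistic: let `S_c` be the vertices
#' whose degree in the full graph is at most `c`. `T` is the number of
#' triangles in the subgraph induced by `S_c`, and `delta = T / n`, where `n`
#' is the total vertex count of the full graph (not `|S_c|`).
#'
#' @param graph An `undirected_graph`.
#' @param c Non-negative degree threshold (inclusive: vertices with degree
#'   `<= c` are retained).
#' @return List with elements `T` (triangle count) and `delta` (`T / n`;
#'   defined as 0 for the empty graph).
#' @export
triangle_foundation <- function(graph, c) {
  if (c < 0) stop("`c` must be non-negative")
  if (graph$n == 0L) return(list(T = 0L, delta = 0))
  sc <- which(degrees(graph) <= c)
  t <- count_triangles(induced_subgraph(graph, sc))
  list(T = t, delta = t / graph$n)
}

#' Degree-triangle curve
#'
#' Evaluates the triangle foundation at every distinct degree value present
#' in the graph, in one triangle enumeration: each triangle is assigned the
#' maximum full-graph degree over its corners, and `T(c)` is the cumulative
#' count of triangles with that maximum at most `c`. This equals pointwise
#' recomputation with [triangle_foundation()].
#'
#' @param graph An `undirected_graph`.
#' @return A `degree_triangle_curve`: list with `thresholds` (ascending
#'   distinct degrees), `triangles` (`T(c)`, nondecreasing), `delta`
#'   (`T(c)/n`) and `n`.
#' @export
degree_triangle_curve <- function(graph) {
  thresholds <- sort(unique(degrees(graph)))
  md <- triangle_max_degrees(graph)
  t_c <- cumsum(tabulate(match(md, thresholds), nbins = length(thresholds)))
  structure(list(thresholds = thresholds,
                 triangles = as.integer(t_c),
                 delta = if (graph$n > 0L) t_c / graph$n else numeric(0),
                 n = graph$n),
            class = "degree_triangle_curve")
}

#' @export
print.degree_triangle_curve <- function(x, ...) {
  cat(sprintf("degree_triangle_curve: n = %d, %d thresholds, total T = %d\n",
              x$n, length(x$thresholds),
              if (length(x$triangles)) max(x$triangles) else 0L))
  invisible(x)
}

#' Evaluate a degree-triangle curve at arbitrary thresholds
#'
#' Step-function extension: below the curve's smallest threshold the density
#' is 0; at or above its largest, the total-triangle density.
#'
#' @param curve A `degree_triangle_curve`.
#' @param c Numeric vector of thresholds.
#' @return Named list with vectors `T` and `delta`, one entry per `c`.
#' @export
curve_at <- function(curve, c) {
  idx <- findInterval(c, curve$thresholds)
  t <- ifelse(idx == 0L, 0L, curve$triangles[pmax(idx, 1L)])
  list(T = as.integer(t),
       delta = if (curve$n > 0L) t / curve$n else rep(0, length(c)))
}

#' Write a degree-triangle curve as TSV
#'
#' Columns `c`, `T`, `delta` with a header line.
#'
#' @param curve A `degree_triangle_curve`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_curve_tsv <- function(curve, path) {
  df <- data.frame(c = curve$thresholds, T = curve$triangles,
                   delta = curve$delta)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
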