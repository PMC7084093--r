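# Fixture generators with known (c, Delta)-triangle foundations.  They stand
# in for downloaded real networks: sparse graphs whose low-degree triangle
# structure is known exactly (disjoint cliques, planted triangles) or in
# expectation (G(n, p)), plus latent-vector families for which the truncated
# dot product equals the raw dot.

fixture_spec <- function(generator, parameters, ground_truth) {
  list(generator = generator, parameters = parameters,
       ground_truth = ground_truth)
}

#' Erdos-Renyi random graph
#'
#' Each of the `n(n-1)/2` unordered pairs is an edge independently with
#' probability `p`.
#'
#' @param n Vertex count.
#' @param p Edge probability.
#' @param seed Integer seed.
#' @return An `undirected_graph`.
#' @export
random_gnp <- function(n, p, seed) {
  pairs <- which(upper.tri(matrix(0, n, n)), arr.ind = TRUE)
  keep <- with_seed(seed, stats::runif(nrow(pairs)) < p)
  undirected_graph(pairs[keep, , drop = FALSE], n = n)
}

#' Disjoint union of cliques
#'
#' `m` vertex-disjoint copies of the complete graph `K_k`: `n = m * k`,
#' every degree `k - 1`, `m * choose(k, 3)` triangles, all of them on
#' degree-`(k-1)` vertices, so `delta(k - 1) = choose(k, 3) / k`. With
#' `k = 3` this is the canonical extremal witness: `delta(2) = 1/3` at
#' degree bound 2.
#'
#' @param m Number of cliques, at least 1.
#' @param k Clique size, at least 3.
#' @return List with `graph` (an `undirected_graph`) and `spec` (generator
#'   name, parameters, and exact ground truth: `triangles`, `degree`,
#'   `delta` at threshold `c = k - 1`).
#' @export
disjoint_cliques <- function(m, k) {
  if (m < 1 || k < 3) stop("need m >= 1 cliques of size k >= 3")
  within <- utils::combn(k, 2L)
  edges <- do.call(rbind, lapply(seq_len(m) - 1L, function(b) {
    cbind(within[1L, ] + b * k, within[2L, ] + b * k)
  }))
  list(graph = undirected_graph(edges, n = m * k),
       spec = fixture_spec("disjoint_cliques", list(m = m, k = k),
                           list(n = m * k,
                                triangles = m * choose(k, 3),
                                degree = k - 1L,
                                c = k - 1L,
                                delta = choose(k, 3) / k)))
}

#' Sparse random graph with planted vertex-disjoint triangles
#'
#' The union of a seeded `G(n, base_p)` and `planted` vertex-disjoint
#' triangles on the first `3 * planted` vertices. The planted count is an
#' exact lower bound on the total triangle count (the background may add
#' more); planting disjointly keeps the degree impact to +2 per planted
#' vertex.
#'
#' @param n Vertex count, `n >= 3 * planted`.
#' @param base_p Background edge probability.
#' @param planted Number of planted triangles.
#' @param seed Integer seed for the background graph.
#' @return List with `graph` and `spec` (ground truth records the planted
#'   lower bound).
#' @export
planted_triangle_graph <- function(n, base_p, planted, seed) {
  if (3 * planted > n) stop("`planted` too large: need 3 * planted <= n")
  base <- if (base_p > 0) random_gnp(n, base_p, seed)$edges
          else matrix(integer(0), ncol = 2L)
  tri <- if (planted > 0) {
    a <- 3L * (seq_len(planted) - 1L)
    rbind(cbind(a + 1L, a + 2L), cbind(a + 1L, a + 3L), cbind(a + 2L, a + 3L))
  } else matrix(integer(0), ncol = 2L)
  list(graph = undirected_graph(rbind(base, tri), n = n),
       spec = fixture_spec("planted_triangle_graph",
                           list(n = n, base_p = base_p, planted = planted,
                                seed = seed),
                           list(min_triangles = planted)))
}

#' Latent-position vector families for dot-product graphs
#'
#' Generates nonnegative coordinate vectors whose pairwise dot products lie
#' in `[0, 1]`, so the truncated dot product equals the raw dot and the
#' family directly parameterizes a random dot-product graph.
#' `style = "clustered"` places vectors near `n_clusters` orthogonal
#' centroids of squared length `self_dot` (within-cluster dots near
#' `self_dot`, cross-cluster dots near 0) — the stochastic-block-model
#' regime. `style = "spherical"` draws unit-norm nonnegative vectors
#' uniformly (folded Gaussian directions).
#'
#' @param n Number of vectors.
#' @param d Dimension, at least 1 (clustered style needs `d >= n_clusters`).
#' @param style `"clustered"` or `"spherical"`.
#' @param seed Integer seed.
#' @param n_clusters Number of centroids for the clustered style.
#' @param self_dot Centroid squared length (within-cluster edge
#'   probability), in (0, 1].
#' @param noise Uniform perturbation half-width for the clustered style.
#' @return List with `emb` (a `signed_embedding`, all-positive signature)
#'   and `spec`.
#' @export
rdpg_vectors <- function(n, d, style = c("clustered", "spherical"), seed,
                         n_clusters = 2L, self_dot = 0.9, noise = 0.02) {
  style <- match.arg(style)
  coords <- with_seed(seed, {
    if (style == "clustered") {
      if (d < n_clusters) stop("clustered style needs d >= n_clusters")
      cluster <- rep_len(seq_len(n_clusters), n)
      base <- matrix(0, n, d)
      base[cbind(seq_len(n), cluster)] <- sqrt(self_dot)
      pert <- matrix(stats::runif(n * d, 0, noise), n, d)
      x <- base + pert
      # rescale so no pairwise dot can exceed 1
      x / max(1, max(sqrt(rowSums(x^2))))
    } else {
      x <- abs(matrix(stats::rnorm(n * d), n, d))
      x / sqrt(rowSums(x^2))
    }
  })
  list(emb = signed_embedding(coords),
       spec = fixture_spec("rdpg_vectors",
                           list(n = n, d = d, style = style, seed = seed,
                                n_clusters = if (style == "clustered")
                                  n_clusters else NULL,
                                self_dot = if (style == "clustered")
                                  self_dot else NULL),
                           list(score_range = c(0, 1))))
}

#' Write a fixture to disk
#'
#' Writes the graph as a standard edge list (or the embedding as a text
#' embedding file) with a JSON sidecar holding the generator spec.
#'
#' @param fixture A list from one of the fixture generators.
#' @param path Output path for the edge list / embedding file; the sidecar
#'   is written to `paste0(path, ".json")`.
#' @return Invisibly, `path`.
#' @export
write_fixture <- function(fixture, path) {
  if (!is.null(fixture$graph)) {
    write_edge_list(fixture$graph, path)
  } else {
    write_embedding_text(fixture$emb, path)
  }
  writeLines(jsonlite::toJSON(fixture$spec, auto_unbox = TRUE, digits = NA,
                              null = "null"),
             paste0(path, ".json"))
  invisible(path)
}
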