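# Independent oracles used across the suite.

# Exhaustive O(n^3) triangle enumeration over all vertex triples.
brute_triangle_count <- function(graph) {
  n <- graph_order(graph)
  if (n < 3L) return(0L)
  A <- adjacency_matrix(graph)
  tr <- utils::combn(n, 3L)
  sum(A[cbind(tr[1L, ], tr[2L, ])] *
        A[cbind(tr[1L, ], tr[3L, ])] *
        A[cbind(tr[2L, ], tr[3L, ])])
}

# Exhaustive degree-triangle curve: per triple, mutual adjacency and the
# maximum full-graph degree over its corners.
brute_curve <- function(graph) {
  n <- graph_order(graph)
  deg <- degrees(graph)
  thresholds <- sort(unique(deg))
  if (n < 3L) {
    return(list(thresholds = thresholds,
                triangles = rep(0L, length(thresholds))))
  }
  A <- adjacency_matrix(graph)
  tr <- utils::combn(n, 3L)
  is_tri <- A[cbind(tr[1L, ], tr[2L, ])] *
    A[cbind(tr[1L, ], tr[3L, ])] *
    A[cbind(tr[2L, ], tr[3L, ])] > 0
  md <- pmax(deg[tr[1L, ]], deg[tr[2L, ]], deg[tr[3L, ]])[is_tri]
  list(thresholds = thresholds,
       triangles = vapply(thresholds, function(c) sum(md <= c), 0L))
}

complete_graph <- function(k) {
  e <- utils::combn(k, 2L)
  undirected_graph(cbind(e[1L, ], e[2L, ]), n = k)
}

# Constant-probability model: all-equal 1-d coordinates give a TDP
# probability of exactly `p` for every pair.
constant_model <- function(n, p) {
  tdp_model(signed_embedding(matrix(sqrt(p), n, 1L)))
}

random_unit_vectors <- function(s, d) {
  u <- matrix(stats::rnorm(s * d), s, d)
  u / sqrt(rowSums(u^2))
}
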