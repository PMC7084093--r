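# Numeric certificates for the linear-algebra apparatus behind the
# triangle-foundation rank lower bounds.  Each routine evaluates an
# inequality on concrete inputs and reports the quantities on both sides,
# so failures are informative rather than boolean.

#' Rank-lemma certificate for a square matrix
#'
#' For any square matrix `M`, `(sum_i M_ii)^2 <= rank(M) * sum_ij M_ij^2`.
#' The certificate reports the trace squared, the squared-entry sum, their
#' ratio (the rank lower bound; 0 when the denominator is 0), and the
#' numerical rank of `M`.
#'
#' @param M Square numeric matrix (symmetric within tolerance for the
#'   certificate to be meaningful; symmetry is not enforced).
#' @param tol Singular-value threshold for the numerical rank, relative to
#'   the largest singular value; default `max(dim) * .Machine$double.eps`.
#' @return A `rank_certificate`: list with `trace_sq`, `entry_sq_sum`,
#'   `bound`, `numerical_rank` and `holds` (bound does not exceed the rank,
#'   up to slack).
#' @export
rank_lemma_certificate <- function(M, tol = NULL) {
  M <- as.matrix(M)
  if (nrow(M) != ncol(M)) stop("`M` must be square")
  trace_sq <- sum(diag(M))^2
  entry_sq <- sum(M^2)
  bound <- if (entry_sq > 0) trace_sq / entry_sq else 0
  sv <- svd(M, nu = 0L, nv = 0L)$d
  if (is.null(tol)) tol <- max(dim(M)) * .Machine$double.eps
  num_rank <- sum(sv > tol * max(sv, 0))
  structure(list(trace_sq = trace_sq, entry_sq_sum = entry_sq,
                 bound = bound, numerical_rank = num_rank,
                 holds = bound <= num_rank + 1e-9),
            class = "rank_certificate")
}

#' @export
print.rank_certificate <- function(x, ...) {
  cat(sprintf("rank_certificate: bound %.4g <= numerical rank %d (%s)\n",
              x$bound, x$numerical_rank, if (x$holds) "holds" else "VIOLATED"))
  invisible(x)
}

#' Dot-sum balance of a vector family
#'
#' Over all ordered pairs (diagonal included) of a family of vectors, the
#' total magnitude of negative pairwise dot products never exceeds the total
#' magnitude of positive ones — a consequence of
#' `sum_ij w_i . w_j = ||sum_i w_i||^2 >= 0`.
#'
#' @param vectors Numeric matrix with one vector per row, or a list of
#'   equal-length numeric vectors.
#' @param tol Slack for the `holds` flag.
#' @return List with `neg_sum`, `pos_sum` and `holds`.
#' @export
dot_sum_balance <- function(vectors, tol = 1e-9) {
  W <- vectors_as_matrix(vectors)
  G <- W %*% t(W)
  neg_sum <- sum(abs(G[G < 0]))
  pos_sum <- sum(G[G > 0])
  list(neg_sum = neg_sum, pos_sum = pos_sum,
       holds = neg_sum <= pos_sum + tol)
}

vectors_as_matrix <- function(vectors) {
  if (is.list(vectors)) {
    lens <- vapply(vectors, length, 0L)
    if (length(vectors) == 0L) stop("empty vector family")
    if (length(unique(lens)) != 1L) stop("vectors differ in dimension")
    vectors <- do.call(rbind, vectors)
  }
  as.matrix(vectors)
}

#' Packing witness among unit vectors
#'
#' Any `4d` (or more) unit vectors in `R^d` contain a pair with dot product
#' at least `1/(4d)`. Returns the maximizing off-diagonal pair, which always
#' satisfies the bound; returning the maximum (rather than any witness)
#' makes a hypothetical violation maximally informative.
#'
#' @param vectors Unit vectors (rows of a matrix, or a list), at least `4d`
#'   of them, each of norm 1 within `1e-8`.
#' @param d Ambient dimension; must equal the vector length.
#' @return List with indices `i`, `j` (`i < j`), their `dot`, and the
#'   guaranteed lower bound `1/(4d)`.
#' @export
packing_witness <- function(vectors, d) {
  U <- vectors_as_matrix(vectors)
  if (ncol(U) != d) stop("vectors are not in dimension d")
  if (nrow(U) < 4 * d) stop("need at least 4d vectors")
  norms <- sqrt(rowSums(U^2))
  if (any(abs(norms - 1) > 1e-8)) stop("all vectors must be unit norm")
  G <- U %*% t(U)
  diag(G) <- -Inf
  best <- arrayInd(which.max(G), dim(G))
  i <- min(best); j <- max(best)
  list(i = i, j = j, dot = G[best[1L], best[2L]], lower_bound = 1 / (4 * d))
}

#' Rank lower bound for triangle-rich low-degree graphs
#'
#' The explicit rank lower bound `min(1, alpha * delta^4 / c^9) * n /
#' log2(n)^2` for any embedding whose sampled graphs have at least
#' `delta * n` expected triangles among vertices of expected degree at most
#' `c`. The hypotheses require `c > 4` and `delta > 0`; `alpha` defaults to
#' the threshold constant `1 / (128 * 3600 * 4^4)`.
#'
#' @param c Degree bound, `c > 4`.
#' @param delta Triangle density, `delta > 0`.
#' @param n Vertex count, `n >= 2`.
#' @param alpha Constant in (0, 1]; default `1 / (128 * 3600 * 4^4)`.
#' @return A `theorem_bound` list with `c`, `delta`, `n`, `alpha`, `bound`.
#' @export
theorem1_rank_bound <- function(c, delta, n, alpha = 1 / (128 * 3600 * 4^4)) {
  if (c <= 4) stop("hypotheses require a degree bound c > 4")
  if (delta <= 0) stop("hypotheses require a triangle density delta > 0")
  if (n < 2) stop("`n` must be at least 2")
  bound <- min(1, alpha * delta^4 / c^9) * n / log2(n)^2
  structure(list(c = c, delta = delta, n = n, alpha = alpha, bound = bound),
            class = "theorem_bound")
}

#' Rank lower bound in the equal-length regime
#'
#' When every latent vector has the same length `L`, the rank bound is linear
#' in `n`: `rank >= delta^2 / (c * (delta^2 + c^4)) * n`. Also reports the
#' minimum common length forced by the triangle count,
#' `L_min = sqrt(delta) / c` (from `delta * n <= L^2 c^2 n`).
#'
#' @param c Degree bound, `c > 0`.
#' @param delta Triangle density, `delta >= 0`.
#' @param n Vertex count, `n >= 1`.
#' @return A `theorem_bound` list with `c`, `delta`, `n`, `bound` and
#'   `L_min`.
#' @export
equal_length_rank_bound <- function(c, delta, n) {
  if (c <= 0) stop("`c` must be positive")
  if (delta < 0) stop("`delta` must be non-negative")
  if (n < 1) stop("`n` must be at least 1")
  structure(list(c = c, delta = delta, n = n,
                 bound = delta^2 / (c * (delta^2 + c^4)) * n,
                 L_min = sqrt(delta) / c),
            class = "theorem_bound")
}

#' @export
print.theorem_bound <- function(x, ...) {
  cat(sprintf("theorem_bound: c = %g, delta = %g, n = %d -> rank >= %.6g\n",
              x$c, x$delta, as.integer(x$n), x$bound))
  invisible(x)
}

#' Serialize a certificate to JSON
#'
#' @param cert A `rank_certificate`, `theorem_bound`, or any list of numeric
#'   certificate fields.
#' @param path Optional output path.
#' @return The JSON string (invisibly when written).
#' @export
certificate_to_json <- function(cert, path = NULL) {
  js <- jsonlite::toJSON(unclass(cert), auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
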