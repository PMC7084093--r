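# Four symmetric dot-product edge-probability models over a shared
# signed-embedding score s(i,j):
#   TDP      p = clamp(s, 0, 1)                     (truncated dot product)
#   LRDP     p = L * sigmoid(k * (s - x0))          (logistic on the dot)
#   LRHP     p = L * sigmoid(w . f + b),  f[r] = signature[r] x_ir x_jr
#   SOFTMAX  directed q(i->j) = deg(i) softmax_j(s(i,.)), symmetrized
# All probabilities are evaluated lazily in row blocks; the n x n matrix is
# never required by the contracts.

new_edge_model <- function(variant, emb, params, calibration = NULL) {
  structure(list(variant = variant, emb = emb, params = params,
                 calibration = calibration),
            class = "edge_model")
}

#' @export
print.edge_model <- function(x, ...) {
  cat(sprintf("edge_model: %s, n = %d, d = %d\n",
              x$variant, x$emb$n, x$emb$d))
  if (!is.null(x$calibration)) {
    cat(sprintf("  calibration residual: %.3g (target edges %g)\n",
                x$calibration$residual, x$calibration$target_edges))
  }
  invisible(x)
}

with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has_old) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv(),
                          inherits = FALSE))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

pair_scores_vec <- function(emb, i, j) {
  rowSums((emb$coords[i, , drop = FALSE] *
             rep(emb$signature, each = length(i))) *
            emb$coords[j, , drop = FALSE])
}

#' Truncated dot product (TDP) model
#'
#' Edge probability `max(0, min(score(i, j), 1))`: a score of 1 or more means
#' the edge is always present, a negative score means never.
#'
#' @param emb A `signed_embedding`.
#' @return An `edge_model` with variant `"TDP"`.
#' @export
tdp_model <- function(emb) new_edge_model("TDP", emb, list())

#' LRDP model from explicit parameters
#'
#' Edge probability `L / (1 + exp(-k * (score(i, j) - x0)))`.
#'
#' @param emb A `signed_embedding`.
#' @param L Amplitude in (0, 1].
#' @param k Slope, `k >= 0` (probability nondecreasing in the score).
#' @param x0 Threshold score.
#' @return An `edge_model` with variant `"LRDP"`.
#' @export
lrdp_model <- function(emb, L, k, x0) {
  if (L <= 0 || L > 1) stop("`L` must be in (0, 1]")
  if (k < 0) stop("`k` must be non-negative")
  new_edge_model("LRDP", emb, list(L = L, k = k, x0 = x0))
}

#' LRHP model from explicit parameters
#'
#' Edge probability `L * sigmoid(w . f(i, j) + b)` where `f(i, j)[r] =
#' signature[r] * x_ir * x_jr` is the (signed) Hadamard-product feature
#' vector. With tied weights `w = k * 1` and `b = -k * x0` this reproduces
#' the LRDP probability for every pair.
#'
#' @param emb A `signed_embedding`.
#' @param w Weight vector of length `d`.
#' @param b Intercept.
#' @param L Amplitude in (0, 1].
#' @return An `edge_model` with variant `"LRHP"`.
#' @export
lrhp_model <- function(emb, w, b, L = 1) {
  if (length(w) != emb$d) stop("`w` must have length d")
  if (L <= 0 || L > 1) stop("`L` must be in (0, 1]")
  new_edge_model("LRHP", emb, list(w = as.numeric(w), b = b, L = L))
}

# Uniform sample of `count` distinct non-adjacent unordered pairs.
sample_non_edges <- function(graph, count, seed) {
  n <- graph$n
  total_pairs <- n * (n - 1) / 2
  avail <- total_pairs - nrow(graph$edges)
  if (count > avail) stop("not enough non-edges to sample")
  edge_key <- (graph$edges[, 1L] - 1) * n + graph$edges[, 2L]
  got <- numeric(0)
  with_seed(seed, {
    while (length(got) < count) {
      i <- sample.int(n, 2L * count, replace = TRUE)
      j <- sample.int(n, 2L * count, replace = TRUE)
      a <- pmin(i, j); b <- pmax(i, j)
      key <- (a - 1) * n + b
      key <- key[a != b & !(key %in% edge_key)]
      got <- unique(c(got, key))
    }
  })
  got <- got[seq_len(count)]
  cbind(floor((got - 1) / n) + 1, ((got - 1) %% n) + 1)
}

# Sum of sigmoid(eta + shift) over all unordered pairs, blockwise.
pair_sigmoid_sum <- function(emb, eta_fun, shift = 0, block = 512L) {
  n <- emb$n
  total <- 0
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    eta <- eta_fun(rows)
    p <- stats::plogis(eta + shift)
    p[cbind(seq_along(rows), rows)] <- 0
    total <- total + sum(p)
  }
  total / 2
}

# Shared L / intercept-shift calibration: p = L * sigmoid(eta + shift) must
# have sum over pairs equal to m.  Sum is linear in L, so L = m / S is exact
# while it stays within (0, 1]; otherwise L is pinned at 1 and the shift is
# solved by monotone root finding (the sum is increasing in the shift).
calibrate_amplitude <- function(emb, eta_fun, m, tol) {
  s0 <- pair_sigmoid_sum(emb, eta_fun)
  if (s0 >= m) {
    list(L = m / s0, shift = 0, residual = 0)
  } else {
    f <- function(shift) pair_sigmoid_sum(emb, eta_fun, shift) - m
    root <- stats::uniroot(f, c(0, 1), extendInt = "upX", tol = 1e-10)
    resid <- abs(f(root$root)) / m
    if (resid > tol) {
      stop(sprintf("calibration did not converge: residual %.3g", resid))
    }
    list(L = 1, shift = root$root, residual = resid)
  }
}

#' Fit the LRDP model to a graph
#'
#' Fits the logistic-of-dot-product model `p = L * sigmoid(k * (s - x0))` so
#' that the expected number of edges matches the observed number. The slope
#' and threshold come from a logistic regression of edges (label 1) against a
#' uniformly sampled set of non-edges (label 0); the amplitude `L` is then
#' calibrated exactly against the observed edge count (pinning `L = 1` and
#' shifting `x0` when the fitted scale cannot reach the count on its own).
#' The slope is constrained to `k >= 0`, so the probability is nondecreasing
#' in the score.
#'
#' @param emb A `signed_embedding` sharing `n` with `graph`.
#' @param graph The observed `undirected_graph` (at least one edge).
#' @param tol Relative tolerance on the expected-vs-observed edge count
#'   (default 1%).
#' @param neg_ratio Non-edges sampled per edge (default 1).
#' @param seed Seed for the non-edge sample.
#' @return A calibrated `edge_model` with variant `"LRDP"`; its
#'   `calibration` element records the residual and the non-edge seed.
#' @export
fit_lrdp <- function(emb, graph, tol = 0.01, neg_ratio = 1, seed = 1L) {
  if (emb$n != graph$n) stop("embedding and graph disagree on n")
  m <- nrow(graph$edges)
  if (m < 1L) stop("graph has no edges to calibrate against")
  s_pos <- pair_scores_vec(emb, graph$edges[, 1L], graph$edges[, 2L])
  ne <- sample_non_edges(graph, max(1L, round(neg_ratio * m)), seed)
  s_neg <- pair_scores_vec(emb, ne[, 1L], ne[, 2L])
  s <- c(s_pos, s_neg)
  y <- rep(c(1L, 0L), c(length(s_pos), length(s_neg)))
  co <- if (stats::sd(s) > 0) {
    suppressWarnings(stats::coef(stats::glm(y ~ s, family = stats::binomial())))
  } else c(0, 0)
  k <- max(if (is.na(co[2L])) 0 else co[2L], 0)
  x0 <- if (k > 0) -co[1L] / k else 0
  eta_fun <- function(rows) k * (score_matrix(emb, rows) - x0)
  cal <- calibrate_amplitude(emb, eta_fun, m, tol)
  if (cal$shift != 0 && k == 0) {
    stop("cannot calibrate a flat-score LRDP model to this edge count")
  }
  new_edge_model("LRDP", emb,
                 list(L = cal$L, k = k,
                      x0 = if (k > 0) x0 - cal$shift / k else x0),
                 list(residual = cal$residual, target_edges = m, seed = seed))
}

#' Fit the LRHP model to a graph
#'
#' Logistic regression on the signed Hadamard-product features
#' `f(i, j)[r] = signature[r] * x_ir * x_jr`, trained on edges versus a
#' uniformly sampled set of non-edges (ridge-regularized for stability),
#' then amplitude-calibrated so the expected edge count matches the observed
#' count, as in [fit_lrdp()].
#'
#' @inheritParams fit_lrdp
#' @param lambda Ridge penalty for the logistic fit (ignored when `d = 1`,
#'   where an unpenalized fit is used).
#' @return A calibrated `edge_model` with variant `"LRHP"`.
#' @export
fit_lrhp <- function(emb, graph, tol = 0.01, neg_ratio = 1, seed = 1L,
                     lambda = 1e-3) {
  if (emb$n != graph$n) stop("embedding and graph disagree on n")
  m <- nrow(graph$edges)
  if (m < 1L) stop("graph has no edges to calibrate against")
  feats <- function(i, j) {
    emb$coords[i, , drop = FALSE] * emb$coords[j, , drop = FALSE] *
      rep(emb$signature, each = length(i))
  }
  ne <- sample_non_edges(graph, max(1L, round(neg_ratio * m)), seed)
  X <- rbind(feats(graph$edges[, 1L], graph$edges[, 2L]),
             feats(ne[, 1L], ne[, 2L]))
  y <- rep(c(1L, 0L), c(m, nrow(ne)))
  if (emb$d >= 2L && stats::sd(as.vector(X)) > 0) {
    fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 0,
                          lambda = lambda, standardize = FALSE)
    w <- as.numeric(fit$beta[, 1L])
    b <- as.numeric(fit$a0[1L])
  } else {
    co <- if (stats::sd(X[, 1L]) > 0) {
      suppressWarnings(stats::coef(stats::glm(y ~ X[, 1L],
                                              family = stats::binomial())))
    } else c(0, 0)
    w <- c(if (is.na(co[2L])) 0 else co[2L], rep(0, emb$d - 1L))
    b <- co[1L]
  }
  eta_fun <- function(rows) {
    emb$coords[rows, , drop = FALSE] %*%
      ((w * emb$signature) * t(emb$coords)) + b
  }
  cal <- calibrate_amplitude(emb, eta_fun, m, tol)
  new_edge_model("LRHP", emb,
                 list(w = w, b = b + cal$shift, L = cal$L),
                 list(residual = cal$residual, target_edges = m, seed = seed))
}

#' Fit the degree-calibrated softmax model
#'
#' Directed probability `q(i -> j) = deg(i) * exp(s(i, j)) /
#' sum_{k != i} exp(s(i, k))`, so each row of `q` sums exactly to the
#' observed degree of `i` (a softmax with a per-vertex proportionality
#' constant matching the expected degree to the true degree). The undirected
#' probability is the symmetrized, clamped average
#' `p(i, j) = clamp((q(i->j) + q(j->i)) / 2, 0, 1)`. Exponentials are
#' computed with per-row max subtraction; an isolated vertex gets an all-zero
#' row.
#'
#' @param emb A `signed_embedding` sharing `n` with `graph`.
#' @param graph The observed `undirected_graph`.
#' @param block Row-block size for the normalizer pass.
#' @return An `edge_model` with variant `"SOFTMAX"`; `params` holds the
#'   per-vertex degrees, row maxima and normalizers.
#' @export
fit_softmax <- function(emb, graph, block = 512L) {
  if (emb$n != graph$n) stop("embedding and graph disagree on n")
  n <- emb$n
  deg <- degrees(graph)
  rowmax <- numeric(n)
  z <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    s <- score_matrix(emb, rows)
    s[cbind(seq_along(rows), rows)] <- -Inf  # exclude self-term
    rowmax[rows] <- apply(s, 1L, max)
    z[rows] <- rowSums(exp(s - rowmax[rows]))
  }
  new_edge_model("SOFTMAX", emb,
                 list(deg = deg, rowmax = rowmax, z = z))
}

# Directed softmax rows q(i -> .) for i in `rows` (pre-symmetrization).
softmax_q_rows <- function(model, rows) {
  emb <- model$emb
  p <- model$params
  s <- score_matrix(emb, rows)
  q <- (p$deg[rows] / p$z[rows]) * exp(s - p$rowmax[rows])
  q[p$deg[rows] == 0L, ] <- 0
  q[cbind(seq_along(rows), rows)] <- 0
  q
}

# Row block of the symmetric probability matrix, diagonal zeroed.
prob_rows <- function(model, rows = NULL) {
  emb <- model$emb
  if (is.null(rows)) rows <- seq_len(emb$n)
  p <- switch(model$variant,
    TDP = {
      s <- score_matrix(emb, rows)
      pmin(pmax(s, 0), 1)
    },
    LRDP = {
      pr <- model$params
      pr$L * stats::plogis(pr$k * (score_matrix(emb, rows) - pr$x0))
    },
    LRHP = {
      pr <- model$params
      eta <- emb$coords[rows, , drop = FALSE] %*%
        ((pr$w * emb$signature) * t(emb$coords)) + pr$b
      pr$L * stats::plogis(eta)
    },
    SOFTMAX = {
      pr <- model$params
      q_fwd <- softmax_q_rows(model, rows)
      s <- score_matrix(emb, rows)
      # q(j -> i) for column j: uses column-vertex degree and normalizer
      q_bwd <- sweep(exp(sweep(s, 2L, pr$rowmax, `-`)), 2L,
                     pr$deg / pr$z, `*`)
      q_bwd[, pr$deg == 0L] <- 0
      pmin(pmax((q_fwd + q_bwd) / 2, 0), 1)
    },
    stop("unknown model variant: ", model$variant))
  p[cbind(seq_along(rows), rows)] <- 0
  p
}

#' Edge probability of a model for one vertex pair
#'
#' @param model An `edge_model`.
#' @param i,j Distinct vertex indices in `1..n`.
#' @return Probability in `[0, 1]`; symmetric in `i, j`, and 0 for `i = j`.
#' @export
edge_probability <- function(model, i, j) {
  n <- model$emb$n
  if (any(c(i, j) < 1L) || any(c(i, j) > n)) stop("vertex index out of range")
  prob_rows(model, i)[1L, j]
}

#' Expected degrees and expected edge count of a model
#'
#' `E[D_i] = sum_{j != i} p(i, j)`, accumulated in row blocks so the full
#' probability matrix is never materialized; the expected number of edges is
#' half the sum of expected degrees.
#'
#' @param model An `edge_model`.
#' @param block Row-block size.
#' @return List with `degrees` (length-`n` numeric) and `expected_edges`.
#' @export
expected_degrees <- function(model, block = 512L) {
  n <- model$emb$n
  ed <- numeric(n)
  for (start in seq(1L, n, by = block)) {
    rows <- start:min(start + block - 1L, n)
    ed[rows] <- rowSums(prob_rows(model, rows))
  }
  list(degrees = ed, expected_edges = sum(ed) / 2)
}

#' Serialize a model's parameters to JSON
#'
#' Records the variant, the variant-specific parameters, the embedding shape,
#' and the calibration metadata (seed and residual) when present.
#'
#' @param model An `edge_model`.
#' @param path Optional output path; when `NULL` the JSON string is returned.
#' @return The JSON string, invisibly when written to `path`.
#' @export
model_to_json <- function(model, path = NULL) {
  doc <- list(variant = model$variant,
              n = model$emb$n, d = model$emb$d,
              params = model$params[setdiff(names(model$params),
                                            c("deg", "rowmax", "z"))],
              calibration = model$calibration)
  js <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, null = "null")
  if (is.null(path)) return(js)
  writeLines(js, path)
  invisible(js)
}
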