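test_that("TDP clamps scores into [0, 1]", {
  emb <- signed_embedding(rbind(sqrt(1.5), sqrt(0.42), 1e-3, -sqrt(0.3)))
  # pairwise scores: products of the 1-d coordinates
  m <- tdp_model(emb)
  expect_equal(edge_probability(m, 1L, 2L),   # interior of the clamp
               sqrt(1.5) * sqrt(0.42), tolerance = 1e-12)
  big <- tdp_model(signed_embedding(rbind(sqrt(1.5), sqrt(1.5))))
  expect_equal(edge_probability(big, 1L, 2L), 1)      # score 1.5 -> 1
  neg <- tdp_model(signed_embedding(rbind(sqrt(0.3), -sqrt(0.3))))
  expect_equal(edge_probability(neg, 1L, 2L), 0)      # score -0.3 -> 0
  k2 <- complete_graph(2L)
  expect_equal(edge_probability(tdp_model(spectral_embedding(k2, 2L)), 1L, 2L),
               1, tolerance = 1e-12)
})

test_that("all variants are symmetric, in range, with zero diagonal", {
  set.seed(7)
  g <- random_gnp(60, 0.15, seed = 44)
  emb <- spectral_embedding(g, 8L)
  models <- list(tdp = tdp_model(emb),
                 lrdp = fit_lrdp(emb, g, seed = 2L),
                 lrhp = fit_lrhp(emb, g, seed = 2L),
                 softmax = fit_softmax(emb, g))
  for (m in models) {
    P <- prob_rows(m)
    expect_true(all(P >= 0 & P <= 1))
    expect_true(all(diag(P) == 0))
    expect_lt(max(abs(P - t(P))), 1e-12)
    i <- sample.int(60, 1L); j <- sample.int(59, 1L)
    if (j >= i) j <- j + 1L
    expect_equal(edge_probability(m, i, j), edge_probability(m, j, i))
  }
})

test_that("LRDP closed forms: k = 0 and flat scores give constant models", {
  emb <- signed_embedding(matrix(1, 10, 1))
  m0 <- lrdp_model(emb, L = 0.6, k = 0, x0 = 3)
  expect_equal(edge_probability(m0, 1L, 5L), 0.6 / 2)  # L * sigmoid(0)

  g <- random_gnp(10, 0.4, seed = 12)
  mflat <- fit_lrdp(emb, g, seed = 5L)
  m <- graph_size(g)
  expect_equal(edge_probability(mflat, 2L, 7L), 2 * m / (10 * 9),
               tolerance = 1e-9)
})

test_that("LRDP calibration matches the observed edge count and is monotone", {
  # graph sampled from a known logistic model on planted scores
  vecs <- rdpg_vectors(200L, 6L, "clustered", seed = 8L, n_clusters = 3L)
  emb <- vecs$emb
  planted <- lrdp_model(emb, L = 0.9, k = 6, x0 = 0.35)
  g <- sample_graph(planted, seed = 19L)
  fit <- fit_lrdp(emb, g, seed = 4L)
  expect_gte(fit$params$k, 0)
  ed <- expected_degrees(fit)
  expect_lt(abs(ed$expected_edges - graph_size(g)) / graph_size(g), 0.01)
  # probability nondecreasing in score
  s <- score_matrix(emb)
  P <- prob_rows(fit)
  off <- upper.tri(s)
  ord <- order(s[off])
  expect_true(all(diff(P[off][ord]) >= -1e-12))
})

test_that("LRHP with tied weights reproduces LRDP, and calibrates on blocks", {
  g <- random_gnp(40, 0.2, seed = 31)
  emb <- spectral_embedding(g, 6L)
  k <- 2.5; x0 <- 0.2
  lrdp <- lrdp_model(emb, L = 0.8, k = k, x0 = x0)
  lrhp <- lrhp_model(emb, w = rep(k, 6L), b = -k * x0, L = 0.8)
  expect_lt(max(abs(prob_rows(lrdp) - prob_rows(lrhp))), 1e-9)

  # planted 2-block model at n = 200: calibrated within 1%
  vecs <- rdpg_vectors(200L, 4L, "clustered", seed = 15L, n_clusters = 2L)
  g2 <- sample_graph(tdp_model(vecs$emb), seed = 22L)
  fit <- fit_lrhp(vecs$emb, g2, seed = 6L)
  ed <- expected_degrees(fit)
  expect_lt(abs(ed$expected_edges - graph_size(g2)) / graph_size(g2), 0.01)

  # d = 1, all coordinates 1: features constant -> constant model
  emb1 <- signed_embedding(matrix(1, 30, 1))
  g3 <- random_gnp(30, 0.3, seed = 40)
  fit1 <- fit_lrhp(emb1, g3, seed = 7L)
  expect_equal(edge_probability(fit1, 3L, 17L),
               2 * graph_size(g3) / (30 * 29), tolerance = 1e-9)
})

test_that("softmax matches expected degrees and closed forms", {
  # identical vectors, k-regular graph: p = k / (n - 1) for all pairs
  cyc <- undirected_graph(cbind(1:6, c(2:6, 1L)), n = 6L)  # 2-regular
  emb_same <- signed_embedding(matrix(0.5, 6, 2))
  msame <- fit_softmax(emb_same, cyc)
  expect_equal(unname(prob_rows(msame)[1L, 2L]), 2 / 5, tolerance = 1e-12)

  # identical vectors, general graph: p = (deg_i + deg_j) / (2 (n - 1))
  g <- random_gnp(12, 0.4, seed = 50)
  emb12 <- signed_embedding(matrix(0.3, 12, 3))
  mgen <- fit_softmax(emb12, g)
  d <- degrees(g)
  P <- prob_rows(mgen)
  expect_equal(unname(P[2L, 9L]), (d[2L] + d[9L]) / (2 * 11),
               tolerance = 1e-12)

  # pre-clamp directed row sums equal the degrees exactly
  g2 <- random_gnp(80, 0.1, seed = 51)
  m2 <- fit_softmax(spectral_embedding(g2, 10L), g2)
  q <- trifound:::softmax_q_rows(m2, seq_len(80))
  expect_lt(max(abs(rowSums(q) - degrees(g2))), 1e-9)

  # isolated vertices give all-zero directed rows; expected edges <= observed
  g3 <- undirected_graph(cbind(c(1L, 1L, 2L), c(2L, 3L, 3L)), n = 5L)
  m3 <- fit_softmax(spectral_embedding(g3, 2L), g3)
  expect_true(all(trifound:::softmax_q_rows(m3, 4L) == 0))
  ed3 <- expected_degrees(m3)
  expect_lte(ed3$expected_edges, graph_size(g3) + 1e-9)
})

test_that("expected degrees reduce to exact and constant cases", {
  g <- random_gnp(25, 0.3, seed = 60)
  m <- tdp_model(spectral_embedding(g, 25L))
  ed <- expected_degrees(m)
  expect_equal(ed$degrees, as.numeric(degrees(g)), tolerance = 1e-7)
  expect_equal(ed$expected_edges, graph_size(g), tolerance = 1e-7)

  ed5 <- expected_degrees(constant_model(5L, 0.5))
  expect_equal(ed5$degrees, rep(2, 5))

  # blockwise accumulation is block-size invariant
  ed_small <- expected_degrees(m, block = 7L)
  expect_equal(ed_small$degrees, ed$degrees)
})

test_that("model parameters serialize to JSON", {
  emb <- signed_embedding(matrix(1, 4, 1))
  js <- jsonlite::fromJSON(model_to_json(lrdp_model(emb, 0.5, 2, 0.1)))
  expect_equal(js$variant, "LRDP")
  expect_equal(js$params$L, 0.5)
  expect_equal(js$n, 4L)
})
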