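test_that("degenerate probabilities sample deterministically", {
  k3 <- complete_graph(3L)
  m1 <- tdp_model(spectral_embedding(k3, 3L))
  for (s in 1:5) {
    g <- sample_graph(m1, seed = s)
    expect_equal(unname(g$edges), unname(k3$edges))
  }
  m0 <- constant_model(10L, 0)
  expect_equal(graph_size(sample_graph(m0, seed = 1L)), 0L)
})

test_that("sampling is deterministic in (model, seed) and block-invariant", {
  g <- random_gnp(30, 0.2, seed = 70)
  m <- tdp_model(spectral_embedding(g, 6L))
  g1 <- sample_graph(m, seed = 123L)
  g2 <- sample_graph(m, seed = 123L)
  expect_identical(g1$edges, g2$edges)
  g3 <- sample_graph(m, seed = 123L, block = 4L)
  expect_identical(g1$edges, g3$edges)
  g4 <- sample_graph(m, seed = 124L)
  expect_false(identical(g1$edges, g4$edges))
})

test_that("sampled edge counts follow the binomial law", {
  m <- constant_model(40L, 0.3)
  counts <- vapply(1:200, function(s) graph_size(sample_graph(m, seed = s)),
                   0L)
  npairs <- choose(40, 2)
  mu <- 0.3 * npairs
  se <- sqrt(npairs * 0.3 * 0.7 / 200)
  expect_lt(abs(mean(counts) - mu), 4 * se)
})

test_that("sampled degrees match expected degrees within Monte-Carlo error", {
  vecs <- rdpg_vectors(50L, 3L, "spherical", seed = 80L)
  m <- tdp_model(vecs$emb)
  ed <- expected_degrees(m)$degrees
  reps <- 200L
  acc <- matrix(0, reps, 50L)
  for (r in seq_len(reps)) {
    acc[r, ] <- degrees(sample_graph(m, seed = 500L + r))
  }
  se <- apply(acc, 2L, sd) / sqrt(reps)
  expect_true(all(abs(colMeans(acc) - ed) <= 5 * pmax(se, 0.02)))
})

test_that("replicate audit merges curves by pointwise maximum", {
  g <- random_gnp(40, 0.25, seed = 90)
  m <- tdp_model(spectral_embedding(g, 8L))
  one <- replicate_audit(m, 1L, seed = 7L)
  expect_equal(one$max_curve$thresholds, one$curves[[1L]]$thresholds)
  expect_equal(one$max_curve$triangles, one$curves[[1L]]$triangles)

  summ <- replicate_audit(m, 6L, seed = 7L)
  expect_length(summ$curves, 6L)
  for (cv in summ$curves) {
    at <- curve_at(cv, summ$max_curve$thresholds)
    expect_true(all(at$delta <= summ$max_curve$delta + 1e-12))
  }
  expect_equal(summ$edge_counts$mean, mean(summ$edge_sizes))

  summ2 <- replicate_audit(m, 6L, seed = 7L)
  expect_identical(summ$max_curve, summ2$max_curve)  # determinism

  k4 <- complete_graph(4L)
  sure <- replicate_audit(tdp_model(spectral_embedding(k4, 4L)), 3L,
                          seed = 2L)
  expect_equal(curve_at(sure$max_curve, 3)$delta, 1.0)
})

test_that("second-moment inequality for sampled degrees holds", {
  # E[D_i^2] <= E[D_i] + E[D_i]^2 for independent-pair Bernoulli sampling
  m <- constant_model(30L, 0.2)
  ed <- expected_degrees(m)$degrees
  reps <- 300L
  d2 <- matrix(0, reps, 30L)
  for (r in seq_len(reps)) {
    d2[r, ] <- degrees(sample_graph(m, seed = 900L + r))^2
  }
  se <- apply(d2, 2L, sd) / sqrt(reps)
  expect_true(all(colMeans(d2) <= ed + ed^2 + 4 * se))
})

test_that("sample summaries export TSV and JSON metadata", {
  g <- random_gnp(20, 0.3, seed = 95)
  m <- tdp_model(spectral_embedding(g, 5L))
  summ <- replicate_audit(m, 3L, seed = 1L)
  tsv <- withr::local_tempfile(fileext = ".tsv")
  js <- withr::local_tempfile(fileext = ".json")
  meta <- write_sample_summary(summ, m, tsv, js)
  tab <- read.delim(tsv)
  expect_named(tab, c("c", "T_max", "delta_max"))
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$variant, "TDP")
  expect_length(parsed$replicate_seeds, 3L)
  expect_equal(parsed$replicate_edges, summ$edge_sizes)
  expect_match(parsed$model_hash, "^[0-9a-f]{32}$")
})
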