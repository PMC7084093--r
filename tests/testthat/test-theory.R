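test_that("rank-lemma certificate is exact on equality cases", {
  id5 <- rank_lemma_certificate(diag(5))
  expect_equal(id5$bound, 5)
  expect_equal(id5$numerical_rank, 5L)
  expect_true(id5$holds)

  ones4 <- rank_lemma_certificate(matrix(1, 4, 4))
  expect_equal(ones4$bound, 1)
  expect_equal(ones4$numerical_rank, 1L)
  expect_true(ones4$holds)

  expect_error(rank_lemma_certificate(matrix(1, 2, 3)), "square")
  expect_equal(rank_lemma_certificate(matrix(0, 3, 3))$bound, 0)
})

test_that("rank-lemma bound never exceeds the numerical rank", {
  set.seed(61)
  for (rep in 1:60) {
    n <- sample(2:40, 1L)
    M <- if (rep %% 2 == 0) {
      X <- matrix(rnorm(n * sample(1:10, 1L)), nrow = n)
      X %*% t(X)                          # Gram matrix
    } else {
      S <- matrix(rnorm(n * n), n, n)
      (S + t(S)) / 2                      # symmetric
    }
    cert <- rank_lemma_certificate(M)
    expect_true(cert$holds)
    expect_gte(cert$bound, 0)
  }
  # Gram matrix of 30 random vectors in R^7: bound at most 7
  X <- matrix(rnorm(30 * 7), 30, 7)
  cert <- rank_lemma_certificate(X %*% t(X))
  expect_lte(cert$bound, 7)
  expect_lte(cert$numerical_rank, 7L)
})

test_that("dot-sum balance follows from the squared-sum identity", {
  u <- c(1, 0, 0)
  bal <- dot_sum_balance(rbind(u, -u))
  expect_equal(bal$neg_sum, 2)
  expect_equal(bal$pos_sum, 2)
  expect_true(bal$holds)

  single <- dot_sum_balance(rbind(c(0.3, -2)))
  expect_equal(single$neg_sum, 0)
  expect_true(single$holds)

  set.seed(62)
  for (rep in 1:30) {
    W <- matrix(rnorm(sample(2:50, 1L) * 5), ncol = 5)
    expect_true(dot_sum_balance(W)$holds)
  }
  expect_error(dot_sum_balance(list(c(1, 2), c(1, 2, 3))), "dimension")
})

test_that("packing witness attains the 1/(4d) guarantee", {
  w1 <- packing_witness(rbind(1, 1, -1, -1), d = 1L)
  expect_equal(w1$dot, 1)
  expect_gte(w1$dot, 1 / 4)

  angles <- (0:7) * pi / 4
  w2 <- packing_witness(cbind(cos(angles), sin(angles)), d = 2L)
  expect_equal(w2$dot, cos(pi / 4), tolerance = 1e-12)
  expect_gte(w2$dot, 1 / 8)

  set.seed(63)
  for (rep in 1:40) {
    d <- sample(2:20, 1L)
    U <- random_unit_vectors(4L * d, d)
    w <- packing_witness(U, d)
    expect_gte(w$dot, 1 / (4 * d))
    # the returned pair is the off-diagonal maximum
    G <- U %*% t(U); diag(G) <- -Inf
    expect_equal(w$dot, max(G))
  }

  expect_error(packing_witness(random_unit_vectors(7L, 2L), 2L), "4d")
  expect_error(packing_witness(2 * random_unit_vectors(8L, 2L), 2L), "unit")
})

test_that("explicit rank bound matches direct arithmetic and hypotheses", {
  tb <- theorem1_rank_bound(5, 1, 2^20)
  alpha <- 1 / (128 * 3600 * 4^4)
  expect_equal(tb$bound, alpha * 5^-9 * 2^20 / 400)

  expect_error(theorem1_rank_bound(4, 1, 100), "c > 4")
  expect_error(theorem1_rank_bound(5, 0, 100), "delta > 0")
  expect_error(theorem1_rank_bound(5, 1, 1), "at least 2")

  # monotone: nondecreasing in delta, nonincreasing in c, increasing in n
  deltas <- c(1e-4, 1e-2, 0.5, 1, 5)
  b_delta <- vapply(deltas, function(d) theorem1_rank_bound(5, d, 1e6)$bound,
                    0)
  expect_true(all(diff(b_delta) >= 0))
  cs <- c(4.5, 5, 10, 50)
  b_c <- vapply(cs, function(c) theorem1_rank_bound(c, 1, 1e6)$bound, 0)
  expect_true(all(diff(b_c) <= 0))
  expect_gt(theorem1_rank_bound(5, 1, 2^21)$bound,
            theorem1_rank_bound(5, 1, 2^20)$bound)
  # vanishing density drives the bound to zero
  expect_lt(theorem1_rank_bound(5, 1e-12, 1e6)$bound, 1e-30)
})

test_that("equal-length bound and minimum length follow the closed form", {
  b <- equal_length_rank_bound(5, 1, 3130)
  expect_equal(b$bound, 1)
  expect_equal(b$L_min, sqrt(1) / 5)
  expect_equal(equal_length_rank_bound(3, 0, 100)$bound, 0)

  set.seed(64)
  for (rep in 1:20) {
    c <- runif(1, 0.5, 20); delta <- runif(1, 0.01, 10)
    n <- sample(10:10000, 1L)
    b <- equal_length_rank_bound(c, delta, n)
    expect_equal(b$bound * c * (delta^2 + c^4) / delta^2, n,
                 tolerance = 1e-9)
    expect_equal(b$L_min^2, delta / c^2, tolerance = 1e-12)
  }
})

test_that("certificates serialize to JSON", {
  cert <- rank_lemma_certificate(diag(3))
  parsed <- jsonlite::fromJSON(certificate_to_json(cert))
  expect_equal(parsed$bound, 3)
  expect_true(parsed$holds)
})
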