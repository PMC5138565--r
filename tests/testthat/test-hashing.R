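make_two_class <- function(n_per = 20, d = 6, sep = 6, seed = 1) {
  withr::with_seed(seed, {
    X <- rbind(matrix(rnorm(n_per * d), n_per, d),
               matrix(rnorm(n_per * d, mean = sep), n_per, d))
    list(X = X, labels = rep(c(0L, 1L), each = n_per))
  })
}

test_that("kernel rows are Gaussian with hand-checkable values", {
  anchors <- matrix(c(0, 0, 3, 4), 2, 2, byrow = TRUE)
  kr <- kernel_row(c(0, 0), anchors, sigma = 2)
  expect_equal(kr[1], 1.0)
  expect_true(all(kr > 0 & kr <= 1))
  # 1-D, ||x - a|| = sigma * sqrt(2) -> exp(-1)
  s <- 1.7
  kr2 <- kernel_row(0, matrix(s * sqrt(2), 1, 1), sigma = s)
  expect_equal(kr2, exp(-1), tolerance = 1e-12)
  expect_error(kernel_row(c(0, 0), anchors, sigma = 0), "sigma")
})

test_that("label matrix encodes same/different with a +1 diagonal", {
  expect_equal(build_label_matrix(c(1, 1, 1)), matrix(1, 3, 3))
  expect_equal(build_label_matrix(c(0, 1)),
               matrix(c(1, -1, -1, 1), 2, 2))
  S <- build_label_matrix(c(0, 1, 0, 1, 1))
  expect_equal(S, t(S))
  expect_equal(diag(S), rep(1, 5))
})

test_that("the bias gives exact mean-zero hash inputs over the training set", {
  K <- withr::with_seed(6, matrix(runif(40 * 5), 40, 5))
  expect_equal(compute_bias(K, rep(0, 5)), 0)
  a <- withr::with_seed(7, rnorm(5))
  b <- compute_bias(K, a)
  f <- K %*% a - b
  expect_lt(abs(mean(f)), 1e-9)
  # n = 2, one anchor, hand arithmetic
  K2 <- matrix(c(0.4, 0.6), 2, 1)
  expect_equal(compute_bias(K2, 2), (0.4 * 2 + 0.6 * 2) / 2)
})

test_that("training rejects inconsistent sample sizes", {
  tc <- make_two_class(10)
  expect_error(train_ksh(tc$X, tc$labels, r = 4, m_anchor = 5, l = 30), "exceed")
  expect_error(train_ksh(tc$X, tc$labels, r = 4, m_anchor = 12, l = 12),
               "m_anchor")
})

test_that("greedy training: trace is non-increasing and matches the direct objective", {
  tc <- make_two_class(25, seed = 3)
  m <- train_ksh(tc$X, tc$labels, r = 12, m_anchor = 10, l = 40, seed = 2)
  expect_true(all(diff(m$trace) <= 1e-6))
  # direct Frobenius evaluation of || B B' - r S || ^2 on the l samples
  Xl <- tc$X[m$label_idx, , drop = FALSE]
  K <- exp(-as.matrix(stats::dist(rbind(Xl, m$anchors)))[1:40, 41:50]^2 /
             (2 * m$sigma^2))
  B <- sign(sweep(K, 2, m$kernel_mean) %*% m$A)
  B[B == 0] <- 1
  S <- build_label_matrix(tc$labels[m$label_idx])
  expect_equal(m$objective, sum((tcrossprod(B) - m$r * S)^2))
})

test_that("a single greedy bit comes close to the exhaustive optimum", {
  for (s in 1:3) {
    tc <- make_two_class(4, d = 3, sep = 5, seed = s)  # l = n = 8
    m <- train_ksh(tc$X, tc$labels, r = 1, m_anchor = 4, l = 8, seed = s)
    S <- build_label_matrix(tc$labels[m$label_idx])
    greedy_cost <- m$trace[1]
    best <- Inf
    for (code in 0:255) {
      b <- 2 * as.integer(intToBits(code)[1:8]) - 1
      best <- min(best, sum((outer(b, b) - S)^2))
    }
    expect_gte(greedy_cost, best)
    expect_lte(greedy_cost, 1.5 * best + 1e-9)
  }
})

test_that("codes separate well-split classes and beat random coefficients", {
  tc <- make_two_class(20, seed = 5)
  m <- train_ksh(tc$X, tc$labels, r = 8, m_anchor = 12, l = 40, seed = 4)
  B <- encode_features(tc$X[m$label_idx, ], m)
  ip <- tcrossprod(B)
  same <- build_label_matrix(tc$labels[m$label_idx]) > 0
  ut <- upper.tri(ip)
  expect_gt(min(ip[same & ut]), max(ip[!same & ut]))

  # supervision works: random A with the same anchors/sigma does worse
  m_rand <- m
  m_rand$A <- withr::with_seed(8, matrix(rnorm(length(m$A)), nrow(m$A)))
  m_rand$bias <- rep(0, m$r)
  B_r <- encode_features(tc$X[m$label_idx, ], m_rand)
  ip_r <- tcrossprod(B_r)
  expect_gt(mean(ip[same & ut]), mean(ip_r[same & ut]))
})

test_that("encoding is deterministic, sign valued, and hand checkable", {
  tc <- make_two_class(10, seed = 9)
  m <- train_ksh(tc$X, tc$labels, r = 4, m_anchor = 6, l = 20, seed = 1)
  B1 <- encode_features(tc$X, m)
  B2 <- encode_features(tc$X, m)
  expect_identical(B1, B2)
  expect_true(all(B1 %in% c(-1, 1)))
  expect_error(encode_features(tc$X[, 1:3], m), "dimension")

  # single anchor, single bit: sign of kappa * a - b by hand
  hand <- structure(
    list(anchors = matrix(0, 1, 1), A = matrix(2, 1, 1), sigma = 1,
         bias = 0.5, r = 1L, kernel_mean = 0.25),
    class = "ksh_model"
  )
  # x = 0: kappa = 1, f = 2 - 0.5 = 1.5 -> +1
  expect_equal(drop(encode_features(matrix(0, 1, 1), hand)), 1)
  # x far away: kappa ~ 0, f ~ -0.5 -> -1
  expect_equal(drop(encode_features(matrix(10, 1, 1), hand)), -1)
})

test_that("every trained hash function is mean zero over the training set", {
  tc <- make_two_class(20, seed = 12)
  m <- train_ksh(tc$X, tc$labels, r = 6, m_anchor = 8, l = 40, seed = 3)
  K <- exp(-(outer(rowSums(tc$X^2), rowSums(m$anchors^2), "+") -
               2 * tc$X %*% t(m$anchors)) / (2 * m$sigma^2))
  F_ <- K %*% m$A - rep(m$bias, each = nrow(tc$X))
  expect_lt(max(abs(colMeans(F_))), 1e-9)
})
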