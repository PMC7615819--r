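test_that("the closed-form map solves the least-squares transition problem", {
  # rank-1 case: W = x2 x1^T / |x1|^2 maps x1 to x2 exactly
  x1 <- c(2, 0, 1); x2 <- c(0, 1, -1)
  s <- pattern_sequence(rbind(x1, x2))
  W <- closed_form_weights(s, center = FALSE)
  expect_equal(W, outer(x2, x1) / sum(x1^2))
  expect_equal(as.numeric(W %*% x1), x2)

  # orthonormal-like stored patterns: C = I so A C^+ = A = W_AHN
  H <- hadamard_rows(2) / 2             # rows orthonormal in R^4
  sH <- pattern_sequence(H)
  WH <- closed_form_weights(sH, center = FALSE)
  A <- t(crossprod(H[1:3, ], H[2:4, ]))
  expect_equal(WH, A, tolerance = 1e-10)

  # generic overdetermined case against an independent QR least-squares solve
  withr::with_seed(9, {
    X <- matrix(rnorm(10 * 6), 10, 6)
  })
  s2 <- pattern_sequence(X)
  W2 <- closed_form_weights(s2, center = FALSE)
  prev <- X[1:9, ]; nxt <- X[2:10, ]
  W_qr <- t(qr.coef(qr(prev), nxt))     # full column rank: unique LS solution
  expect_lt(norm(W2 - W_qr, "F") / norm(W_qr, "F"), 1e-8)
})

test_that("the whitener inverts the square root of the mean second moment", {
  # diagonal case: C / P = diag(4, 1) gives M = diag(1/2, 1)
  s <- pattern_sequence(rbind(c(sqrt(8), 0), c(0, sqrt(2)), c(1, 1)))
  wh <- whitening_matrix(s, center = FALSE)
  expect_equal(wh$M, diag(c(1 / 2, 1)), tolerance = 1e-6)

  # full-rank sequence: whitened second moment is the identity
  s2 <- generate_binary_sequence(10, 11, seed = 21)
  wh2 <- whitening_matrix(s2, center = FALSE)
  X <- as.matrix(s2)
  Mx <- X[1:10, ] %*% wh2$M
  expect_lt(norm(crossprod(Mx) / 10 - diag(10), "F"), 1e-4)

  # rank-deficient input: no error, identity holds on the span
  Xd <- rbind(c(1, 0, 0), c(2, 0, 0), c(0, 1, 0), c(1, 1, 1))
  whd <- whitening_matrix(pattern_sequence(Xd), center = FALSE)
  expect_equal(whd$rank, 2L)
  S <- crossprod(Xd[1:3, ] %*% whd$M) / 3
  U <- whd$basis
  expect_lt(norm(t(U) %*% S %*% U - diag(2), "F"), 1e-10)
})

test_that("whitened retrieval equals the closed-form map applied to the query", {
  for (sd in 1:3) {
    s <- center_sequence(generate_correlated_binary_sequence(15, 9, 0.4, seed = sd))
    W <- closed_form_weights(s, center = FALSE)
    wh <- whitening_matrix(s, center = FALSE)
    X <- as.matrix(s)
    for (mu in c(1, 4, 8)) {
      want <- as.numeric(W %*% X[mu, ])
      got <- whitened_retrieve(s, wh, X[mu, ])
      expect_lt(sqrt(sum((got - want)^2)) / sqrt(sum(want^2)), 1e-6)
    }
  }
})

test_that("whitening with M = I reduces to identity-separation Hopfield retrieval", {
  s <- generate_binary_sequence(6, 5, seed = 2)
  wh <- whitening_matrix(s, center = FALSE)
  wh$M <- diag(6)
  wh$mean <- rep(0, 6)
  q <- as.numeric(as.matrix(s)[3, ])
  raw <- ahn_retrieve(ahn(s, sep_identity()), q, binary_output = FALSE)
  expect_equal(whitened_retrieve(s, wh, q), as.numeric(raw) / 4)  # mean over P = 4
})

test_that("whitened retrieval is exact for correlated patterns where raw dot products fail", {
  # full-rank regime: stored query returns its successor exactly under
  # whitening, while the classical asymmetric network degrades with b
  s <- generate_correlated_binary_sequence(40, 9, 0.6, seed = 14)
  X <- as.matrix(s)
  wh <- whitening_matrix(s, center = FALSE)
  errs_wh <- errs_ahn <- numeric(7)
  m_ahn <- ahn(s, sep_identity())
  for (mu in 1:7) {
    errs_wh[mu] <- max(abs(whitened_retrieve(s, wh, X[mu, ]) - X[mu + 1, ]))
    r <- ahn_retrieve(m_ahn, X[mu, ], binary_output = TRUE)
    errs_ahn[mu] <- mean(r != X[mu + 1, ])
  }
  expect_lt(max(errs_wh), 1e-6)
  expect_gt(mean(errs_ahn), 0)          # raw dot products make bit errors
})
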