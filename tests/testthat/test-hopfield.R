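test_that("the asymmetric weight matrix is the cross-step outer-product sum", {
  s <- pattern_sequence(rbind(c(1, 1), c(1, -1)), domain = "binary")
  expect_equal(ahn(s)$W_AHN, rbind(c(1, 1), c(-1, -1)))

  s3 <- pattern_sequence(rbind(c(1, 1), c(1, -1), c(-1, 1)), domain = "binary")
  X <- as.matrix(s3)
  expect_equal(ahn(s3)$W_AHN, outer(X[2, ], X[1, ]) + outer(X[3, ], X[2, ]))

  sb <- generate_binary_sequence(7, 6, seed = 1)
  W <- ahn(sb)$W_AHN
  expect_true(all(W == round(W)))
  expect_true(all(abs(W) <= 5))         # P = 5 transitions of +/-1 products
})

test_that("orthogonal stored patterns are retrieved exactly", {
  H <- hadamard_rows(3)                 # 8 orthogonal binary patterns
  s <- pattern_sequence(H[1:5, ], domain = "binary")
  m <- ahn(s)
  for (k in 1:4)
    expect_equal(ahn_retrieve(m, H[k, ], binary_output = TRUE),
                 H[k + 1, ], ignore_attr = TRUE)
})

test_that("softmax separation is a convex combination that sharpens with beta", {
  s <- generate_binary_sequence(12, 6, seed = 3)
  m <- ahn(s, sep_softmax(beta = 5))
  r <- ahn_retrieve(m, as.matrix(s)[2, ], binary_output = FALSE)
  w <- attr(r, "weights")
  expect_equal(sum(w), 1)
  expect_true(all(w >= 0))
  # retrieval lies in the convex hull of the successor patterns
  expect_true(all(r >= apply(as.matrix(s)[-1, ], 2, min) - 1e-12))
  expect_true(all(r <= apply(as.matrix(s)[-1, ], 2, max) + 1e-12))

  # large beta puts weight ~1 on the best-matching transition
  mbig <- ahn(s, sep_softmax(beta = 50))
  rbig <- ahn_retrieve(mbig, as.matrix(s)[2, ], binary_output = TRUE)
  expect_equal(rbig, as.matrix(s)[3, ], ignore_attr = TRUE)
  expect_gt(max(attr(rbig, "weights")), 0.999)
})

test_that("degree-1 polynomial retrieval equals the materialized matrix form", {
  for (sd in 1:3) {
    s <- generate_binary_sequence(10, 7, seed = sd)
    q <- as.numeric(generate_binary_sequence(10, 2, seed = sd + 100)[1, ])
    m1 <- ahn(s, sep_polynomial(1))
    mI <- ahn(s, sep_identity())
    expect_equal(ahn_retrieve(m1, q, binary_output = TRUE),
                 ifelse(as.numeric(mI$W_AHN %*% q) >= 0, 1, -1),
                 ignore_attr = TRUE)
  }
})

test_that("sequence recall chains single-shot retrievals", {
  H <- hadamard_rows(3)
  s <- pattern_sequence(H[1:4, ], domain = "binary")
  m <- ahn(s)
  r_on <- ahn_recall(m, s, mode = "online")
  r_off <- ahn_recall(m, s, mode = "offline")
  expect_equal(as.matrix(r_on$recalled), as.matrix(s), ignore_attr = TRUE)
  expect_equal(as.matrix(r_off$recalled)[2, ], as.matrix(r_on$recalled)[2, ])

  s2 <- pattern_sequence(H[1:2, ], domain = "binary")
  expect_equal(as.matrix(ahn_recall(ahn(s2), s2, mode = "online")$recalled)[2, ],
               H[2, ], ignore_attr = TRUE)
})

test_that("a frame with outsized norm hijacks softmax offline recall", {
  withr::with_seed(42, {
    # positively biased frames so dot products are positive, with one
    # source frame of 10x norm: its successor hijacks the softmax
    X <- matrix(rnorm(8 * 30), 8, 30) + 0.5
    X[5, ] <- X[5, ] * 10
  })
  s <- pattern_sequence(X)
  m <- ahn(s, sep_softmax(beta = 5))
  diag_tab <- strong_attractor_diagnostic(m, s)
  expect_true(attr(diag_tab, "hit"))
  expect_error(strong_attractor_diagnostic(ahn(s, sep_identity()), s), "softmax")
})

test_that("the sign convention maps zero to +1", {
  s <- pattern_sequence(rbind(c(1, 1), c(1, -1)), domain = "binary")
  m <- ahn(s)
  r <- ahn_retrieve(m, c(1, -1), binary_output = TRUE)  # scores include a zero
  expect_true(all(r %in% c(-1, 1)))
  expect_equal(seqmem:::sign_pm(0), 1)
})
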