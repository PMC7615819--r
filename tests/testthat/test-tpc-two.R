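test_that("two-layer recall honors the shape contract", {
  s <- generate_binary_sequence(8, 5, seed = 1)
  m <- tpc_two(8, hidden_dim = 6, seed = 1)
  m <- tpc_train(m, s, n_epochs = 30, tol = 0)
  r <- tpc_recall(m, s, mode = "offline")
  expect_equal(dim(r$recalled), dim(s))
  expect_equal(dim(r$hidden_trajectory), c(5L, 6L))
  expect_true(all(is.finite(r$hidden_trajectory)))
  expect_equal(as.matrix(r$recalled)[1, ], as.matrix(s)[1, ])  # cue passthrough
})

test_that("hidden inference with zero weights relaxes to the origin", {
  z <- seqmem:::tpc_infer_hidden_cpp(rep(1, 4), rep(2, 3), matrix(0, 3, 3),
                            matrix(0, 4, 3), 0.1, 500, 1e-10, TRUE, FALSE)
  expect_lt(max(abs(z$z)), 1e-4)
})

test_that("hidden inference energy is non-increasing along the relaxation", {
  withr::with_seed(1, {
    for (i in 1:3) {
      WF <- matrix(rnorm(12, sd = 0.5), 4, 3)
      WH <- matrix(rnorm(9, sd = 0.5), 3, 3)
      out <- seqmem:::tpc_infer_hidden_cpp(rnorm(4), rnorm(3), WH, WF,
                                  0.01, 300, 0, TRUE, FALSE)
      expect_true(all(diff(out$energy_trace) <= 1e-12))
    }
  })
})

test_that("the moving-bar movie is memorized and de-aliased by hidden context", {
  bar <- generate_moving_bar()
  m <- train_moving_bar_model(seed = 1)
  r <- tpc_recall(m, bar, mode = "offline")
  frame_mse <- rowMeans((as.matrix(r$recalled) - as.matrix(bar))^2)
  expect_lt(max(frame_mse[-1]), 1e-2)
  # identical inputs at steps 2 and 4, distinct hidden states
  expect_gt(hidden_context_separation(m, bar), 0.01)
  Z <- r$hidden_trajectory
  cosine <- sum(Z[2, ] * Z[4, ]) / sqrt(sum(Z[2, ]^2) * sum(Z[4, ]^2))
  expect_lt(cosine, 0.99)
})

test_that("online recall is no worse than offline recall on average", {
  err_on <- err_off <- numeric(4)
  for (sd in 1:4) {
    s <- generate_binary_sequence(20, 8, seed = sd)
    m <- tpc_two(20, hidden_dim = 40, seed = sd, lr_weights = 3e-3)
    m <- tpc_train(m, s, n_epochs = 100, tol = 0)
    err_on[sd] <- recall_mse(tpc_recall(m, s, mode = "online"), s)
    err_off[sd] <- recall_mse(tpc_recall(m, s, mode = "offline"), s)
  }
  expect_lte(mean(err_on), mean(err_off) + 1e-10)
})

test_that("two-layer training is deterministic and divergence raises", {
  s <- generate_binary_sequence(6, 4, seed = 2)
  a <- tpc_train(tpc_two(6, hidden_dim = 4, seed = 3), s, n_epochs = 20, tol = 0)
  b <- tpc_train(tpc_two(6, hidden_dim = 4, seed = 3), s, n_epochs = 20, tol = 0)
  expect_identical(a$WH, b$WH)
  expect_identical(a$WF, b$WF)

  m_bad <- tpc_two(6, hidden_dim = 4, seed = 1, lr_weights = 50, optimizer = "sgd")
  expect_error(tpc_train(m_bad, s, n_epochs = 500, tol = 0), "diverged")
})
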