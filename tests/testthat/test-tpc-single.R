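test_that("single-layer training follows the prediction-error gradient", {
  # all-zero sequence: every error is zero, W never moves
  zeros <- pattern_sequence(matrix(0, 4, 6))
  m <- tpc_train(tpc_single(6), zeros, n_epochs = 10)
  expect_equal(m$W, matrix(0, 6, 6))

  # one gradient step from W = 0 on a single transition is lr * x2 x1^T
  x1 <- c(1, -1, 1); x2 <- c(-1, 1, 1)
  s <- pattern_sequence(rbind(x1, x2), domain = "binary")
  m1 <- tpc_train(tpc_single(3, lr_weights = 0.05), s, n_epochs = 1)
  expect_equal(m1$W, 0.05 * outer(x2, x1))
})

test_that("linear training converges to the least-squares transition map", {
  s <- generate_binary_sequence(20, 11, seed = 5)
  m <- tpc_train(tpc_single(20), s, n_epochs = 5000, tol = 1e-12)
  W_ls <- closed_form_weights(s, center = FALSE)
  expect_lt(norm(m$W - W_ls, "F") / norm(W_ls, "F"), 1e-3)
})

test_that("recall converges to W f(q) and the protocols agree at step 2", {
  s <- generate_binary_sequence(15, 8, seed = 2)
  m <- tpc_train(tpc_single(15), s, n_epochs = 2000, tol = 1e-10)
  X <- as.matrix(s)
  r_on <- tpc_recall(m, s, mode = "online")
  for (mu in 2:8)
    expect_lt(max(abs(as.matrix(r_on$recalled)[mu, ] -
                        as.numeric(m$W %*% X[mu - 1, ]))), 1e-4)
  r_off <- tpc_recall(m, s, mode = "offline")
  expect_equal(as.matrix(r_off$recalled)[2, ], as.matrix(r_on$recalled)[2, ])

  # two-pattern sequence trained to convergence recalls exactly
  s2 <- generate_binary_sequence(10, 2, seed = 3)
  m2 <- tpc_train(tpc_single(10), s2, n_epochs = 2000, tol = 1e-12)
  expect_lt(recall_mse(tpc_recall(m2, s2, mode = "online"), s2), 1e-3)
})

test_that("stored patterns act as attractors in the linear full-rank regime", {
  # P << N, well-conditioned: online recall is essentially exact
  s <- generate_binary_sequence(60, 9, seed = 4)
  m <- tpc_train(tpc_single(60), s, n_epochs = 2000, tol = 1e-12)
  expect_lt(recall_mse(tpc_recall(m, s, mode = "online"), s), 1e-4)
})

test_that("recall inference energy is non-increasing along the relaxation", {
  for (sd in 1:3) {
    s <- generate_binary_sequence(12, 6, seed = sd)
    m <- tpc_train(tpc_single(12, lr_inference = 0.01), s, n_epochs = 100)
    r <- tpc_recall(m, s, mode = "online", trace_energy = TRUE)
    for (tr in r$inference_traces)
      if (length(tr) > 1) expect_true(all(diff(tr) <= 1e-12))
  }
})

test_that("training is deterministic and guards against divergence", {
  s <- generate_binary_sequence(10, 6, seed = 6)
  a <- tpc_train(tpc_single(10), s, n_epochs = 50)
  b <- tpc_train(tpc_single(10), s, n_epochs = 50)
  expect_identical(a$W, b$W)

  expect_error(tpc_train(tpc_single(10, lr_weights = 10), s, n_epochs = 200),
               "diverged.*learning rate")
  expect_warning(tpc_recall(tpc_single(10), s), "untrained")
})
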