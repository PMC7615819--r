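test_that("bit_error_rate counts sign mismatches over scored steps", {
  t <- generate_binary_sequence(100, 10, seed = 1)
  expect_equal(bit_error_rate(t, t), 0)

  flipped <- pattern_sequence(-as.matrix(t), domain = "binary")
  expect_equal(bit_error_rate(flipped, t), 1)

  one_off <- as.matrix(t)
  one_off[5, 17] <- -one_off[5, 17]
  expect_equal(bit_error_rate(pattern_sequence(one_off), t), 1 / 900)

  expect_error(bit_error_rate(generate_binary_sequence(5, 3, seed = 1), t),
               "same shape")
  expect_error(bit_error_rate(t, pattern_sequence(matrix(0, 10, 100))), "binary")
})

test_that("recall_mse averages squared errors over scored steps", {
  t <- generate_binary_sequence(6, 5, seed = 2)
  expect_equal(recall_mse(t, t), 0)
  shifted <- pattern_sequence(as.matrix(t) + 0.3)
  expect_equal(recall_mse(shifted, t), 0.09)

  # hand-computed toy: scored step differs by (1, -2)
  truth <- pattern_sequence(rbind(c(0, 0), c(1, 1)))
  rec <- pattern_sequence(rbind(c(0, 0), c(2, -1)))
  expect_equal(recall_mse(rec, truth), (1 + 4) / 2)
  expect_equal(recall_mse(rec, truth, skip_first = FALSE), 5 / 4)
})

test_that("capacity estimation is reproducible and honors its contract", {
  rec <- ahn_recipe(sep_polynomial(1))
  a <- estimate_pmax(rec, 25, n_trials = 3, seed = 7, max_length = 20)
  b <- estimate_pmax(rec, 25, n_trials = 3, seed = 7, max_length = 20)
  expect_identical(a$per_length_error, b$per_length_error)
  expect_gte(a$p_max, 1)                # a single transition always recalls

  vac <- estimate_pmax(rec, 10, threshold = 1, n_trials = 2, seed = 1,
                       max_length = 6)
  expect_equal(vac$p_max, 6L)
  expect_true(vac$censored)
})

test_that("capacity ordering: quadratic separation beats the classical network", {
  d1 <- estimate_pmax(ahn_recipe(sep_polynomial(1)), 50, n_trials = 5, seed = 2,
                      max_length = 60)
  d2 <- estimate_pmax(ahn_recipe(sep_polynomial(2)), 50, n_trials = 5, seed = 2,
                      max_length = 60)
  expect_gte(d2$p_max, d1$p_max)
})

test_that("primacy/recency scores summarize the positional profile", {
  flat <- diag(rep(0.7, 5))
  expect_equal(unname(primacy_recency_scores(flat)), c(0, 0))
  u <- diag(c(0.9, 0.5, 0.4, 0.5, 0.8))
  expect_equal(unname(primacy_recency_scores(u)), c(0.5, 0.4))
  expect_error(primacy_recency_scores(diag(2)), "at least 3")
})

test_that("a converged model recalls single-transition words perfectly", {
  sums <- serial_recall_experiment(8, lengths = 2L, n_repetitions = 10,
                                   seeds = 1, model_recipe = fast_two(8))
  expect_gte(sums[[1]]$accuracy, 0.9)
  expect_error(serial_recall_experiment(5, lengths = 7L, n_repetitions = 2,
                                        seeds = 1), "alphabet_size")
})

test_that("hidden_context_separation demands an aliased pair", {
  s <- generate_binary_sequence(6, 4, seed = 3)   # generic: no duplicates
  m <- tpc_two(6, hidden_dim = 4, seed = 1)
  expect_error(hidden_context_separation(m, s), "aliased pair")
})

test_that("aliasing driver returns the four MSE columns reproducibly", {
  fast_one <- tpc_recipe(n_epochs = 100, tol = 1e-6)
  a <- aliasing_experiment(lengths = 6L, n_features = 12L, seeds = 1,
                           single_recipe = fast_one, two_recipe = fast_two(24))
  expect_named(a, c("length", "seed", "single_plain", "single_aliased",
                    "two_plain", "two_aliased"))
  expect_true(all(is.finite(unlist(a[3:6]))))
  b <- aliasing_experiment(lengths = 6L, n_features = 12L, seeds = 1,
                           single_recipe = tpc_recipe(n_epochs = 100, tol = 1e-6),
                           two_recipe = fast_two(24))
  expect_equal(a, b)
  expect_error(aliasing_experiment(alias_fraction = 0), "alias_fraction")
})
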