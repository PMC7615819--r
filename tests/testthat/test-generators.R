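test_that("binary sequences are uniform, seeded and validated", {
  s <- generate_binary_sequence(1, 2, seed = 7)
  expect_true(all(as.matrix(s) %in% c(-1, 1)))

  big <- generate_binary_sequence(100, 50, seed = 0)
  expect_lt(abs(mean(as.matrix(big))), 4 / sqrt(5000))

  expect_identical(as.matrix(generate_binary_sequence(20, 9, seed = 3)),
                   as.matrix(generate_binary_sequence(20, 9, seed = 3)))
  expect_error(generate_binary_sequence(0, 5, seed = 1), "positive integer")
  expect_error(generate_binary_sequence(5, -1, seed = 1), "positive integer")
})

test_that("correlated binary sequences hit the requested feature correlation", {
  # empirical mean off-diagonal correlation tracks b
  off_diag_corr <- function(b, len = 1000, seed = 11) {
    X <- as.matrix(generate_correlated_binary_sequence(40, len, b, seed))
    C <- cor(X)
    mean(C[upper.tri(C)])
  }
  expect_lt(abs(off_diag_corr(0)), 0.05)
  for (b in c(0.2, 0.4, 0.6, 0.8))
    expect_lt(abs(off_diag_corr(b) - b), 0.05)

  X25 <- as.matrix(generate_correlated_binary_sequence(100, 2000, 0.25, seed = 1))
  C25 <- cor(X25)
  expect_lt(abs(mean(C25[upper.tri(C25)]) - 0.25), 0.03)

  # marginals stay uniform
  expect_lt(max(abs(colMeans(X25))), 0.1)

  Chigh <- cor(as.matrix(generate_correlated_binary_sequence(30, 1500, 0.9, seed = 2)))
  expect_true(all(Chigh[upper.tri(Chigh)] > 0))

  expect_error(generate_correlated_binary_sequence(10, 10, 1, seed = 1), "\\[0, 1\\)")
  expect_error(generate_correlated_binary_sequence(10, 10, -0.1, seed = 1), "\\[0, 1\\)")
})

test_that("one-hot words are permutations of basis vectors", {
  w <- generate_onehot_word(3, 3, seed = 5, distinct = TRUE)
  M <- as.matrix(w)
  expect_equal(colSums(M), rep(1, 3))   # each letter used exactly once
  expect_equal(rowSums(M), rep(1, 3))

  expect_equal(as.matrix(generate_onehot_word(1, 1, seed = 1)),
               matrix(1, 1, 1), ignore_attr = TRUE)

  w2 <- generate_onehot_word(10, 4, seed = 9, distinct = TRUE)
  expect_equal(sum(colSums(as.matrix(w2)) == 1), 4)
  expect_error(generate_onehot_word(3, 4, seed = 1, distinct = TRUE),
               "alphabet_size")
})

test_that("the moving bar is a 5x5 movie aliased at steps 2 and 4", {
  bar <- generate_moving_bar()
  X <- as.matrix(bar)
  expect_equal(attr(bar, "frame_shape"), c(5L, 5L))
  expect_true(all(X %in% c(0, 1)))
  expect_equal(X[2, ], X[4, ])
  # down-then-up over rows 1,2,3,2,1 also returns to the start, so the
  # identical pairs are exactly (2,4) and (1,5)
  pairs <- combn(5, 2)
  same <- apply(pairs, 2, function(p) identical(X[p[1], ], X[p[2], ]))
  expect_equal(which(same), which(apply(pairs, 2, function(p)
    all(p == c(1, 5)) || all(p == c(2, 4)))))
})

test_that("alias_sequence replaces exactly ceil(fraction * length) positions", {
  s <- generate_binary_sequence(12, 10, seed = 4)
  rep_pat <- rep(1, 12)
  a <- alias_sequence(s, 0.2, rep_pat, seed = 8)
  changed <- which(rowSums(as.matrix(a) != as.matrix(s)) > 0)
  expect_length(attr(a, "aliased_steps"), 2L)
  expect_true(all(changed %in% attr(a, "aliased_steps")))
  expect_true(all(as.matrix(a)[attr(a, "aliased_steps"), ] == 1))
  # untouched rows are bitwise identical
  keep <- setdiff(1:10, attr(a, "aliased_steps"))
  expect_identical(as.matrix(a)[keep, ], as.matrix(s)[keep, ])

  s3 <- generate_binary_sequence(4, 3, seed = 1)
  expect_length(attr(alias_sequence(s3, 0.2, rep(1, 4), seed = 1),
                     "aliased_steps"), 1L)  # ceil(0.6) = 1
  expect_error(alias_sequence(s, 0, rep_pat, seed = 1), "\\(0, 1\\)")
  expect_error(alias_sequence(s, 1, rep_pat, seed = 1), "\\(0, 1\\)")
  expect_error(alias_sequence(s, 0.5, rep(1, 3), seed = 1), "dimension")
})

test_that("rotating-shape movies follow the requested rotation", {
  still <- generate_rotating_shape_set(2, frame_side = 12, n_steps = 4,
                                       angle_per_step = 0, seed = 3)
  for (s in still)
    expect_lt(max(abs(sweep(as.matrix(s), 2, as.matrix(s)[1, ]))), 1e-12)

  # a full turn lands near the first frame (tolerance for resampling)
  full <- generate_rotating_shape_set(2, frame_side = 16, n_steps = 5,
                                      angle_per_step = 90, seed = 5)[[1]]
  X <- as.matrix(full)
  expect_lt(mean((X[5, ] - X[1, ])^2), 1e-3)

  train <- generate_rotating_shape_set(3, seed = 7, shape_family = "train")
  held <- generate_rotating_shape_set(3, seed = 7, shape_family = "heldout")
  expect_true(all(vapply(c(train, held), function(s)
    all(as.matrix(s) >= 0 & as.matrix(s) <= 1), logical(1))))
  # same seed, different family => different base shapes
  expect_gt(mean((as.matrix(train[[1]]) - as.matrix(held[[1]]))^2), 1e-3)

  again <- generate_rotating_shape_set(3, seed = 7, shape_family = "train")
  expect_identical(lapply(train, as.matrix), lapply(again, as.matrix))
})

test_that("pattern_sequence validates domains and centering removes the mean", {
  expect_error(pattern_sequence(matrix(c(0, 1), 1), domain = "binary"), "-1")
  expect_error(pattern_sequence(matrix(c(1, 1), 1), domain = "onehot"), "exactly one")
  expect_error(pattern_sequence(matrix(0, 2, 4), domain = "image"), "frame_shape")
  sc <- center_sequence(generate_binary_sequence(6, 8, seed = 2))
  expect_lt(max(abs(colMeans(as.matrix(sc)))), 1e-14)
})
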