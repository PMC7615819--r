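#' Model recipes for the experiment drivers
#'
#' A recipe is a function `(seq, mode)` that builds/trains a fresh model on
#' `seq` and returns its `recall_result`. Recipes keep the experiment
#' drivers model-agnostic while guaranteeing a fresh model per trial.
#'
#' @param nonlinearity,lr_weights,lr_inference,n_inference_steps,inference_tol,hidden_init_scale
#'   model hyperparameters; see [tpc_single()] and [tpc_two()].
#' @param n_epochs,tol training schedule; see [tpc_train()].
#' @param hidden_dim hidden layer width of the two-layer recipe.
#' @param seed base seed for the two-layer weight initialization (offset by
#'   a per-call counter so repeated trials differ deterministically).
#' @param separation separation spec for the Hopfield recipe.
#' @return A function `(seq, mode)` returning a `recall_result`.
#' @export
tpc_recipe <- function(nonlinearity = "identity", lr_weights = 1e-2,
                       n_epochs = 100L, tol = 1e-4, lr_inference = 0.1,
                       n_inference_steps = 200L, inference_tol = 1e-6) {
  function(seq, mode) {
    m <- tpc_single(ncol(seq), nonlinearity = nonlinearity,
                    lr_weights = lr_weights, lr_inference = lr_inference,
                    n_inference_steps = n_inference_steps,
                    inference_tol = inference_tol)
    m <- tpc_train(m, seq, n_epochs = n_epochs, tol = tol)
    tpc_recall(m, seq, mode = mode)
  }
}

#' @rdname tpc_recipe
#' @export
tpc_two_recipe <- function(hidden_dim, nonlinearity = "tanh",
                           lr_weights = 1e-3, n_epochs = 200L, tol = 1e-5,
                           lr_inference = 0.1, n_inference_steps = 200L,
                           inference_tol = 1e-6, hidden_init_scale = 0.1,
                           seed = 0L) {
  counter <- 0L
  function(seq, mode) {
    counter <<- counter + 1L
    m <- tpc_two(ncol(seq), hidden_dim = hidden_dim,
                 nonlinearity = nonlinearity, lr_weights = lr_weights,
                 lr_inference = lr_inference,
                 n_inference_steps = n_inference_steps,
                 inference_tol = inference_tol,
                 hidden_init_scale = hidden_init_scale,
                 seed = seed + counter)
    m <- tpc_train(m, seq, n_epochs = n_epochs, tol = tol)
    tpc_recall(m, seq, mode = mode)
  }
}

#' @rdname tpc_recipe
#' @export
ahn_recipe <- function(separation = sep_identity()) {
  function(seq, mode) {
    ahn_recall(ahn(seq, separation), seq, mode = mode)
  }
}

#' Sequence generators for the capacity experiments
#'
#' Returns a function `(n_features, length, seed)` producing a
#' [pattern_sequence()]; `b = 0` gives uncorrelated binary patterns,
#' `b > 0` binary patterns with pairwise feature correlation `b`.
#'
#' @param b correlation level in `[0, 1)`.
#' @return A generator function for [estimate_pmax()].
#' @export
binary_generator <- function(b = 0) {
  force(b)
  if (b == 0) {
    function(n_features, length, seed)
      generate_binary_sequence(n_features, length, seed)
  } else {
    function(n_features, length, seed)
      generate_correlated_binary_sequence(n_features, length, b, seed)
  }
}

#' Sequence capacity of a memory model
#'
#' Estimates `P_max`, the maximum number of transitions a model can
#' memorize such that the probability of incorrectly recalled bits stays at
#' or below `threshold`. Lengths are scanned incrementally (`P = 1, 2,
#' ...`), each length averaging the bit-error rate of `n_trials` fresh
#' (model, sequence) pairs; the scan stops early after `fail_streak`
#' consecutive failing lengths. Bit error is not guaranteed monotone in `P`
#' at small trial counts, so per-length errors are reported rather than
#' assumed monotone.
#'
#' @param model_factory a recipe, e.g. [tpc_recipe()] or [ahn_recipe()].
#' @param n_features pattern dimension `N`.
#' @param generator sequence generator, e.g. [binary_generator()].
#' @param threshold bit-error probability bound defining capacity
#'   (default 0.01).
#' @param n_trials fresh trials per length (default 10).
#' @param mode recall protocol; the capacity comparisons use `"online"`.
#' @param max_length largest length scanned (default `2 * n_features`).
#' @param seed integer seed; the whole scan is reproducible.
#' @param fail_streak consecutive failing lengths that end the scan.
#' @return A `capacity_result`: `n_features`, `p_max`, `threshold`,
#'   `n_trials`, `per_length_error` (named vector), and `censored` (`TRUE`
#'   if the scan hit `max_length` while still passing).
#' @export
estimate_pmax <- function(model_factory, n_features, generator = binary_generator(),
                          threshold = 0.01, n_trials = 10L,
                          mode = c("online", "offline"),
                          max_length = 2L * n_features, seed = 0L,
                          fail_streak = 3L) {
  mode <- match.arg(mode)
  stopifnot(threshold > 0, threshold <= 1)
  n_trials <- check_count(n_trials, "n_trials")
  p_max <- 0L
  errs <- numeric(0)
  streak <- 0L
  last_passed <- FALSE
  for (P in seq_len(max_length)) {
    ber <- vapply(seq_len(n_trials), function(tr) {
      s <- as.integer((abs(seed) + 7919 * P + 104729 * tr) %% 2147483647L)
      seq <- generator(n_features, P + 1L, s)
      bit_error_rate(model_factory(seq, mode), seq)
    }, numeric(1))
    m <- mean(ber)
    errs[as.character(P)] <- m
    if (m <= threshold) {
      p_max <- P
      streak <- 0L
      last_passed <- TRUE
    } else {
      streak <- streak + 1L
      last_passed <- FALSE
      if (streak >= fail_streak) break
    }
  }
  structure(list(n_features = n_features, p_max = p_max,
                 threshold = threshold, n_trials = n_trials,
                 per_length_error = errs,
                 censored = last_passed && P == max_length),
            class = "capacity_result")
}

#' @export
print.capacity_result <- function(x, ...) {
  cat(sprintf("<capacity_result> N = %d: P_max = %d (bit-error <= %g, %d trials%s)\n",
              x$n_features, x$p_max, x$threshold, x$n_trials,
              if (x$censored) ", censored" else ""))
  invisible(x)
}

decode_letters <- function(R) apply(R, 1L, which.max)  # ties -> lowest index

#' Serial recall of one-hot letter words
#'
#' Trains a fresh two-layer tPC on each "word" (a sequence of one-hot
#' letter vectors), recalls it offline cued by the first letter, and
#' decodes every recalled vector to a letter by argmax. Accuracy is the
#' proportion of perfectly recalled words; the positional matrix entry
#' `(i, j)` is the frequency (over repetitions) with which the item shown
#' at scored position `i` is recalled at scored position `j`. The cued
#' first position is not scored.
#'
#' @param alphabet_size one-hot dimension (number of letters).
#' @param lengths word lengths to test (letters per word, including the
#'   cue); each must be at most `alphabet_size` since letters are distinct.
#' @param n_repetitions words per (length, seed) cell.
#' @param seeds integer seeds; one summary per (length, seed).
#' @param model_recipe a two-layer recipe. The default uses a hidden layer
#'   of half the alphabet size and a short training schedule — a
#'   capacity-limited regime in which the model operates at
#'   human-comparable accuracy, so positional error structure is visible
#'   rather than saturated at ceiling.
#' @return A list of `serial_recall_summary` objects (fields
#'   `sequence_length`, `accuracy`, `positional_matrix`, `n_repetitions`,
#'   `seed`).
#' @export
serial_recall_experiment <- function(alphabet_size = 26L,
                                     lengths = c(3L, 5L, 7L, 9L, 11L),
                                     n_repetitions = 100L, seeds = 1:3,
                                     model_recipe = NULL) {
  alphabet_size <- check_count(alphabet_size, "alphabet_size")
  if (any(lengths > alphabet_size))
    stop("lengths must not exceed alphabet_size (letters are distinct)")
  if (is.null(model_recipe))
    model_recipe <- tpc_two_recipe(hidden_dim = max(4L, alphabet_size %/% 2L),
                                   lr_weights = 3e-3, n_epochs = 50L,
                                   tol = 0, n_inference_steps = 100L)
  out <- list()
  for (L in lengths) for (sd in seeds) {
    n_scored <- L - 1L
    pos <- matrix(0, n_scored, n_scored)
    n_perfect <- 0L
    for (rep in seq_len(n_repetitions)) {
      ws <- as.integer((abs(sd) + 7919 * L + 104729 * rep) %% 2147483647L)
      word <- generate_onehot_word(alphabet_size, L, seed = ws, distinct = TRUE)
      res <- model_recipe(word, "offline")
      shown <- attr(word, "letters")[-1L]
      rec <- decode_letters(as.matrix(res$recalled)[-1L, , drop = FALSE])
      if (all(rec == shown)) n_perfect <- n_perfect + 1L
      pos <- pos + outer(shown, rec, `==`)
    }
    out[[length(out) + 1L]] <- structure(
      list(sequence_length = L, accuracy = n_perfect / n_repetitions,
           positional_matrix = pos / n_repetitions,
           n_repetitions = n_repetitions, seed = sd),
      class = "serial_recall_summary")
  }
  out
}

#' @export
print.serial_recall_summary <- function(x, ...) {
  cat(sprintf("<serial_recall_summary> length %d, seed %d: accuracy %.3f over %d words\n",
              x$sequence_length, x$seed, x$accuracy, x$n_repetitions))
  invisible(x)
}

#' Primacy and recency scores of a serial-recall summary
#'
#' Positional correct-recall frequencies are the diagonal of the positional
#' matrix. Primacy is the first scored position's frequency minus the
#' minimum over the middle positions; recency is the last scored position's
#' frequency minus the same minimum. A flat positional profile scores
#' `(0, 0)`.
#'
#' @param summary a `serial_recall_summary` (or an averaged positional
#'   matrix).
#' @return Named numeric vector `c(primacy = , recency = )`.
#' @export
primacy_recency_scores <- function(summary) {
  M <- if (inherits(summary, "serial_recall_summary"))
    summary$positional_matrix else as.matrix(summary)
  d <- diag(M)
  if (length(d) < 3L)
    stop("primacy/recency need at least 3 scored positions")
  mid <- d[-c(1L, length(d))]
  c(primacy = d[1L] - min(mid), recency = d[length(d)] - min(mid))
}

#' Effect of aliased inputs on single- versus two-layer recall
#'
#' For each length and seed, memorizes a random binary sequence and an
#' aliased copy (a fraction of positions replaced by one repeated random
#' pattern) with fresh single-layer and two-layer tPC models, and measures
#' the online-recall MSE in all four conditions. Aliased positions make
#' the correct successor ambiguous for a memory without context: the
#' single-layer model can only recall the average of the aliased frame's
#' successors, while the two-layer model's hidden state disambiguates
#' them.
#'
#' @param lengths sequence lengths (number of patterns) to test.
#' @param alias_fraction fraction of positions replaced, in `(0, 1)`.
#' @param n_features pattern dimension.
#' @param seeds integer seeds (one row per length x seed).
#' @param single_recipe,two_recipe model recipes; defaults are a linear
#'   single-layer recipe and a tanh two-layer recipe with hidden width
#'   `2 * n_features`.
#' @param mode recall protocol (default `"online"`).
#' @return A data frame with columns `length`, `seed`, `single_plain`,
#'   `single_aliased`, `two_plain`, `two_aliased`.
#' @export
aliasing_experiment <- function(lengths = c(5L, 10L, 15L), alias_fraction = 0.2,
                                n_features = 50L, seeds = 1:5,
                                single_recipe = NULL, two_recipe = NULL,
                                mode = "online") {
  if (alias_fraction <= 0 || alias_fraction >= 1)
    stop("`alias_fraction` must lie in (0, 1)")
  if (is.null(single_recipe)) single_recipe <- tpc_recipe(n_epochs = 500L, tol = 1e-8)
  if (is.null(two_recipe))
    two_recipe <- tpc_two_recipe(hidden_dim = 2L * n_features, lr_weights = 3e-3,
                                 n_epochs = 200L, tol = 0,
                                 n_inference_steps = 100L)
  rows <- list()
  for (L in lengths) for (sd in seeds) {
    s <- as.integer((abs(sd) + 7919 * L) %% 2147483647L)
    plain <- generate_binary_sequence(n_features, L, seed = s)
    rep_pat <- as.numeric(generate_binary_sequence(n_features, 2L, seed = s + 1L)[1L, ])
    aliased <- alias_sequence(plain, alias_fraction, rep_pat, seed = s + 2L)
    mse <- function(recipe, seq) recall_mse(recipe(seq, mode), seq)
    rows[[length(rows) + 1L]] <- data.frame(
      length = L, seed = sd,
      single_plain = mse(single_recipe, plain),
      single_aliased = mse(single_recipe, aliased),
      two_plain = mse(two_recipe, plain),
      two_aliased = mse(two_recipe, aliased))
  }
  do.call(rbind, rows)
}

#' Hidden-state separation at aliased inputs
#'
#' Runs offline recall of `seq` with a trained two-layer model and returns
#' the minimum, over all pairs of time steps with identical sensory
#' patterns, of one minus the cosine similarity between the converged
#' hidden states at those steps. A value above zero means the model
#' represents the aliased inputs differentially in its hidden layer —
#' the context signal that lets it recall differing successors. Hidden
#' states with norm below `norm_floor` are treated as degenerate and score
#' 0.
#'
#' @param model a trained [tpc_two()] model.
#' @param seq a [pattern_sequence()] containing at least one aliased pair.
#' @param norm_floor guard against near-zero hidden states.
#' @return A scalar in `[0, 2]`.
#' @export
hidden_context_separation <- function(model, seq, norm_floor = 1e-6) {
  stopifnot(inherits(model, "tpc_two"))
  X <- as.matrix(seq)
  pairs <- which(as.matrix(stats::dist(X)) < 1e-12 &
                   upper.tri(matrix(0, nrow(X), nrow(X))), arr.ind = TRUE)
  if (nrow(pairs) == 0L)
    stop("sequence contains no aliased pair (no two identical patterns)")
  res <- tpc_recall(model, seq, mode = "offline")
  Z <- res$hidden_trajectory
  seps <- apply(pairs, 1L, function(ij) {
    zi <- Z[ij[1L], ]; zj <- Z[ij[2L], ]
    ni <- sqrt(sum(zi^2)); nj <- sqrt(sum(zj^2))
    if (ni < norm_floor || nj < norm_floor) return(0)
    1 - sum(zi * zj) / (ni * nj)
  })
  min(seps)
}

#' Generalization of learned rotational dynamics
#'
#' Trains one two-layer tPC per (training size, seed) on that many
#' rotating-shape movies from the `train` family and measures offline
#' recall MSE cued by the first frame on (a) a sample of seen training
#' movies and (b) fresh movies from the disjoint `heldout` shape family.
#' Falling heldout MSE with growing training size indicates the model has
#' extracted the shared rotational dynamics rather than memorizing
#' individual movies.
#'
#' @param training_sizes numbers of training movies.
#' @param frame_side,n_steps,angle movie geometry; see
#'   [generate_rotating_shape_set()].
#' @param seeds integer seeds (one model per size x seed).
#' @param hidden_dim hidden width (default: one unit per pixel).
#' @param nonlinearity the rotation is a fixed linear map of the frame, so
#'   the default is the identity; `"tanh"` is available.
#' @param lr_weights,n_epochs training schedule.
#' @param n_eval movies scored per evaluation set.
#' @return A data frame with columns `training_size`, `seed`, `seen_mse`,
#'   `heldout_mse`.
#' @export
generalization_experiment <- function(training_sizes = c(16L, 64L, 256L),
                                      frame_side = 16L, n_steps = 8L,
                                      angle = 45, seeds = 1:3,
                                      hidden_dim = frame_side^2,
                                      nonlinearity = "identity",
                                      lr_weights = 5e-3, n_epochs = 5L,
                                      n_eval = 8L) {
  rows <- list()
  for (size in training_sizes) for (sd in seeds) {
    s <- as.integer((abs(sd) * 7919) %% 2147483647L)
    train_set <- generate_rotating_shape_set(size, frame_side, n_steps, angle,
                                             shape_family = "train", seed = s)
    heldout <- generate_rotating_shape_set(n_eval, frame_side, n_steps, angle,
                                           shape_family = "heldout",
                                           seed = s + 1L)
    model <- tpc_two(frame_side^2, hidden_dim = hidden_dim,
                     nonlinearity = nonlinearity, lr_weights = lr_weights,
                     seed = s)
    model <- tpc_train(model, train_set, n_epochs = n_epochs, tol = 1e-7)
    score <- function(seqs) mean(vapply(seqs, function(q)
      recall_mse(tpc_recall(model, q, mode = "offline"), q), numeric(1)))
    seen <- train_set[seq_len(min(size, n_eval))]
    rows[[length(rows) + 1L]] <- data.frame(
      training_size = size, seed = sd,
      seen_mse = score(seen), heldout_mse = score(heldout))
  }
  do.call(rbind, rows)
}
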