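#' Single-layer temporal predictive coding network
#'
#' A network of `N` value neurons and `N` error neurons that learns the
#' transition between consecutive patterns of a sequence. At step `mu` the
#' error neurons carry `eps = x^mu - W f(x^{mu-1})` and the single weight
#' matrix `W` is updated by the local, Hebbian rule `dW = lr * eps f(x)^T`.
#' During recall the value neurons relax to minimize the squared prediction
#' error given a query; with `nonlinearity = "identity"` the converged
#' retrieval is `W f(q)`.
#'
#' @param n_features pattern dimension `N`.
#' @param nonlinearity `"identity"` (default; the linear regime in which the
#'   whitening equivalence holds) or `"tanh"`.
#' @param lr_weights learning rate for the weight updates.
#' @param lr_inference Euler step size of the inference dynamics.
#' @param n_inference_steps maximum relaxation iterations per recalled step.
#' @param inference_tol stop relaxation when the update norm falls below this.
#' @return An object of class `tpc_single` with an all-zero weight matrix
#'   (zero initialization is a valid gradient-descent start for the convex
#'   single-layer objective and makes the least-squares limit clean).
#' @seealso [tpc_train()], [tpc_recall()], [closed_form_weights()]
#' @export
tpc_single <- function(n_features, nonlinearity = c("identity", "tanh"),
                       lr_weights = 1e-2, lr_inference = 0.1,
                       n_inference_steps = 200L, inference_tol = 1e-6) {
  n_features <- check_count(n_features, "n_features")
  stopifnot(lr_weights > 0, lr_inference > 0, inference_tol > 0)
  structure(list(
    W = matrix(0, n_features, n_features),
    n_features = n_features,
    nonlinearity = match.arg(nonlinearity),
    lr_weights = lr_weights,
    lr_inference = lr_inference,
    n_inference_steps = check_count(n_inference_steps, "n_inference_steps"),
    inference_tol = inference_tol,
    trained = FALSE
  ), class = "tpc_single")
}

#' Two-layer temporal predictive coding network
#'
#' Adds a layer of hidden value neurons `z` above the sensory layer. The
#' hidden layer predicts its own next state through `W_H` (temporal
#' prediction) and the current sensory input through `W_F` (top-down
#' prediction); learning and inference jointly minimize
#' `|z - W_H f(zhat_prev)|^2 + |x - W_F f(z)|^2`. The hidden state carries
#' temporal context between steps, which lets the model disambiguate
#' aliased (repeating) inputs; it is reset to a seeded random state at the
#' start of recall, so memories can only be read out through the weights.
#'
#' @inheritParams tpc_single
#' @param hidden_dim number of hidden value neurons `Nz`.
#' @param nonlinearity `"tanh"` (default) or `"identity"`.
#' @param lr_weights learning rate for both weight matrices.
#' @param hidden_init_scale standard deviation of the random hidden reset at
#'   recall start.
#' @param inference_init `"recognition"` (default) starts each hidden
#'   relaxation from the feedforward guess `W_F^T x`; `"prior"` starts from
#'   the temporal prediction `W_H f(zhat_prev)`. Recognition init avoids the
#'   early-training degeneracy where near-zero hidden states give no
#'   learning signal.
#' @param optimizer `"adam"` (default) or `"sgd"` for the weight updates.
#'   The prediction-error gradients are identical either way; Adam rescales
#'   each synapse's step adaptively, which the non-convex two-layer
#'   objective needs to reach good optima at desk scale.
#' @param seed seed for weight initialization and hidden resets.
#' @return An object of class `tpc_two`. Weights are initialized
#'   `N(0, 0.05/sqrt(fan_in))` — the non-convex two-layer objective needs
#'   symmetry breaking.
#' @export
tpc_two <- function(n_features, hidden_dim, nonlinearity = c("tanh", "identity"),
                    lr_weights = 1e-3, lr_inference = 0.1,
                    n_inference_steps = 200L, inference_tol = 1e-6,
                    hidden_init_scale = 0.1,
                    inference_init = c("recognition", "prior"),
                    optimizer = c("adam", "sgd"), seed = 0L) {
  n_features <- check_count(n_features, "n_features")
  hidden_dim <- check_count(hidden_dim, "hidden_dim")
  stopifnot(lr_weights > 0, lr_inference > 0, inference_tol > 0,
            hidden_init_scale > 0)
  init <- withr::with_seed(seed, list(
    WH = matrix(stats::rnorm(hidden_dim^2, sd = 0.05 / sqrt(hidden_dim)),
                hidden_dim, hidden_dim),
    WF = matrix(stats::rnorm(n_features * hidden_dim, sd = 0.05 / sqrt(hidden_dim)),
                n_features, hidden_dim)
  ))
  structure(list(
    WH = init$WH, WF = init$WF,
    n_features = n_features, hidden_dim = hidden_dim,
    nonlinearity = match.arg(nonlinearity),
    lr_weights = lr_weights,
    lr_inference = lr_inference,
    n_inference_steps = check_count(n_inference_steps, "n_inference_steps"),
    inference_tol = inference_tol,
    hidden_init_scale = hidden_init_scale,
    inference_init = match.arg(inference_init),
    optimizer = match.arg(optimizer),
    seed = as.integer(seed),
    trained = FALSE
  ), class = "tpc_two")
}

#' @export
print.tpc_single <- function(x, ...) {
  cat(sprintf("<tpc_single> N = %d, f = %s, %strained\n",
              x$n_features, x$nonlinearity, if (x$trained) "" else "un"))
  invisible(x)
}

#' @export
print.tpc_two <- function(x, ...) {
  cat(sprintf("<tpc_two> N = %d, Nz = %d, f = %s, %strained\n",
              x$n_features, x$hidden_dim, x$nonlinearity,
              if (x$trained) "" else "un"))
  invisible(x)
}

seq_matrix <- function(seq, n_features) {
  stopifnot(inherits(seq, "pattern_sequence"))
  if (ncol(seq) != n_features)
    stop("sequence feature dimension does not match the model")
  if (nrow(seq) < 2L) stop("training needs a sequence with at least 2 patterns")
  as.matrix(seq)
}

#' Memorize sequences by minimizing temporal prediction errors
#'
#' Presents the sequence(s) repeatedly, updating the weights once per time
#' step per presentation, until the relative weight change per epoch drops
#' below `tol` or `n_epochs` is reached. For the two-layer model each time
#' step first relaxes the hidden state to convergence before the Hebbian
#' weight updates are applied; the converged hidden state is carried to the
#' next step and reset between sequences.
#'
#' @param object a [tpc_single()] or [tpc_two()] model.
#' @param seqs a [pattern_sequence()]; the two-layer model also accepts a
#'   list of sequences sharing one feature dimension.
#' @param n_epochs maximum number of full-sequence presentations.
#' @param tol relative Frobenius weight-change threshold for early stopping.
#' @param n_starts two-layer only: number of deterministic random restarts.
#'   The non-convex two-layer objective has poor local optima (e.g. a
#'   collapsed context for aliased inputs); each restart re-draws the
#'   weight initialization from `seed + start - 1` and the fit with the
#'   lowest final memorization energy is kept.
#' @param ... unused.
#' @return The trained model, with `$epochs_run` recording how many epochs
#'   actually ran. Exploding weights (Frobenius norm above `1e6`) raise an
#'   error naming the offending learning rate.
#' @export
tpc_train <- function(object, seqs, n_epochs = 200L, tol = 1e-5, ...) {
  UseMethod("tpc_train")
}

#' @rdname tpc_train
#' @export
tpc_train.tpc_single <- function(object, seqs, n_epochs = 200L, tol = 1e-5, ...) {
  X <- seq_matrix(seqs, object$n_features)
  fit <- tpc_train_single_cpp(X, object$W, object$lr_weights,
                              check_count(n_epochs, "n_epochs"), tol,
                              object$nonlinearity == "tanh")
  object$W <- fit$W
  object$epochs_run <- fit$epochs_run
  object$trained <- TRUE
  object
}

#' @rdname tpc_train
#' @export
tpc_train.tpc_two <- function(object, seqs, n_epochs = 200L, tol = 1e-5,
                              n_starts = 1L, ...) {
  if (inherits(seqs, "pattern_sequence")) seqs <- list(seqs)
  Xs <- lapply(seqs, seq_matrix, n_features = object$n_features)
  # the chain starts from the same fixed reset state (zeros) that recall
  # uses, so the cue's inferred context matches between the two phases
  Z0 <- matrix(0, object$hidden_dim, length(Xs))
  best <- NULL
  for (start in seq_len(check_count(n_starts, "n_starts"))) {
    init <- if (start == 1L) list(WH = object$WH, WF = object$WF) else
      withr::with_seed(object$seed + start - 1L, list(
        WH = matrix(stats::rnorm(object$hidden_dim^2,
                                 sd = 0.05 / sqrt(object$hidden_dim)),
                    object$hidden_dim, object$hidden_dim),
        WF = matrix(stats::rnorm(object$n_features * object$hidden_dim,
                                 sd = 0.05 / sqrt(object$hidden_dim)),
                    object$n_features, object$hidden_dim)))
    fit <- tpc_train_two_cpp(Xs, init$WH, init$WF, object$lr_weights,
                             check_count(n_epochs, "n_epochs"), tol,
                             object$lr_inference, object$n_inference_steps,
                             object$inference_tol,
                             object$nonlinearity == "tanh",
                             object$optimizer == "adam",
                             object$inference_init == "recognition", Z0)
    if (is.null(best) || fit$final_energy < best$final_energy) best <- fit
  }
  object$WH <- best$WH
  object$WF <- best$WF
  object$epochs_run <- best$epochs_run
  object$final_energy <- best$final_energy
  object$trained <- TRUE
  object
}

recall_result <- function(recalled, mode, per_step_energy,
                          hidden_trajectory = NULL, inference_traces = NULL) {
  structure(list(recalled = recalled, mode = mode,
                 per_step_energy = per_step_energy,
                 hidden_trajectory = hidden_trajectory,
                 inference_traces = inference_traces),
            class = "recall_result")
}

#' @export
print.recall_result <- function(x, ...) {
  cat(sprintf("<recall_result> %s recall, %d steps x %d features%s\n",
              x$mode, nrow(x$recalled), ncol(x$recalled),
              if (is.null(x$hidden_trajectory)) "" else
                sprintf(", hidden dim %d", ncol(x$hidden_trajectory))))
  invisible(x)
}

#' Recall a memorized sequence
#'
#' Cues the model with the first pattern and recalls the rest step by step
#' through the iterative inference dynamics. In `"online"` mode the query at
#' each step is the ground-truth previous pattern, so every step has
#' real-time feedback; in `"offline"` mode only the first pattern is given
#' and each query is the model's own previous recall, so errors can
#' accumulate. For the two-layer model the hidden state is re-initialized
#' from a seeded Gaussian before recall; offline recall carries the
#' converged hidden estimate directly to the next step, while online recall
#' re-infers it from the ground-truth query.
#'
#' @param object a trained [tpc_single()] or [tpc_two()] model.
#' @param seq the queried [pattern_sequence()] (ground truth; only its first
#'   pattern is used in offline mode).
#' @param mode `"online"` or `"offline"`.
#' @param trace_energy if `TRUE`, keep the per-iteration energy trajectory
#'   of every relaxation (for diagnostics).
#' @param ... unused.
#' @return A `recall_result` with `$recalled` (same shape as `seq`; the
#'   first row is the cue), `$per_step_energy` (converged energy per step)
#'   and, for the two-layer model, `$hidden_trajectory` (one converged
#'   hidden state per step).
#' @export
tpc_recall <- function(object, seq, mode = c("online", "offline"),
                       trace_energy = FALSE, ...) {
  UseMethod("tpc_recall")
}

#' @rdname tpc_recall
#' @export
tpc_recall.tpc_single <- function(object, seq, mode = c("online", "offline"),
                                  trace_energy = FALSE, ...) {
  mode <- match.arg(mode)
  X <- seq_matrix(seq, object$n_features)
  if (all(object$W == 0))
    warning("recalling with an untrained single-layer model: W is all zero")
  out <- tpc_recall_single_cpp(X, object$W, object$lr_inference,
                               object$n_inference_steps, object$inference_tol,
                               object$nonlinearity == "tanh",
                               mode == "online", trace_energy)
  rec <- pattern_sequence(out$Xhat, domain = "real",
                          frame_shape = attr(seq, "frame_shape"))
  recall_result(rec, mode, as.numeric(out$energy),
                inference_traces = if (trace_energy) out$traces)
}

#' @rdname tpc_recall
#' @export
tpc_recall.tpc_two <- function(object, seq, mode = c("online", "offline"),
                               trace_energy = FALSE,
                               reset = c("zero", "gaussian"), ...) {
  mode <- match.arg(mode)
  reset <- match.arg(reset)
  X <- seq_matrix(seq, object$n_features)
  z0 <- if (reset == "zero") numeric(object$hidden_dim) else
    withr::with_seed(object$seed + 1L,
      stats::rnorm(object$hidden_dim, sd = object$hidden_init_scale))
  out <- tpc_recall_two_cpp(X, object$WH, object$WF, z0, object$lr_inference,
                            object$n_inference_steps, object$inference_tol,
                            object$nonlinearity == "tanh",
                            mode == "online",
                            object$inference_init == "recognition",
                            trace_energy)
  rec <- pattern_sequence(out$Xhat, domain = "real",
                          frame_shape = attr(seq, "frame_shape"))
  recall_result(rec, mode, as.numeric(out$energy),
                hidden_trajectory = out$Z,
                inference_traces = if (trace_energy) out$traces)
}
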