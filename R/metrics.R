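as_recalled_matrix <- function(x) {
  if (inherits(x, "recall_result")) x <- x$recalled
  stopifnot(inherits(x, "pattern_sequence"))
  as.matrix(x)
}

scored_steps <- function(L, skip_first) if (skip_first) seq.int(2L, L) else seq_len(L)

#' Bit-error probability of a binary recall
#'
#' Fraction of sign-mismatched entries between the (signed) recalled
#' sequence and the binary ground truth, over the scored steps. The first
#' step is the cue and is not scored by default. Recalled values are signed
#' before comparison with `sgn(0) = +1`.
#'
#' @param recalled a `recall_result` or [pattern_sequence()].
#' @param truth the ground-truth binary [pattern_sequence()].
#' @param skip_first exclude the cued first step from scoring (default).
#' @return A scalar in `[0, 1]`.
#' @export
bit_error_rate <- function(recalled, truth, skip_first = TRUE) {
  R <- as_recalled_matrix(recalled)
  X <- as_recalled_matrix(truth)
  if (!all(dim(R) == dim(X))) stop("recalled and truth must have the same shape")
  if (!all(X %in% c(-1, 1))) stop("ground truth must be binary (+/- 1)")
  s <- scored_steps(nrow(X), skip_first)
  mean(sign_pm(R[s, , drop = FALSE]) != X[s, , drop = FALSE])
}

#' Mean squared recall error
#'
#' Mean of squared element differences between recall and ground truth over
#' the scored steps (the cued first step is excluded by default).
#'
#' @inheritParams bit_error_rate
#' @return A non-negative scalar.
#' @export
recall_mse <- function(recalled, truth, skip_first = TRUE) {
  R <- as_recalled_matrix(recalled)
  X <- as_recalled_matrix(truth)
  if (!all(dim(R) == dim(X))) stop("recalled and truth must have the same shape")
  s <- scored_steps(nrow(X), skip_first)
  mean((R[s, , drop = FALSE] - X[s, , drop = FALSE])^2)
}
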