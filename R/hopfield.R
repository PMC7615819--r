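#' Separation functions for Hopfield-style retrieval
#'
#' Under the Universal Hopfield retrieval form, a sequential memory model
#' retrieves `sum_mu x^{mu+1} sep(sim(x^mu, q))`: the query is compared to
#' every stored pattern by a similarity function (here always the dot
#' product) and a separation function sharpens the similarity scores before
#' the weighted sum of successors.
#'
#' * `sep_identity()` — raw dot products (the classical asymmetric Hopfield
#'   network, AHN).
#' * `sep_polynomial(d)` — scores raised elementwise to the power `d`
#'   (polynomial AHN; `d = 1` is again the classical AHN).
#' * `sep_softmax(beta)` — `softmax(beta * scores)`; the modern continuous
#'   AHN (MCAHN), whose weights form a convex combination. `beta` is the
#'   temperature controlling the separation strength (default 5).
#'
#' @param d positive integer polynomial degree.
#' @param beta positive softmax temperature.
#' @return A separation spec used by [ahn()].
#' @export
sep_identity <- function() {
  structure(list(kind = "identity"), class = "ahn_separation")
}

#' @rdname sep_identity
#' @export
sep_polynomial <- function(d) {
  d <- check_count(d, "d")
  structure(list(kind = "polynomial", d = d), class = "ahn_separation")
}

#' @rdname sep_identity
#' @export
sep_softmax <- function(beta = 5) {
  stopifnot(length(beta) == 1L, is.finite(beta), beta > 0)
  structure(list(kind = "softmax", beta = beta), class = "ahn_separation")
}

#' @export
format.ahn_separation <- function(x, ...) {
  switch(x$kind,
         identity = "identity",
         polynomial = sprintf("polynomial(d = %d)", x$d),
         softmax = sprintf("softmax(beta = %g)", x$beta))
}

#' @export
print.ahn_separation <- function(x, ...) {
  cat("<ahn_separation>", format(x), "\n")
  invisible(x)
}

#' Asymmetric Hopfield Network over a stored sequence
#'
#' Stores a sequence for single-shot next-pattern retrieval. The stored
#' patterns are kept explicitly for the general retrieval form; for
#' identity separation the classical weight matrix
#' `W_AHN = sum_mu x^{mu+1} (x^mu)^T`, which encodes the asymmetric
#' autocovariance of the sequence, is also materialized.
#'
#' @param seq a [pattern_sequence()] of at least two patterns.
#' @param separation a separation spec from [sep_identity()],
#'   [sep_polynomial()] or [sep_softmax()].
#' @return An object of class `ahn`.
#' @export
ahn <- function(seq, separation = sep_identity()) {
  stopifnot(inherits(seq, "pattern_sequence"),
            inherits(separation, "ahn_separation"))
  if (nrow(seq) < 2L) stop("an AHN needs a sequence with at least 2 patterns")
  X <- as.matrix(seq)
  P <- nrow(X) - 1L
  prev <- X[seq_len(P), , drop = FALSE]
  nxt <- X[seq_len(P) + 1L, , drop = FALSE]
  W <- if (separation$kind == "identity") t(crossprod(prev, nxt)) else NULL
  structure(list(stored = seq, prev = prev, nxt = nxt, W_AHN = W,
                 separation = separation, n_features = ncol(X)),
            class = "ahn")
}

#' @export
print.ahn <- function(x, ...) {
  cat(sprintf("<ahn> %d stored transitions, N = %d, separation %s\n",
              nrow(x$prev), x$n_features, format(x$separation)))
  invisible(x)
}

apply_separation <- function(sep, scores) {
  switch(sep$kind,
         identity = scores,
         polynomial = scores^sep$d,
         softmax = {
           e <- exp(sep$beta * (scores - max(scores)))
           e / sum(e)
         })
}

#' Single-shot Hopfield retrieval
#'
#' Retrieves `sum_mu x^{mu+1} sep((x^mu)^T q)`. For binary output the sign
#' function is applied with the convention `sgn(0) = +1`; real-valued
#' retrieval (e.g. images) skips it.
#'
#' @param model an [ahn()] model.
#' @param query numeric query vector of the stored dimension.
#' @param binary_output apply the sign nonlinearity? Defaults to `TRUE` for
#'   binary-domain stored sequences.
#' @return The retrieved vector. The separation weights actually used are
#'   attached as attribute `"weights"`.
#' @export
ahn_retrieve <- function(model, query,
                         binary_output = attr(model$stored, "domain") == "binary") {
  stopifnot(inherits(model, "ahn"))
  if (length(query) != model$n_features)
    stop("query dimension does not match the stored patterns")
  w <- apply_separation(model$separation, as.numeric(model$prev %*% query))
  r <- as.numeric(crossprod(model$nxt, w))
  if (binary_output) r <- sign_pm(r)
  attr(r, "weights") <- w
  r
}

# sign with sgn(0) = +1
sign_pm <- function(x) ifelse(x >= 0, 1, -1)

#' Step-by-step Hopfield recall of a whole sequence
#'
#' Chains [ahn_retrieve()] over a sequence under the same online/offline
#' protocols used for the tPC models: online feeds ground-truth queries,
#' offline feeds the previous retrieval.
#'
#' @inheritParams ahn_retrieve
#' @param seq the queried [pattern_sequence()].
#' @param mode `"online"` or `"offline"`.
#' @return A `recall_result`; `$separation_weights` holds the per-step
#'   separation weight vectors (rows) for diagnostics.
#' @export
ahn_recall <- function(model, seq, mode = c("online", "offline"),
                       binary_output = attr(model$stored, "domain") == "binary") {
  mode <- match.arg(mode)
  stopifnot(inherits(seq, "pattern_sequence"))
  X <- as.matrix(seq)
  L <- nrow(X)
  Xhat <- matrix(0, L, ncol(X))
  Xhat[1L, ] <- X[1L, ]
  Wts <- matrix(NA_real_, L, nrow(model$prev))
  for (mu in 2:L) {
    q <- if (mode == "online") X[mu - 1L, ] else Xhat[mu - 1L, ]
    r <- ahn_retrieve(model, q, binary_output = binary_output)
    Wts[mu, ] <- attr(r, "weights")
    Xhat[mu, ] <- r
  }
  res <- recall_result(pattern_sequence(Xhat, domain = "real",
                                        frame_shape = attr(seq, "frame_shape")),
                       mode, per_step_energy = NULL)
  res$separation_weights <- Wts
  res
}

#' Strong-attractor diagnostic for softmax retrieval
#'
#' A stored frame with an outsized norm gives its successor an undesirable
#' dot-product advantage, and softmax retrieval can lock onto that
#' transition regardless of where recall actually is. This diagnostic runs
#' offline recall and flags every step whose softmax weight exceeds
#' `weight_threshold` on a transition whose source index is not the
#' previous step.
#'
#' @param model an [ahn()] model with softmax separation.
#' @param seq the queried [pattern_sequence()].
#' @param weight_threshold softmax weight above which a step counts as
#'   locked (default 0.9).
#' @return A data frame with one row per recalled step: `step`,
#'   `top_source` (transition source with the largest weight), `top_weight`
#'   and `hijacked` (top source is not `step - 1` and its weight exceeds
#'   the threshold). Attribute `"hit"` is `TRUE` if any step is hijacked.
#' @export
strong_attractor_diagnostic <- function(model, seq, weight_threshold = 0.9) {
  stopifnot(inherits(model, "ahn"))
  if (model$separation$kind != "softmax")
    stop("the strong-attractor diagnostic applies to softmax separation")
  res <- ahn_recall(model, seq, mode = "offline", binary_output = FALSE)
  L <- nrow(res$recalled)
  steps <- 2:L
  top <- apply(res$separation_weights[steps, , drop = FALSE], 1L, which.max)
  topw <- res$separation_weights[cbind(steps, top)]
  out <- data.frame(step = steps, top_source = top, top_weight = topw,
                    hijacked = topw > weight_threshold & top != steps - 1L)
  attr(out, "hit") <- any(out$hijacked)
  out
}
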