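#' Closed-form linear transition map
#'
#' The unique minimum-norm solution of the least-squares problem
#' `min_W sum_mu |x^{mu+1} - W x^mu|^2`, namely `W = A C^+` with
#' `A = sum_mu x^{mu+1} (x^mu)^T` and `C = sum_{mu=1..P} x^mu (x^mu)^T`.
#' This is the fixed point that iterative single-layer tPC training with an
#' identity nonlinearity converges to from a zero start, and serves as the
#' analytical oracle for the trained network.
#'
#' @param seq a [pattern_sequence()] of at least two patterns.
#' @param center subtract the sequence mean first (default `TRUE`; the
#'   whitening equivalence assumes zero-mean memories). Idempotent on
#'   already-centered data.
#' @param eps relative pseudoinverse regularization: eigenvalues of `C`
#'   below `eps * max(eigenvalue)` are treated as zero.
#' @return The `N x N` transition matrix (for centered data if
#'   `center = TRUE`).
#' @export
closed_form_weights <- function(seq, center = TRUE, eps = 1e-8) {
  X <- theory_matrix(seq, center)
  P <- nrow(X) - 1L
  prev <- X[seq_len(P), , drop = FALSE]
  nxt <- X[seq_len(P) + 1L, , drop = FALSE]
  A <- t(crossprod(prev, nxt))          # sum of x^{mu+1} (x^mu)^T
  C <- crossprod(prev)                  # sum of x^mu (x^mu)^T
  e <- eigen(C, symmetric = TRUE)
  keep <- e$values > eps * max(e$values, 0)
  inv <- ifelse(keep, 1 / pmax(e$values, .Machine$double.eps), 0)
  Cpinv <- e$vectors %*% (inv * t(e$vectors))
  A %*% Cpinv
}

theory_matrix <- function(seq, center) {
  stopifnot(inherits(seq, "pattern_sequence"))
  if (nrow(seq) < 2L) stop("need a sequence with at least 2 patterns")
  X <- as.matrix(seq)
  if (center) sweep(X, 2L, colMeans(X)) else X
}

#' Empirical whitening operator
#'
#' The symmetric (ZCA) inverse square root of the mean second-moment matrix
#' of the stored patterns, `Cbar = (1/P) sum_{mu=1..P} x^mu (x^mu)^T`,
#' computed by symmetric eigendecomposition with eigenvalues below
#' `eps * max(eigenvalue)` truncated to zero (the same spectral cutoff as
#' [closed_form_weights()], so the two retrieval routes agree to machine
#' precision; rank-deficient sequences are handled without error). On the
#' span of the patterns the whitened patterns have identity second moment,
#' `mean_mu (M x^mu)(M x^mu)^T = I`. The symmetric square root is fixed for
#' determinism; the whitened retrieval value depends on `M` only through
#' `M^T M`.
#'
#' @inheritParams closed_form_weights
#' @param eps relative eigenvalue cutoff of the pseudoinverse square root.
#' @return An object of class `whitening_operator` with fields `M`, `C`
#'   (the mean second-moment matrix), `basis` (orthonormal basis of the
#'   retained span), `mean` (the removed mean, or zeros), `rank`
#'   (effective rank of `C`), `eps` and `P`.
#' @export
whitening_matrix <- function(seq, center = TRUE, eps = 1e-8) {
  X <- theory_matrix(seq, center)
  P <- nrow(X) - 1L
  prev <- X[seq_len(P), , drop = FALSE]
  Cbar <- crossprod(prev) / P
  e <- eigen(Cbar, symmetric = TRUE)
  lam_max <- max(e$values, .Machine$double.eps)
  keep <- e$values > eps * lam_max
  # truncated pseudoinverse square root: the same spectral cutoff as the
  # closed-form transition map, so the two retrieval routes agree to
  # machine precision; directions below the cutoff are annihilated
  inv_sqrt <- ifelse(keep, 1 / sqrt(pmax(e$values, .Machine$double.eps)), 0)
  M <- e$vectors %*% (inv_sqrt * t(e$vectors))
  structure(list(M = M, C = Cbar, basis = e$vectors[, keep, drop = FALSE],
                 mean = if (center) colMeans(as.matrix(seq)) else
                   numeric(ncol(X)),
                 rank = sum(keep),
                 eps = eps, P = P),
            class = "whitening_operator")
}

#' @export
print.whitening_operator <- function(x, ...) {
  cat(sprintf("<whitening_operator> N = %d, effective rank %d, eps = %g\n",
              nrow(x$M), x$rank, x$eps))
  invisible(x)
}

#' Hopfield retrieval with whitened similarity
#'
#' The Universal-Hopfield-form counterpart of linear tPC retrieval: the
#' stored patterns and the query are whitened by `M` before the dot
#' product, and the successor patterns are combined with identity
#' separation, averaged over the stored transitions:
#' `R(q) = (1/P) sum_mu x^{mu+1} (M x^mu)^T (M q)`.
#' With `M` built from the mean second moment (so the whitened patterns
#' have identity second moment), this equals the closed-form transition map
#' applied to the query, `A C^+ q`, up to pseudoinverse regularization —
#' whitening of already-white data is the identity, in which case the
#' expression reduces to classical AHN retrieval.
#'
#' @param seq the stored [pattern_sequence()].
#' @param whitener a [whitening_matrix()] built from the same sequence.
#' @param query numeric query vector (uncentered; the whitener's stored
#'   mean is subtracted to match its centering convention).
#' @return The retrieved vector (in the whitener's centered coordinates).
#' @export
whitened_retrieve <- function(seq, whitener, query) {
  stopifnot(inherits(seq, "pattern_sequence"),
            inherits(whitener, "whitening_operator"))
  if (length(query) != ncol(seq))
    stop("query dimension does not match the sequence")
  X <- sweep(as.matrix(seq), 2L, whitener$mean)
  P <- nrow(X) - 1L
  if (P != whitener$P) stop("whitener was built for a different sequence length")
  prev <- X[seq_len(P), , drop = FALSE]
  nxt <- X[seq_len(P) + 1L, , drop = FALSE]
  q <- query - whitener$mean
  sims <- as.numeric(prev %*% (whitener$M %*% (whitener$M %*% q)))
  as.numeric(crossprod(nxt, sims)) / P
}
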