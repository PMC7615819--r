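#' Ordered sequence of patterns
#'
#' The unit of memorization throughout the package: an ordered list of
#' `P + 1` pattern vectors `x^mu` sharing a common dimension `N`, stored as
#' the rows of a numeric matrix.
#'
#' @param x numeric matrix with one row per time step and one column per
#'   feature, or an object coercible to one.
#' @param domain character tag describing the value domain of the patterns:
#'   `"real"` (unconstrained), `"binary"` (entries in `{-1, +1}`),
#'   `"onehot"` (exactly one entry 1, the rest 0) or `"image"` (pixel
#'   values, typically in `[0, 1]`, with a known `frame_shape`).
#' @param frame_shape optional integer pair `(rows, cols)`; required for
#'   `domain = "image"` and used when frames are written out for
#'   inspection.
#'
#' @return An object of class `pattern_sequence`: the pattern matrix with
#'   `domain` and `frame_shape` attributes.
#' @export
pattern_sequence <- function(x, domain = c("real", "binary", "onehot", "image"),
                             frame_shape = NULL) {
  domain <- match.arg(domain)
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  if (nrow(x) < 1L) stop("a pattern sequence needs at least one pattern")
  if (!all(is.finite(x))) stop("pattern values must be finite")
  if (domain == "binary" && !all(x %in% c(-1, 1)))
    stop("binary-domain entries must lie in {-1, +1}")
  if (domain == "onehot") {
    ok <- apply(x, 1L, function(r) sum(r == 1) == 1L && all(r %in% c(0, 1)))
    if (!all(ok)) stop("onehot-domain patterns must have exactly one entry equal to 1")
  }
  if (domain == "image") {
    if (is.null(frame_shape)) stop("image-domain sequences require frame_shape")
    frame_shape <- as.integer(frame_shape)
    if (length(frame_shape) != 2L || prod(frame_shape) != ncol(x))
      stop("frame_shape must be a (rows, cols) pair with prod(frame_shape) == n_features")
  }
  structure(x, domain = domain, frame_shape = frame_shape,
            class = c("pattern_sequence", "matrix", "array"))
}

#' @export
print.pattern_sequence <- function(x, ...) {
  fs <- attr(x, "frame_shape")
  cat(sprintf("<pattern_sequence> %d steps x %d features, domain '%s'%s\n",
              nrow(x), ncol(x), attr(x, "domain"),
              if (is.null(fs)) "" else sprintf(", frames %dx%d", fs[1], fs[2])))
  invisible(x)
}

#' @export
as.matrix.pattern_sequence <- function(x, ...) {
  attributes(x) <- list(dim = dim(x))
  x
}

#' @rdname pattern_sequence
#' @param seq a `pattern_sequence`.
#' @export
n_steps <- function(seq) nrow(seq)

#' @rdname pattern_sequence
#' @export
n_features <- function(seq) ncol(seq)

#' Subset the time steps of a sequence
#'
#' @param seq a `pattern_sequence`.
#' @param steps integer vector of (1-based) time steps to keep, in order.
#' @return A `pattern_sequence` over the selected steps.
#' @export
subset_steps <- function(seq, steps) {
  stopifnot(inherits(seq, "pattern_sequence"))
  pattern_sequence(unclass(seq)[steps, , drop = FALSE],
                   domain = attr(seq, "domain"),
                   frame_shape = attr(seq, "frame_shape"))
}

#' Center a sequence to zero mean
#'
#' Subtracts the mean pattern (averaged over all time steps) from every
#' pattern. The closed-form and whitened retrieval identities assume
#' zero-mean memories; centering once up front makes the `center = TRUE`
#' flags of the theory functions no-ops.
#'
#' @param seq a `pattern_sequence`.
#' @return A real-domain `pattern_sequence` with column means zero, with the
#'   removed mean stored in attribute `"removed_mean"`.
#' @export
center_sequence <- function(seq) {
  stopifnot(inherits(seq, "pattern_sequence"))
  m <- colMeans(unclass(seq))
  out <- pattern_sequence(sweep(unclass(seq), 2L, m), domain = "real",
                          frame_shape = attr(seq, "frame_shape"))
  attr(out, "removed_mean") <- m
  out
}

check_count <- function(x, name) {
  if (length(x) != 1L || !is.finite(x) || x < 1 || x != floor(x))
    stop(sprintf("`%s` must be a positive integer", name))
  as.integer(x)
}

#' Uncorrelated binary pattern sequence
#'
#' Each entry is drawn i.i.d. uniformly from `{-1, +1}`. These are the
#' sequences on which classical asymmetric Hopfield capacity results hold.
#'
#' @param n_features pattern dimension `N`.
#' @param length number of patterns (`P + 1`).
#' @param seed integer seed; identical arguments give identical output.
#' @return A binary-domain [pattern_sequence()].
#' @export
generate_binary_sequence <- function(n_features, length, seed) {
  n_features <- check_count(n_features, "n_features")
  length <- check_count(length, "length")
  x <- withr::with_seed(seed, {
    matrix(sample(c(-1, 1), n_features * length, replace = TRUE),
           nrow = length, ncol = n_features)
  })
  pattern_sequence(x, domain = "binary")
}

#' Correlated binary pattern sequence
#'
#' Binary patterns whose features are pairwise correlated at level `b`
#' while keeping uniform `{-1, +1}` marginals. Construction: each pattern
#' draws a latent sign `g`; every feature takes `g` with probability
#' `p = (1 + sqrt(b)) / 2` and `-g` otherwise, independently, giving
#' pairwise feature correlation exactly `(2p - 1)^2 = b` with uniform
#' marginals (the latent sign is uniform).
#'
#' @inheritParams generate_binary_sequence
#' @param b correlation magnitude, in `[0, 1)`.
#' @return A binary-domain [pattern_sequence()].
#' @export
generate_correlated_binary_sequence <- function(n_features, length, b, seed) {
  n_features <- check_count(n_features, "n_features")
  length <- check_count(length, "length")
  if (length(b) != 1L || !is.finite(b) || b < 0 || b >= 1)
    stop("`b` must lie in [0, 1)")
  p <- (1 + sqrt(b)) / 2
  x <- withr::with_seed(seed, {
    g <- sample(c(-1, 1), length, replace = TRUE)
    keep <- matrix(ifelse(stats::runif(length * n_features) < p, 1, -1),
                   nrow = length, ncol = n_features)
    g * keep
  })
  pattern_sequence(x, domain = "binary")
}

#' One-hot letter "word"
#'
#' Represents a word as an ordered sequence of one-hot letter vectors, the
#' stimulus format of the serial-recall experiments.
#'
#' @param alphabet_size number of letters (one-hot dimension).
#' @param word_length number of letters in the word.
#' @param seed integer seed.
#' @param distinct if `TRUE` (default) letters are sampled without
#'   replacement, so no letter repeats within the word.
#' @return A onehot-domain [pattern_sequence()] with attribute `"letters"`,
#'   the integer letter indices.
#' @export
generate_onehot_word <- function(alphabet_size, word_length, seed, distinct = TRUE) {
  alphabet_size <- check_count(alphabet_size, "alphabet_size")
  word_length <- check_count(word_length, "word_length")
  if (distinct && word_length > alphabet_size)
    stop("word_length must not exceed alphabet_size when letters are distinct")
  letters_idx <- withr::with_seed(seed,
    sample(alphabet_size, word_length, replace = !distinct))
  x <- matrix(0, nrow = word_length, ncol = alphabet_size)
  x[cbind(seq_len(word_length), letters_idx)] <- 1
  out <- pattern_sequence(x, domain = "onehot")
  attr(out, "letters") <- letters_idx
  out
}

#' The aliased moving-bar movie
#'
#' A deterministic 5-frame movie in a 5x5 frame: a white bar (one full row
#' of ones) moves down rows 1, 2, 3 and back up through 2 to 1, so the
#' frames at steps 2 and 4 are identical (aliased) while their successors
#' differ. The canonical desk-scale task for hidden-context disambiguation.
#'
#' @return An image-domain [pattern_sequence()] of five 25-vectors.
#' @export
generate_moving_bar <- function() {
  rows <- c(1L, 2L, 3L, 2L, 1L)
  x <- t(vapply(rows, function(r) {
    f <- matrix(0, 5, 5)
    f[r, ] <- 1
    as.vector(f)
  }, numeric(25)))
  pattern_sequence(x, domain = "image", frame_shape = c(5L, 5L))
}

#' Replace a fraction of a sequence with one repeated pattern
#'
#' Replaces `ceiling(fraction * n_steps)` positions, chosen uniformly at
#' random, with a single repeated pattern, producing aliased (repeating)
#' inputs at different time steps.
#'
#' @param seq a [pattern_sequence()].
#' @param fraction fraction of positions to replace, in `(0, 1)`.
#' @param repeated_pattern numeric vector of length `n_features(seq)`.
#' @param seed integer seed controlling which positions are replaced.
#' @return A [pattern_sequence()] with attribute `"aliased_steps"`, the
#'   sorted replaced positions.
#' @export
alias_sequence <- function(seq, fraction, repeated_pattern, seed) {
  stopifnot(inherits(seq, "pattern_sequence"))
  if (length(fraction) != 1L || !is.finite(fraction) || fraction <= 0 || fraction >= 1)
    stop("`fraction` must lie in (0, 1)")
  if (length(repeated_pattern) != ncol(seq))
    stop("`repeated_pattern` must have the sequence's feature dimension")
  k <- ceiling(fraction * nrow(seq))
  pos <- sort(withr::with_seed(seed, sample(nrow(seq), k)))
  x <- unclass(seq)
  x[pos, ] <- matrix(repeated_pattern, nrow = k, ncol = ncol(seq), byrow = TRUE)
  out <- pattern_sequence(x, domain = "real", frame_shape = attr(seq, "frame_shape"))
  attr(out, "aliased_steps") <- pos
  out
}

# Inverse-map bilinear rotation of a [0,1] image about its center;
# out-of-frame samples are zero. Keeps the canvas size fixed.
rotate_image <- function(img, angle_deg) {
  n <- nrow(img)
  m <- ncol(img)
  th <- angle_deg * pi / 180
  ct <- cos(th); st <- sin(th)
  cy <- (n + 1) / 2; cx <- (m + 1) / 2
  dy <- rep(seq_len(n) - cy, times = m)
  dx <- rep(seq_len(m) - cx, each = n)
  # inverse rotation: source coordinates in the unrotated image
  sy <- ct * dy + st * dx + cy
  sx <- -st * dy + ct * dx + cx
  y0 <- floor(sy); x0 <- floor(sx)
  fy <- sy - y0; fx <- sx - x0
  at <- function(yy, xx) {
    ok <- yy >= 1 & yy <= n & xx >= 1 & xx <= m
    v <- numeric(length(yy))
    v[ok] <- img[cbind(yy[ok], xx[ok])]
    v
  }
  v <- (1 - fy) * (1 - fx) * at(y0, x0) +
       fy * (1 - fx) * at(y0 + 1, x0) +
       (1 - fy) * fx * at(y0, x0 + 1) +
       fy * fx * at(y0 + 1, x0 + 1)
  matrix(v, n, m)
}

# Shape renderers on a [0,1] square canvas. The "train" family is filled
# regular polygons; the "heldout" family is line crosses. Disjoint classes
# preserve a seen/unseen split without any external image data.
render_polygon <- function(side, n_vertices, radius, cx, cy, phase) {
  ang <- phase + 2 * pi * (seq_len(n_vertices) - 1) / n_vertices
  px <- cx + radius * cos(ang)
  py <- cy + radius * sin(ang)
  img <- matrix(0, side, side)
  for (i in seq_len(side)) for (j in seq_len(side)) {
    # even-odd point-in-polygon test at pixel centers
    x <- j; y <- i
    inside <- FALSE
    k2 <- n_vertices
    for (k in seq_len(n_vertices)) {
      if ((py[k] > y) != (py[k2] > y)) {
        xint <- px[k] + (y - py[k]) * (px[k2] - px[k]) / (py[k2] - py[k])
        if (x < xint) inside <- !inside
      }
      k2 <- k
    }
    if (inside) img[i, j] <- 1
  }
  img
}

render_cross <- function(side, arm_halfwidth, arm_halflength, cx, cy, diagonal) {
  img <- matrix(0, side, side)
  for (i in seq_len(side)) for (j in seq_len(side)) {
    dy <- i - cy; dx <- j - cx
    if (diagonal) {
      u <- (dx + dy) / sqrt(2); v <- (dx - dy) / sqrt(2)
    } else {
      u <- dx; v <- dy
    }
    if ((abs(u) <= arm_halfwidth && abs(v) <= arm_halflength) ||
        (abs(v) <= arm_halfwidth && abs(u) <= arm_halflength))
      img[i, j] <- 1
  }
  img
}

#' Rotating-shape movie set
#'
#' Parametric movies of a single shape rotating by a fixed angle at every
#' step — a stand-in for rotating handwritten-character movies, emulating
#' "identical dynamics, varying content". The `train` family renders filled
#' regular polygons (3-6 vertices); the disjoint `heldout` family renders
#' straight and diagonal line crosses, so generalization is always measured
#' on a shape class never seen in training.
#'
#' @param n_sequences number of movies to generate.
#' @param frame_side frame side length in pixels (frames are square).
#' @param n_steps frames per movie; frame `k` is the base shape rotated by
#'   `(k - 1) * angle_per_step` degrees.
#' @param angle_per_step rotation per step, in degrees.
#' @param shape_family `"train"` (polygons) or `"heldout"` (crosses).
#' @param seed integer seed for shape parameters.
#' @return A list of image-domain [pattern_sequence()] objects with pixel
#'   values in `[0, 1]`.
#' @export
generate_rotating_shape_set <- function(n_sequences, frame_side = 16L,
                                        n_steps = 8L, angle_per_step = 45,
                                        shape_family = c("train", "heldout"),
                                        seed = 0L) {
  n_sequences <- check_count(n_sequences, "n_sequences")
  frame_side <- check_count(frame_side, "frame_side")
  n_steps <- check_count(n_steps, "n_steps")
  shape_family <- match.arg(shape_family)
  params <- withr::with_seed(seed, {
    lapply(seq_len(n_sequences), function(i) {
      list(kind = sample(4L, 1L),
           size = stats::runif(1, 0.22, 0.38) * frame_side,
           off = stats::runif(2, -0.08, 0.08) * frame_side,
           phase = stats::runif(1, 0, 2 * pi),
           width = stats::runif(1, 0.05, 0.12) * frame_side)
    })
  })
  c0 <- (frame_side + 1) / 2
  lapply(params, function(p) {
    base <- if (shape_family == "train") {
      render_polygon(frame_side, n_vertices = p$kind + 2L, radius = p$size,
                     cx = c0 + p$off[1], cy = c0 + p$off[2], phase = p$phase)
    } else {
      render_cross(frame_side, arm_halfwidth = p$width,
                   arm_halflength = p$size,
                   cx = c0 + p$off[1], cy = c0 + p$off[2],
                   diagonal = p$kind %% 2L == 0L)
    }
    frames <- t(vapply(seq_len(n_steps) - 1L, function(k) {
      as.vector(rotate_image(base, k * angle_per_step))
    }, numeric(frame_side^2)))
    pattern_sequence(pmin(pmax(frames, 0), 1), domain = "image",
                     frame_shape = c(frame_side, frame_side))
  })
}
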