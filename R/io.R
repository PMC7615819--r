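#' Read and write pattern sequences as CSV
#'
#' One row per time step with header `t,f0,...,f{N-1}`; the domain and
#' frame shape ride along as comment-free extra columns are avoided, so
#' they must be re-supplied on read (default `"real"`).
#'
#' @param seq a [pattern_sequence()].
#' @param path file path.
#' @param domain,frame_shape domain tag and optional frame shape to attach
#'   on read; see [pattern_sequence()].
#' @return `write_sequence_csv` returns `path` invisibly;
#'   `read_sequence_csv` returns a [pattern_sequence()].
#' @export
write_sequence_csv <- function(seq, path) {
  stopifnot(inherits(seq, "pattern_sequence"))
  X <- as.matrix(seq)
  df <- data.frame(t = seq_len(nrow(X)), X)
  names(df) <- c("t", paste0("f", seq_len(ncol(X)) - 1L))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_sequence_csv
#' @export
read_sequence_csv <- function(path, domain = "real", frame_shape = NULL) {
  df <- utils::read.csv(path)
  if (names(df)[1L] != "t") stop("not a sequence CSV: first column must be 't'")
  pattern_sequence(as.matrix(df[, -1L, drop = FALSE]), domain = domain,
                   frame_shape = frame_shape)
}

#' Write one frame of an image sequence as plain PGM
#'
#' Plain-text (P2) PGM at 8-bit depth, for eyeballing image-domain
#' sequences with any image viewer.
#'
#' @param seq an image-domain [pattern_sequence()].
#' @param step time step to dump.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_frame_pgm <- function(seq, step, path) {
  stopifnot(inherits(seq, "pattern_sequence"))
  fs <- attr(seq, "frame_shape")
  if (is.null(fs)) stop("sequence has no frame_shape; not an image sequence")
  f <- matrix(as.matrix(seq)[step, ], fs[1L], fs[2L])
  v <- round(255 * pmin(pmax(f, 0), 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(fs[2L], fs[1L]), "255"), con)
  utils::write.table(v, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Save and load models as portable text
#'
#' Weights go to CSV files and hyperparameters to a JSON metadata sidecar
#' (`<prefix>_meta.json`), so saved models are plain text and portable.
#' Supported classes: [tpc_single()], [tpc_two()] and [ahn()].
#'
#' @param model a supported model object.
#' @param prefix path prefix for the files written.
#' @return `save_model` returns the metadata path invisibly; `load_model`
#'   returns the reconstructed model.
#' @export
save_model <- function(model, prefix) {
  write_mat <- function(M, suffix) {
    p <- paste0(prefix, "_", suffix, ".csv")
    utils::write.table(M, p, sep = ",", row.names = FALSE, col.names = FALSE)
    basename(p)
  }
  meta <- if (inherits(model, "tpc_single")) {
    list(kind = "tpc_single", n_features = model$n_features,
         nonlinearity = model$nonlinearity, lr_weights = model$lr_weights,
         lr_inference = model$lr_inference,
         n_inference_steps = model$n_inference_steps,
         inference_tol = model$inference_tol, trained = model$trained,
         files = list(W = write_mat(model$W, "W")))
  } else if (inherits(model, "tpc_two")) {
    list(kind = "tpc_two", n_features = model$n_features,
         hidden_dim = model$hidden_dim, nonlinearity = model$nonlinearity,
         lr_weights = model$lr_weights, lr_inference = model$lr_inference,
         n_inference_steps = model$n_inference_steps,
         inference_tol = model$inference_tol,
         hidden_init_scale = model$hidden_init_scale, seed = model$seed,
         trained = model$trained,
         files = list(WH = write_mat(model$WH, "WH"),
                      WF = write_mat(model$WF, "WF")))
  } else if (inherits(model, "ahn")) {
    list(kind = "ahn", n_features = model$n_features,
         separation = unclass(model$separation),
         domain = attr(model$stored, "domain"),
         files = list(stored = write_mat(as.matrix(model$stored), "stored")))
  } else stop("unsupported model class")
  meta_path <- paste0(prefix, "_meta.json")
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA)
  invisible(meta_path)
}

#' @rdname save_model
#' @export
load_model <- function(prefix) {
  meta <- jsonlite::read_json(paste0(prefix, "_meta.json"), simplifyVector = TRUE)
  read_mat <- function(fname)
    as.matrix(utils::read.table(file.path(dirname(prefix), fname), sep = ","))
  if (meta$kind == "tpc_single") {
    m <- tpc_single(meta$n_features, nonlinearity = meta$nonlinearity,
                    lr_weights = meta$lr_weights,
                    lr_inference = meta$lr_inference,
                    n_inference_steps = meta$n_inference_steps,
                    inference_tol = meta$inference_tol)
    m$W <- unname(read_mat(meta$files$W))
    m$trained <- isTRUE(meta$trained)
    m
  } else if (meta$kind == "tpc_two") {
    m <- tpc_two(meta$n_features, hidden_dim = meta$hidden_dim,
                 nonlinearity = meta$nonlinearity,
                 lr_weights = meta$lr_weights,
                 lr_inference = meta$lr_inference,
                 n_inference_steps = meta$n_inference_steps,
                 inference_tol = meta$inference_tol,
                 hidden_init_scale = meta$hidden_init_scale,
                 seed = meta$seed)
    m$WH <- unname(read_mat(meta$files$WH))
    m$WF <- unname(read_mat(meta$files$WF))
    m$trained <- isTRUE(meta$trained)
    m
  } else if (meta$kind == "ahn") {
    sep <- switch(meta$separation$kind,
                  identity = sep_identity(),
                  polynomial = sep_polynomial(meta$separation$d),
                  softmax = sep_softmax(meta$separation$beta))
    ahn(pattern_sequence(unname(read_mat(meta$files$stored)),
                         domain = meta$domain), sep)
  } else stop("unknown model kind in metadata: ", meta$kind)
}
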