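# Model construction and window-level prediction.  Parameters live in a
# plain named list of matrices/vectors; the numerics are in src/nn.cpp.

#' Model hyperparameters
#'
#' @param recurrent_units Width of the (shared) GRU layer.  Default 32,
#'   sized for desk-scale data sets.
#' @param attention_units Width of the additive-attention scoring layer.
#' @param window_length Window length in bp; fixed once trained
#'   (default 342).
#' @param n_classes Number of output classes (4 repeat classes + the
#'   no-repeat class).
#' @return A `model_config` list.
#' @export
model_config <- function(recurrent_units = 32L, attention_units = 8L,
                         window_length = 342L, n_classes = 5L) {
  stopifnot(recurrent_units >= 1L, attention_units >= 1L,
            window_length >= 1L, n_classes == 5L)
  structure(list(recurrent_units = as.integer(recurrent_units),
                 attention_units = as.integer(attention_units),
                 window_length = as.integer(window_length),
                 n_classes = as.integer(n_classes),
                 vocabulary = 5L),
            class = "model_config")
}

glorot <- function(nin, nout) {
  lim <- sqrt(6 / (nin + nout))
  matrix(stats::runif(nin * nout, -lim, lim), nin, nout)
}

#' Build a model with seeded initial parameters
#'
#' The architecture: forward-strand and reverse-complement one-hot inputs
#' are processed by one GRU whose single weight set serves both
#' directions; per-position outputs (reverse stream re-reversed to
#' forward coordinates) and the two final hidden states are averaged;
#' additive attention scores each position against the averaged hidden
#' state and yields a context vector; a position-wise dense layer over
#' the position features plus context produces softmax class
#' probabilities.
#'
#' @param config A [model_config()].
#' @param seed Integer seed for parameter initialization.
#' @return A `repeatnet_model` (list with `config` and `params`).
#' @export
build_model <- function(config = model_config(), seed = 0L) {
  u <- config$recurrent_units; a <- config$attention_units
  k <- config$n_classes; f <- config$vocabulary
  set.seed(as.integer(seed))
  params <- list(
    Wz = glorot(f, u), Wr = glorot(f, u), Wh = glorot(f, u),
    Uz = glorot(u, u), Ur = glorot(u, u), Uh = glorot(u, u),
    bz = numeric(u), br = numeric(u), bh = numeric(u),
    Wa = glorot(u, a), Ua = glorot(u, a), ba = numeric(a),
    v = matrix(stats::runif(a, -sqrt(3 / a), sqrt(3 / a)), a, 1),
    Wd1 = glorot(u, k), Wd2 = glorot(u, k), bd = numeric(k))
  structure(list(config = config, params = params),
            class = "repeatnet_model")
}

#' Number of trainable parameters
#'
#' Because the two directions share one weight set, the recurrent
#' parameters are counted once.
#'
#' @param model A `repeatnet_model`.
#' @return Integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params, length, 0L))
}

#' @export
print.repeatnet_model <- function(x, ...) {
  cat(sprintf(paste0("<repeatnet_model> GRU units %d (shared), ",
                     "attention %d, window %d bp, %d parameters\n"),
              x$config$recurrent_units, x$config$attention_units,
              x$config$window_length, n_parameters(x)))
  invisible(x)
}

#' Predict class probabilities for a batch of windows
#'
#' @param model A `repeatnet_model`.
#' @param xf,xr Arrays of shape `batch x 5 x window_length`: forward and
#'   reverse-complement one-hot encodings of the same windows.
#' @return Array `batch x 5 x window_length` of class probabilities;
#'   every position's 5-vector sums to 1.
#' @export
predict_windows <- function(model, xf, xr) {
  check_batch_shape(model, xf); check_batch_shape(model, xr)
  cpp_nn_predict(model$params, xf, xr)
}

check_batch_shape <- function(model, x) {
  d <- dim(x)
  if (length(d) != 3L || d[2L] != 5L || d[3L] != model$config$window_length)
    stop("encoding batch must have shape B x 5 x ",
         model$config$window_length)
  invisible(TRUE)
}

# --- parameter vector helpers (for the optimizer and tests) -----------

flatten_params <- function(params) unlist(params, use.names = FALSE)

unflatten_params <- function(flat, template) {
  out <- template
  pos <- 0L
  for (nm in names(template)) {
    len <- length(template[[nm]])
    vals <- flat[(pos + 1L):(pos + len)]
    if (is.matrix(template[[nm]])) {
      out[[nm]] <- matrix(vals, nrow(template[[nm]]), ncol(template[[nm]]))
    } else {
      out[[nm]] <- vals
    }
    pos <- pos + len
  }
  out
}

#' Save / load a model checkpoint
#'
#' A checkpoint is a directory holding the serialized parameters plus a
#' plain-text sidecar (`config.txt`) recording the architecture and any
#' training metadata, so a checkpoint is self-describing.
#'
#' @param model A `repeatnet_model`.
#' @param dir Checkpoint directory (created if needed).
#' @param metadata Optional named list of scalars recorded in the sidecar.
#' @return `save_model()` the directory, invisibly; `load_model()` the
#'   model.
#' @export
save_model <- function(model, dir, metadata = list()) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  saveRDS(model$params, file.path(dir, "params.rds"))
  cfg <- c(unclass(model$config), metadata)
  write_config(cfg, file.path(dir, "config.txt"))
  invisible(dir)
}

#' @rdname save_model
#' @export
load_model <- function(dir) {
  cfg_path <- file.path(dir, "config.txt")
  par_path <- file.path(dir, "params.rds")
  if (!file.exists(cfg_path) || !file.exists(par_path))
    stop("not a model checkpoint directory: ", dir)
  cfg <- read_config(cfg_path)
  config <- model_config(recurrent_units = cfg$recurrent_units,
                         attention_units = cfg$attention_units,
                         window_length = cfg$window_length,
                         n_classes = cfg$n_classes)
  structure(list(config = config, params = readRDS(par_path)),
            class = "repeatnet_model")
}
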