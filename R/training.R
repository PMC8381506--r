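# Class-balanced batch construction, the Adam-driven training loop,
# early stopping on validation loss, and checkpoint restoration.

#' Training hyperparameters
#'
#' @param batch_size Windows per batch (`n`).
#' @param repeat_fraction `r` in `[0,1]`: at least `floor(n*r)` windows
#'   in every batch contain a repeat-annotated position, and among those
#'   at least `floor(n*r/4)` contain each repeat class, so rare classes
#'   are oversampled relative to their genome frequency.
#' @param max_epochs Hard cap on epochs.
#' @param patience Early stopping: training halts once the validation
#'   loss has not improved for this many consecutive epochs (default 10).
#' @param learning_rate Adam step size.
#' @param train_step Step (bp) between training window starts.
#' @param batches_per_epoch Batches drawn per epoch; default covers the
#'   pool once.
#' @param augment_rate Training-time noise: probability that a non-N
#'   base of a training window is substituted by a random other base
#'   before encoding.  Emulates the sequence divergence between repeat
#'   copies and discourages memorizing individual instances.
#' @param weight_decay Decoupled (AdamW-style) weight decay coefficient.
#' @param lr_decay Multiplicative step decay of the learning rate,
#'   applied every `lr_decay_every` epochs; stabilizes late epochs so
#'   validation-loss early stopping selects among converged models.
#' @param lr_decay_every Epoch interval of the step decay.
#' @param seed Seed for sampling and shuffling.
#' @return A `train_config` list.
#' @export
train_config <- function(batch_size = 32L, repeat_fraction = 0.7,
                         max_epochs = 60L, patience = 10L,
                         learning_rate = 8e-3, train_step = 50L,
                         batches_per_epoch = 40L, augment_rate = 0.05,
                         weight_decay = 0, lr_decay = 0.5,
                         lr_decay_every = 15L, seed = 0L) {
  stopifnot(repeat_fraction >= 0, repeat_fraction <= 1, patience >= 1L,
            batch_size >= 1L, max_epochs >= 1L, augment_rate >= 0,
            augment_rate < 1, weight_decay >= 0, lr_decay > 0,
            lr_decay <= 1, lr_decay_every >= 1L)
  structure(list(batch_size = as.integer(batch_size),
                 repeat_fraction = repeat_fraction,
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience),
                 learning_rate = learning_rate,
                 train_step = as.integer(train_step),
                 batches_per_epoch = batches_per_epoch,
                 augment_rate = augment_rate,
                 weight_decay = weight_decay,
                 lr_decay = lr_decay,
                 lr_decay_every = as.integer(lr_decay_every),
                 seed = as.integer(seed)),
            class = "train_config")
}

#' Build the pool of training windows for a labeled sequence
#'
#' Windows are laid out with [make_windows()]; each window records which
#' repeat classes it contains (a window contains a class if at least one
#' position carries that label).
#'
#' @param labels Integer label track (values 0..4).
#' @param window_length,step Window geometry.
#' @return Data frame with `start`, `any_repeat` and logical columns
#'   `has_1` .. `has_4`.
#' @export
training_windows <- function(labels, window_length = 342L, step = 50L) {
  n <- length(labels)
  if (n < window_length)
    stop("sequence shorter than one window (", n, " < ", window_length, ")")
  starts <- make_windows(n, window_length, step)$starts
  pool <- data.frame(start = starts)
  for (c_id in 1:4) {
    cs <- c(0L, cumsum(labels == c_id))
    pool[[paste0("has_", c_id)]] <-
      (cs[starts + window_length + 1L] - cs[starts + 1L]) > 0L
  }
  pool$any_repeat <- pool$has_1 | pool$has_2 | pool$has_3 | pool$has_4
  pool
}

#' Compose one class-balanced batch
#'
#' Draws `n` window indices from the pool honoring the `r` floors: at
#' least `floor(n*r)` windows contain a repeat and at least
#' `floor(n*r/|C|)` contain each of the four repeat classes; remaining
#' slots are uniform draws from the whole pool.  Sampling uses the
#' current RNG state (seed it for reproducibility).
#'
#' @param pool Data frame from [training_windows()].
#' @param n Batch size.
#' @param r Repeat fraction in `[0,1]`.
#' @return Integer vector of `n` row indices into `pool`.
#' @export
compose_batch <- function(pool, n, r) {
  stopifnot(r >= 0, r <= 1, n >= 1L)
  n <- as.integer(n)
  per_class <- floor(n * r / N_REPEAT_CLASSES)
  n_repeat <- floor(n * r)
  chosen <- integer(0)
  if (per_class > 0) {
    for (c_id in 1:4) {
      avail <- which(pool[[paste0("has_", c_id)]])
      if (length(avail) < per_class)
        stop("cannot balance batch: only ", length(avail),
             " windows contain class ", repeat_class_name(c_id),
             " (need ", per_class, ")")
      chosen <- c(chosen, sample_int(avail, per_class))
    }
  }
  n_rep_have <- sum(pool$any_repeat[chosen])
  if (n_rep_have < n_repeat) {
    avail <- which(pool$any_repeat)
    if (length(avail) < n_repeat)
      stop("cannot balance batch: only ", length(avail),
           " repeat-containing windows (need ", n_repeat, ")")
    extra <- sample_int(setdiff(avail, chosen), n_repeat - n_rep_have)
    chosen <- c(chosen, extra)
  }
  if (length(chosen) < n)
    chosen <- c(chosen, sample_int(seq_len(nrow(pool)), n - length(chosen)))
  chosen[seq_len(n)]
}

# sample() without the length-1 surprise; falls back to replacement when
# the pool is smaller than the request.
sample_int <- function(x, size) {
  if (length(x) == 0L) stop("empty sampling pool")
  x[sample.int(length(x), size, replace = length(x) < size)]
}

# One-hot label targets for a batch of windows: B x 5 x T array.
label_batch <- function(labels, starts, window_length) {
  b <- length(starts)
  y <- array(0, dim = c(b, 5L, window_length))
  for (i in seq_len(b)) {
    lab <- labels[(starts[i] + 1L):(starts[i] + window_length)]
    m <- matrix(0, nrow = 5L, ncol = window_length)
    m[cbind(lab + 1L, seq_len(window_length))] <- 1
    y[i, , ] <- m
  }
  y
}

# --- early stopping bookkeeping (pure, unit-testable) -----------------

# Index of the best (lowest) validation loss; improvement = strictly
# lower than the best so far.
best_epoch <- function(val_losses) which.min(val_losses)

# TRUE when the last `patience` epochs brought no improvement.
should_stop <- function(val_losses, patience) {
  length(val_losses) - best_epoch(val_losses) >= patience
}

adam_init <- function(n) list(m = numeric(n), v = numeric(n), t = 0L)

adam_step <- function(state, theta, grad, lr, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8, weight_decay = 0) {
  state$t <- state$t + 1L
  state$m <- beta1 * state$m + (1 - beta1) * grad
  state$v <- beta2 * state$v + (1 - beta2) * grad^2
  mhat <- state$m / (1 - beta1^state$t)
  vhat <- state$v / (1 - beta2^state$t)
  theta <- theta - lr * (mhat / (sqrt(vhat) + eps) + weight_decay * theta)
  list(state = state, theta = theta)
}

#' Train a model on a labeled sequence
#'
#' Minimizes per-position categorical cross-entropy with Adam over
#' class-balanced batches.  After every epoch the validation loss is
#' computed on non-overlapping windows of the validation sequence;
#' training stops when it has not improved for `patience` epochs (or at
#' `max_epochs`), and the parameters from the best-validation epoch are
#' restored.
#'
#' @param model A `repeatnet_model` from [build_model()].
#' @param train_seq,val_seq Sequences (strings or `dna_sequence`).
#' @param train_labels,val_labels Integer label tracks matching the
#'   trimmed sequences.
#' @param config A [train_config()].
#' @param verbose Print per-epoch losses to stderr.
#' @return List with `model` (best-epoch parameters) and `history`
#'   (data frame of per-epoch train/validation loss).
#' @export
train <- function(model, train_seq, train_labels, val_seq, val_labels,
                  config = train_config(), verbose = FALSE) {
  w <- model$config$window_length
  train_seq <- as_dna_sequence(train_seq); val_seq <- as_dna_sequence(val_seq)
  stopifnot(nchar(train_seq$bases) == length(train_labels),
            nchar(val_seq$bases) == length(val_labels))
  enc_tr <- one_hot_encode(train_seq$bases)
  enc_va <- one_hot_encode(val_seq$bases)
  pool <- training_windows(train_labels, w, config$train_step)
  val_starts <- make_windows(length(val_labels), w, w)$starts
  n_batches <- if (is.null(config$batches_per_epoch))
    ceiling(nrow(pool) / config$batch_size)
  else as.integer(config$batches_per_epoch)

  set.seed(config$seed)
  theta <- flatten_params(model$params)
  opt <- adam_init(length(theta))
  params <- model$params
  history <- data.frame(epoch = integer(0), train_loss = numeric(0),
                        val_loss = numeric(0))
  best_params <- params
  val_losses <- numeric(0)

  for (epoch in seq_len(config$max_epochs)) {
    lr <- config$learning_rate *
      config$lr_decay^((epoch - 1L) %/% config$lr_decay_every)
    tr_loss <- 0
    for (b in seq_len(n_batches)) {
      idx <- compose_batch(pool, config$batch_size, config$repeat_fraction)
      starts <- pool$start[idx]
      xs <- encode_window_batch(enc_tr, starts, w, config$augment_rate)
      y <- label_batch(train_labels, starts, w)
      res <- cpp_nn_loss_grad(params, xs$xf, xs$xr, y, TRUE)
      if (!is.finite(res$loss))
        stop("training diverged (non-finite loss) at epoch ", epoch)
      tr_loss <- tr_loss + res$loss
      grad <- flatten_params(res$grads)
      upd <- adam_step(opt, theta, grad, lr,
                       weight_decay = config$weight_decay)
      opt <- upd$state; theta <- upd$theta
      params <- unflatten_params(theta, params)
    }
    tr_loss <- tr_loss / n_batches

    vl <- validation_loss(params, enc_va, val_labels, val_starts, w,
                          config$batch_size)
    val_losses <- c(val_losses, vl)
    history <- rbind(history, data.frame(epoch = epoch,
                                         train_loss = tr_loss,
                                         val_loss = vl))
    if (verbose)
      message(sprintf("epoch %3d  train %.4f  val %.4f", epoch, tr_loss, vl))
    if (best_epoch(val_losses) == epoch) best_params <- params
    if (should_stop(val_losses, config$patience)) break
  }
  model$params <- best_params
  list(model = model, history = history)
}

validation_loss <- function(params, enc, labels, starts, w, batch_size) {
  total <- 0; nb <- 0L
  for (i in seq(1L, length(starts), by = batch_size)) {
    s <- starts[i:min(i + batch_size - 1L, length(starts))]
    xs <- encode_window_batch(enc, s, w)
    y <- label_batch(labels, s, w)
    res <- cpp_nn_loss_grad(params, xs$xf, xs$xr, y, FALSE)
    total <- total + res$loss * length(s)
    nb <- nb + length(s)
  }
  total / nb
}
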