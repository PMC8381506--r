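# Whole-sequence prediction: slide windows, predict each on both
# strands, and keep the per-position, per-class maximum over all
# covering windows.  The aggregate is a streaming element-wise max, so
# memory stays O(n * 5) whatever the step.

#' Predict an aggregated probability track for a sequence
#'
#' Windows of the model's training length are slid with the given step
#' (a prediction-time knob trading run time against accuracy: a smaller
#' step can only raise aggregated probabilities).  For every position
#' and class the result holds the maximum probability over all windows
#' covering the position; rows therefore need not sum to 1.  Padded
#' window rows (sequences shorter than a window) are ignored.
#'
#' @param model A `repeatnet_model`.
#' @param seq A `dna_sequence` or raw string (trimmed internally).
#' @param step Window step in bp.
#' @param batch_size Windows evaluated per batch.
#' @return `n x 5` matrix of aggregated probabilities (n = trimmed
#'   length), with the trim offset in `attr(, "origin")`.
#' @export
predict_sequence <- function(model, seq, step = 50L, batch_size = 64L) {
  seq <- as_dna_sequence(seq)
  n <- nchar(seq$bases)
  w <- model$config$window_length
  track <- matrix(0, nrow = n, ncol = 5L,
                  dimnames = list(NULL, names(REPEAT_CLASSES)))
  attr(track, "origin") <- seq$origin
  if (n == 0L) return(track)
  enc <- one_hot_encode(seq$bases)
  starts <- make_windows(n, w, step)$starts
  for (i in seq(1L, length(starts), by = batch_size)) {
    s <- starts[i:min(i + batch_size - 1L, length(starts))]
    xs <- encode_window_batch(enc, s, w)
    probs <- cpp_nn_predict(model$params, xs$xf, xs$xr)  # B x 5 x T
    for (j in seq_along(s)) {
      hi <- min(s[j] + w, n)
      len <- hi - s[j]
      rows <- (s[j] + 1L):hi
      p <- t(probs[j, , seq_len(len), drop = TRUE])
      if (len == 1L) p <- matrix(probs[j, , 1L], nrow = 1L)
      track[rows, ] <- pmax(track[rows, , drop = FALSE], p)
    }
  }
  track
}

#' Dump an aggregated track as tab-separated text
#'
#' Debugging aid: position (0-based) plus the five aggregated class
#' probabilities per line.
#'
#' @param track Matrix from [predict_sequence()].
#' @param path Output path.
#' @export
write_track <- function(track, path) {
  df <- data.frame(position = seq_len(nrow(track)) - 1L,
                   round(track, 6L))
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
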