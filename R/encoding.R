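# DNA -> dual-strand one-hot windowed representation.  Column order of the
# one-hot encoding is fixed as A, C, G, T, N; the fifth column exists only
# to represent unresolved bases.

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

#' Trim terminal N stretches from a raw sequence
#'
#' Leading and trailing maximal runs of `N` are removed; the number of
#' leading `N`s removed is kept as the `origin` offset so predictions can
#' be reported in the untrimmed coordinate system.  Internal `N`s are
#' preserved.
#'
#' @param raw Character scalar over `{A,C,G,T,N}` (lowercase accepted).
#' @return A `dna_sequence`: list with `bases` (string) and `origin`
#'   (0-based offset of `bases[1]` in `raw`).
#' @export
trim_n_stretches <- function(raw) {
  raw <- toupper(raw)
  if (nchar(raw) > 0L && grepl("[^ACGTN]", raw))
    stop("sequence contains symbols outside {A,C,G,T,N}")
  lead <- attr(regexpr("^N*", raw), "match.length")
  if (lead == nchar(raw)) {  # all N (or empty): empty sequence, origin = run
    return(structure(list(bases = "", origin = lead), class = "dna_sequence"))
  }
  trail <- attr(regexpr("N*$", raw), "match.length")
  bases <- substr(raw, lead + 1L, nchar(raw) - trail)
  structure(list(bases = bases, origin = lead), class = "dna_sequence")
}

#' @export
print.dna_sequence <- function(x, ...) {
  n <- nchar(x$bases)
  head <- substr(x$bases, 1L, 60L)
  cat(sprintf("<dna_sequence> %d bp, origin %d\n  %s%s\n", n, x$origin,
              head, if (n > 60L) "..." else ""))
  invisible(x)
}

as_dna_sequence <- function(x) {
  if (inherits(x, "dna_sequence")) x else trim_n_stretches(x)
}

#' Reverse complement
#'
#' `A<->T`, `C<->G`, `N->N`, order reversed.  An involution.
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return The reverse complement string.
#' @export
reverse_complement <- function(seq) {
  if (nchar(seq) == 0L) return(seq)
  comp <- chartr("ACGTN", "TGCAN", toupper(seq))
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' One-hot encode a DNA sequence
#'
#' @param seq Character scalar over `{A,C,G,T,N}`.
#' @return `n x 5` integer matrix with columns A, C, G, T, N; each row
#'   has exactly one 1.
#' @export
one_hot_encode <- function(seq) {
  n <- nchar(seq)
  m <- matrix(0L, nrow = n, ncol = 5L,
              dimnames = list(NULL, DNA_ALPHABET))
  if (n == 0L) return(m)
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1L]]
  idx <- match(chars, DNA_ALPHABET)
  if (anyNA(idx))
    stop("cannot encode symbol '", chars[which(is.na(idx))[1L]], "'")
  m[cbind(seq_len(n), idx)] <- 1L
  m
}

# Reverse-complement directly on an encoding: reverse rows, swap A<->T
# and C<->G columns.  Equals one_hot_encode(reverse_complement(seq)).
rc_encoding <- function(m) {
  if (nrow(m) == 0L) return(m)
  out <- m[rev(seq_len(nrow(m))), c(4L, 3L, 2L, 1L, 5L), drop = FALSE]
  colnames(out) <- DNA_ALPHABET
  out
}

#' Sliding-window layout over a sequence
#'
#' Windows of fixed length are slid with the given step.  If the last
#' regular window does not reach the end of the sequence, one extra
#' window is anchored at `n - window_length` so every position is
#' covered.  Sequences shorter than a window get a single window at 0,
#' padded with N rows on the right (padding is excluded from
#' aggregation).
#'
#' @param n Sequence length (bp).
#' @param window_length Window length (bp); fixed at training time
#'   (default 342).
#' @param step Step between window starts (bp); free at prediction time
#'   (default 50).
#' @return List with `window_length`, `step`, `starts` (0-based, strictly
#'   increasing) and `pad` (number of padded rows in the final window; 0
#'   unless `n < window_length`).
#' @export
make_windows <- function(n, window_length = 342L, step = 50L) {
  n <- as.integer(n); window_length <- as.integer(window_length)
  step <- as.integer(step)
  if (window_length < 1L) stop("window_length must be >= 1")
  if (step < 1L) stop("step must be >= 1")
  # a step beyond the window length would leave uncovered gaps; the
  # largest useful step is non-overlapping tiling
  if (step > window_length) step <- window_length
  if (n == 0L)
    return(list(window_length = window_length, step = step,
                starts = integer(0), pad = 0L))
  if (n < window_length)
    return(list(window_length = window_length, step = step,
                starts = 0L, pad = window_length - n))
  starts <- seq.int(0L, n - window_length, by = step)
  if (starts[length(starts)] + window_length < n)
    starts <- c(starts, n - window_length)
  list(window_length = window_length, step = step, starts = starts,
       pad = 0L)
}

# Slice window encodings out of a precomputed one-hot matrix `enc`
# (n x 5) into the B x 5 x T arrays the network consumes.  Rows beyond
# the sequence end are N-padded.  `augment_rate` > 0 substitutes each
# non-N base with probability augment_rate by a random other base
# (training-time noise; the reverse-complement stream sees the same
# perturbed window so the strands stay consistent).  Returns
# list(xf, xr).
encode_window_batch <- function(enc, starts, window_length,
                                augment_rate = 0) {
  b <- length(starts)
  n <- nrow(enc)
  xf <- array(0, dim = c(b, 5L, window_length))
  xr <- array(0, dim = c(b, 5L, window_length))
  for (i in seq_len(b)) {
    s <- starts[i]
    hi <- min(s + window_length, n)
    w <- matrix(0L, nrow = window_length, ncol = 5L)
    w[, 5L] <- 1L  # pad rows encode N
    if (hi > s) w[seq_len(hi - s), ] <- enc[(s + 1L):hi, , drop = FALSE]
    if (augment_rate > 0) {
      base_idx <- max.col(w, ties.method = "first")
      flip <- which(stats::runif(window_length) < augment_rate &
                      base_idx < 5L)
      if (length(flip) > 0L) {
        shift <- sample.int(3L, length(flip), replace = TRUE)
        new_idx <- 1L + (base_idx[flip] - 1L + shift) %% 4L
        w[flip, ] <- 0L
        w[cbind(flip, new_idx)] <- 1L
      }
    }
    xf[i, , ] <- t(w)
    xr[i, , ] <- t(rc_encoding(w))
  }
  list(xf = xf, xr = xr)
}
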