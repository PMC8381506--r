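# From aggregated probabilities to classified repeat segments: signed
# logit scores, maximum scoring segments with min-score/X-drop, majority
# class inheritance, splitting, and the length filter.

#' Default segmentation parameters
#'
#' `min_score` and `xdrop` defaults are stand-ins expressed in units of
#' the capped position score ln(99) (the score of a position predicted
#' with probability >= 0.99): a segment must accumulate at least five
#' saturated positions' worth of score, and an extension survives a dip
#' of up to ten.
#'
#' @param min_score Segments scoring below this are discarded.
#' @param xdrop Extension stops when the running score falls more than
#'   this below the running maximum; `Inf` disables the rule.
#' @param min_length Segments must be strictly longer than this (bp).
#' @return An `mss_params` list.
#' @export
mss_params <- function(min_score = 5 * log(99), xdrop = 10 * log(99),
                       min_length = 50L) {
  stopifnot(xdrop >= 0)
  structure(list(min_score = min_score, xdrop = xdrop,
                 min_length = as.integer(min_length)),
            class = "mss_params")
}

#' Convert aggregated probabilities to signed position scores
#'
#' Per position: `q = min(max_c p_c, 0.99)` (the cap avoids the logit
#' singularity at 1), `c = argmax_c p_c` (ties to the smallest class
#' id), and
#' `s = logit(q)` if `c` is a repeat class, `s = -10 * logit(q)` if `c`
#' is the no-repeat class — the factor 10 penalizes extending segments
#' across confidently non-repetitive positions.  Natural logarithm
#' throughout.
#'
#' @param track `n x 5` matrix of aggregated probabilities.
#' @return Data frame with `q`, `class_id` (`c_i`) and `score` (`s_i`)
#'   per position.
#' @export
probabilities_to_scores <- function(track) {
  if (!is.matrix(track) || ncol(track) != 5L)
    stop("track must be an n x 5 matrix")
  if (nrow(track) == 0L)
    return(data.frame(q = numeric(0), class_id = integer(0),
                      score = numeric(0)))
  cls <- max.col(track, ties.method = "first") - 1L  # smallest id wins ties
  q <- pmin(track[cbind(seq_len(nrow(track)), cls + 1L)], 0.99)
  q <- pmax(q, 1e-12)  # keep scores finite on degenerate all-zero rows
  s <- log(q / (1 - q))
  s[cls == 0L] <- -10 * s[cls == 0L]
  data.frame(q = q, class_id = cls, score = s)
}

#' All maximal scoring segments with min-score threshold and X-drop
#'
#' The classic all-maximal-scoring-subsequences algorithm (linear scan
#' with a stack of candidate subsequences and suffix merging) extended
#' by two rules: segments whose total score is below `min_score` are
#' discarded, and whenever the cumulative score falls more than `xdrop`
#' below its maximum since the last such event, the pending candidates
#' are finalized and never merged with later segments.  With
#' `xdrop = Inf`, `min_score = -Inf` the result is exactly the classic
#' disjoint decomposition.
#'
#' @param scores Numeric vector of finite position scores.
#' @param params An [mss_params()] (`min_length` is not applied here).
#' @return Data frame of disjoint intervals, ascending: `start`, `end`
#'   (0-based half-open) and `score` (sum of member scores).
#' @export
max_scoring_segments <- function(scores, params = mss_params()) {
  n <- length(scores)
  if (n > 0L && !all(is.finite(scores)))
    stop("scores must be finite (position ",
         which(!is.finite(scores))[1L], ")")
  # preallocated stack of candidate subsequences: positions [st, en) and
  # cumulative scores L (before st) and R (after en); `top` is the depth
  st <- integer(n); en <- integer(n); L <- numeric(n); R <- numeric(n)
  top <- 0L
  emitted <- list()
  cum <- 0; maxcum <- 0
  flush <- function() {
    if (top > 0L) {
      idx <- seq_len(top)
      keep <- (R[idx] - L[idx]) >= params$min_score
      if (any(keep))
        emitted[[length(emitted) + 1L]] <<- data.frame(
          start = st[idx][keep], end = en[idx][keep],
          score = (R[idx] - L[idx])[keep])
      top <<- 0L
    }
  }
  for (i in seq_len(n)) {
    s <- scores[i]
    if (s > 0) {
      # new candidate [i-1, i); then Ruzzo-Tompa merge loop
      k_st <- i - 1L; k_en <- i; k_L <- cum; k_R <- cum + s
      repeat {
        j <- top
        while (j >= 1L && L[j] >= k_L) j <- j - 1L  # nearest L_j < L_k
        if (j == 0L || R[j] >= k_R) {
          top <- top + 1L
          st[top] <- k_st; en[top] <- k_en; L[top] <- k_L; R[top] <- k_R
          break
        }
        # merge candidates j..top into the new one and retry
        k_st <- st[j]; k_L <- L[j]
        top <- j - 1L
      }
    }
    cum <- cum + s
    if (cum > maxcum) maxcum <- cum
    if (maxcum - cum > params$xdrop) {
      flush()
      cum <- 0; maxcum <- 0
    }
  }
  flush()
  if (length(emitted) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  out <- do.call(rbind, emitted)
  rownames(out) <- NULL
  out
}

#' Assign one repeat class to each raw segment
#'
#' Inside each segment, positions whose argmax class is no-repeat
#' inherit the repeat class occurring most often in the segment (ties to
#' the smallest class id); segments containing more than one repeat
#' class are then split so that each maximal single-class run becomes
#' its own segment, with its score recomputed as the sum of its member
#' position scores.  Segments with no repeat-class position at all are
#' dropped with a warning.
#'
#' @param raw_segments Data frame from [max_scoring_segments()].
#' @param scored Data frame from [probabilities_to_scores()] covering
#'   the same positions.
#' @return Data frame of classified segments: `start`, `end`,
#'   `class_id`, `class_name`, `score`, `length`.
#' @export
classify_segments <- function(raw_segments, scored) {
  empty <- data.frame(start = integer(0), end = integer(0),
                      class_id = integer(0), class_name = character(0),
                      score = numeric(0), length = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(raw_segments) || nrow(raw_segments) == 0L) return(empty)
  if (max(raw_segments$end) > nrow(scored))
    stop("segment exceeds scored range")
  pieces <- list()
  n_dropped <- 0L
  for (i in seq_len(nrow(raw_segments))) {
    rows <- (raw_segments$start[i] + 1L):raw_segments$end[i]
    cls <- scored$class_id[rows]
    sc <- scored$score[rows]
    nz <- cls[cls > 0L]
    if (length(nz) == 0L) {
      n_dropped <- n_dropped + 1L
      next
    }
    maj <- which.max(tabulate(nz, nbins = 4L))  # first max = smallest id
    cls[cls == 0L] <- maj
    runs <- rle(cls)
    ends <- cumsum(runs$lengths)
    starts <- ends - runs$lengths + 1L
    pieces[[length(pieces) + 1L]] <- data.frame(
      start = raw_segments$start[i] + starts - 1L,
      end = raw_segments$start[i] + ends,
      class_id = runs$values,
      class_name = repeat_class_name(runs$values),
      score = vapply(seq_along(runs$values),
                     function(k) sum(sc[starts[k]:ends[k]]), 0),
      length = runs$lengths,
      stringsAsFactors = FALSE)
  }
  if (n_dropped > 0L)
    warning("dropped ", n_dropped,
            " segment(s) with no repeat-class position")
  if (length(pieces) == 0L) return(empty)
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}

#' Filter segments by length
#'
#' Keeps segments strictly longer than `min_length` (default 50 bp).
#'
#' @param segments Data frame with a `length` column (or `start`/`end`).
#' @param min_length Length threshold in bp.
#' @return The filtered data frame.
#' @export
filter_by_length <- function(segments, min_length = 50L) {
  if (is.null(segments) || nrow(segments) == 0L) return(segments)
  len <- if ("length" %in% names(segments)) segments$length
         else segments$end - segments$start
  segments[len > min_length, , drop = FALSE]
}

#' Full track-to-segments pipeline
#'
#' Scores the track, extracts maximum scoring segments, classifies and
#' splits them, and applies the length filter.
#'
#' @param track `n x 5` aggregated probability matrix.
#' @param params An [mss_params()].
#' @return Data frame of classified segments (0-based half-open, in the
#'   track's coordinate system).
#' @export
call_segments <- function(track, params = mss_params()) {
  scored <- probabilities_to_scores(track)
  raw <- max_scoring_segments(scored$score, params)
  seg <- classify_segments(raw, scored)
  out <- filter_by_length(seg, params$min_length)
  rownames(out) <- NULL
  out
}
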