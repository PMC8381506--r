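# Independent reference implementations and small fixture builders used
# across the test files.  These deliberately take different routes than
# the package code they check.

# All maximal scoring subsequences by recursive extraction: find the
# maximum-sum interval by exhaustive enumeration, then recurse on the
# flanks.  On score vectors with distinct interval sums (random reals)
# this equals the classic disjoint decomposition.
rt_oracle <- function(scores) {
  find <- function(lo, hi) {
    if (lo > hi) return(NULL)
    best_sum <- 0; best_i <- 0L; best_j <- -1L
    for (i in lo:hi) {
      s <- 0
      for (j in i:hi) {
        s <- s + scores[j]
        if (s > best_sum) { best_sum <- s; best_i <- i; best_j <- j }
      }
    }
    if (best_j < best_i) return(NULL)
    rbind(find(lo, best_i - 1L),
          data.frame(start = best_i - 1L, end = best_j,
                     score = best_sum),
          find(best_j + 1L, hi))
  }
  out <- find(1L, length(scores))
  if (is.null(out))
    out <- data.frame(start = integer(0), end = integer(0),
                      score = numeric(0))
  rownames(out) <- NULL
  out
}

# Transparent quadratic reference for the min-score/X-drop semantics:
# same operational contract as the package implementation, but with
# interval sums recomputed from scratch and a plain list of candidates.
mss_reference <- function(scores, min_score, xdrop) {
  n <- length(scores)
  seg_sum <- function(a, b) if (a > b) 0 else sum(scores[a:b])
  out <- list(); cand <- list()   # cand: list of c(st, en), 1-based incl.
  r0 <- 1L                         # first position since last flush
  emit <- function() {
    for (cd in cand) {
      sc <- seg_sum(cd[1L], cd[2L])
      if (sc >= min_score)
        out[[length(out) + 1L]] <<- data.frame(start = cd[1L] - 1L,
                                               end = cd[2L], score = sc)
    }
    cand <<- list()
  }
  for (i in seq_len(n)) {
    if (scores[i] > 0) {
      k <- c(i, i)
      repeat {
        kL <- seg_sum(r0, k[1L] - 1L)
        kR <- kL + seg_sum(k[1L], k[2L])
        j <- 0L
        if (length(cand) > 0L)
          for (jj in length(cand):1L)
            if (seg_sum(r0, cand[[jj]][1L] - 1L) < kL) { j <- jj; break }
        if (j == 0L ||
            seg_sum(r0, cand[[j]][2L]) >= kR) {
          cand[[length(cand) + 1L]] <- k
          break
        }
        k <- c(cand[[j]][1L], k[2L])
        cand <- cand[seq_len(j - 1L)]
      }
    }
    cum <- seg_sum(r0, i)
    maxcum <- max(0, vapply(r0:i, function(m) seg_sum(r0, m), 0))
    if (maxcum - cum > xdrop) {
      emit()
      r0 <- i + 1L
    }
  }
  emit()
  if (length(out) == 0L)
    return(data.frame(start = integer(0), end = integer(0),
                      score = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

# Gorodkin's multi-class correlation via covariances of the indicator
# matrices (a formula-direct second route, using stats::cov).
mcc_cov_oracle <- function(pred, gold) {
  X <- sapply(0:4, function(k) as.numeric(gold == k))
  Y <- sapply(0:4, function(k) as.numeric(pred == k))
  cxy <- sum(sapply(1:5, function(k) stats::cov(X[, k], Y[, k])))
  cxx <- sum(sapply(1:5, function(k) stats::cov(X[, k], X[, k])))
  cyy <- sum(sapply(1:5, function(k) stats::cov(Y[, k], Y[, k])))
  cxy / sqrt(cxx * cyy)
}

random_dna_string <- function(n) {
  paste(sample(c("A", "C", "G", "T", "N"), n, replace = TRUE,
               prob = c(0.24, 0.24, 0.24, 0.24, 0.04)), collapse = "")
}

write_toy_fasta <- function(seqs, path = tempfile(fileext = ".fa")) {
  lines <- unlist(lapply(names(seqs), function(nm)
    c(paste0(">", nm), seqs[[nm]])))
  writeLines(lines, path)
  path
}

# Minimal RepeatMasker .out: 3 header lines then whitespace columns with
# 1-based inclusive coordinates in fields 6/7, repeat name in field 10.
write_toy_rm_out <- function(records, path = tempfile(fileext = ".out")) {
  header <- c(
    "   SW  perc perc perc  query     position in query    matching repeat",
    "score  div. del. ins.  sequence  begin end (left)     repeat class/family",
    "")
  body <- sprintf("  225 10.0  0.0  0.0  %s %d %d (0) + %s %s 1 100 (0) 1",
                  records$sequence_name, records$start + 1L, records$end,
                  records$repname, records$family)
  writeLines(c(header, body), path)
  path
}

# A small untrained but seeded model for inference-level properties.
tiny_model <- function(window_length = 40L, units = 6L, seed = 7L) {
  build_model(model_config(recurrent_units = units, attention_units = 4L,
                           window_length = window_length), seed = seed)
}

# Batch encodings for explicit windows of a sequence string.
window_batch <- function(seq, starts, window_length) {
  enc <- one_hot_encode(seq)
  repeatnet:::encode_window_batch(enc, starts, window_length)
}
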