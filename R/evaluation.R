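# Per-base and boundary-level comparison of a prediction against a gold
# annotation: confusion matrices, set-theoretic FPR/FNR, multi-class and
# one-vs-rest Matthews correlation, and delta-tolerant boundary matching.

#' Confusion matrix of two label tracks
#'
#' @param pred,gold Integer label tracks of equal length (values 0..4).
#' @return 5 x 5 integer matrix, rows = gold class, columns = predicted
#'   class, with a `"normalized"` attribute holding the rows divided by
#'   the gold class totals (NaN rows for absent classes).
#' @export
confusion <- function(pred, gold) {
  if (length(pred) != length(gold))
    stop("pred and gold tracks differ in length (", length(pred),
         " vs ", length(gold), ")")
  lv <- 0:4
  counts <- table(factor(gold, levels = lv), factor(pred, levels = lv))
  m <- matrix(as.integer(counts), 5L, 5L,
              dimnames = list(gold = names(REPEAT_CLASSES),
                              pred = names(REPEAT_CLASSES)))
  attr(m, "normalized") <- m / rowSums(m)
  m
}

#' Per-base false positive / false negative rates for one class
#'
#' With `P_c` the predicted and `A_c` the annotated position sets of
#' class `c`: FPR = |P_c \\ A_c| / |A_not-c| and
#' FNR = |A_c \\ P_c| / |A_c|.  A rate whose denominator is zero is
#' returned as `NA`.
#'
#' @param pred,gold Integer label tracks of equal length.
#' @param class_id Repeat class id in 1..4 (0 is allowed and rates the
#'   no-repeat label like any other class).
#' @return List with `fpr` and `fnr`.
#' @export
class_rates <- function(pred, gold, class_id) {
  if (length(pred) != length(gold))
    stop("pred and gold tracks differ in length")
  in_p <- pred == class_id; in_a <- gold == class_id
  n_not_a <- sum(!in_a); n_a <- sum(in_a)
  list(fpr = if (n_not_a > 0) sum(in_p & !in_a) / n_not_a else NA_real_,
       fnr = if (n_a > 0) sum(in_a & !in_p) / n_a else NA_real_)
}

#' Multi-class Matthews correlation coefficient
#'
#' Gorodkin's generalization computed from the confusion counts:
#' `(c*s - sum t_k p_k) / sqrt((s^2 - sum p_k^2)(s^2 - sum t_k^2))`
#' with `c` the trace, `s` the total, `t_k` the gold and `p_k` the
#' predicted class totals.  Returns 0 when either variance term is 0
#' (a constant prediction or constant gold).
#'
#' @param conf Square confusion matrix (rows gold, columns predicted).
#' @return MCC in `[-1, 1]`.
#' @export
mcc_k <- function(conf) {
  conf <- matrix(as.numeric(conf), nrow(conf), ncol(conf))  # avoid integer overflow
  s <- sum(conf)
  if (s == 0) stop("empty confusion matrix")
  cc <- sum(diag(conf))
  t_k <- rowSums(conf); p_k <- colSums(conf)
  num <- cc * s - sum(t_k * p_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  if (den == 0) return(0)
  num / den
}

#' One-vs-rest binary MCC for a single class
#'
#' Collapses the joint 5-class prediction to class-c-vs-rest and
#' computes the binary MCC, matching the per-class evaluation scheme
#' applied to a single joint model.
#'
#' @param pred,gold Integer label tracks.
#' @param class_id Class id in 0..4.
#' @return Binary MCC.
#' @export
mcc_ovr <- function(pred, gold, class_id) {
  mcc_k(confusion(as.integer(pred == class_id),
                  as.integer(gold == class_id))[1:2, 1:2])
}

#' Boundary-tolerant segment matching
#'
#' A gold segment is recovered iff some predicted segment of the same
#' class differs by at most `delta` bp at both the start and the end
#' (inclusive).  Matching is one-to-one and greedy in coordinate order.
#'
#' @param pred_segments,gold_segments Data frames with `start`, `end`,
#'   `class_id`, sorted and non-overlapping.
#' @param delta Boundary tolerance in bp (default 50).
#' @return List with `sensitivity` (recovered gold / total gold) and
#'   `specificity` (matched predictions / total predictions); `NA` when
#'   the respective list is empty.
#' @export
boundary_match <- function(pred_segments, gold_segments, delta = 50L) {
  ng <- if (is.null(gold_segments)) 0L else nrow(gold_segments)
  np <- if (is.null(pred_segments)) 0L else nrow(pred_segments)
  if (ng == 0L || np == 0L)
    return(list(sensitivity = if (ng > 0) 0 else NA_real_,
                specificity = if (np > 0) 0 else NA_real_))
  used <- logical(np)
  matched <- 0L
  by_seq <- "sequence_name" %in% names(pred_segments) &&
    "sequence_name" %in% names(gold_segments)
  for (i in order(gold_segments$start)) {
    for (j in order(pred_segments$start)) {
      if (used[j]) next
      if (pred_segments$class_id[j] != gold_segments$class_id[i]) next
      if (by_seq &&
          pred_segments$sequence_name[j] != gold_segments$sequence_name[i])
        next
      if (abs(pred_segments$start[j] - gold_segments$start[i]) <= delta &&
          abs(pred_segments$end[j] - gold_segments$end[i]) <= delta) {
        used[j] <- TRUE
        matched <- matched + 1L
        break
      }
    }
  }
  list(sensitivity = matched / ng, specificity = sum(used) / np)
}

#' Segments to a per-position label track
#'
#' @param segments Data frame with `start`, `end`, `class_id`.
#' @param sequence_length Track length.
#' @return Integer label track.
#' @export
segments_to_label_track <- function(segments, sequence_length) {
  records_to_label_track(segments, sequence_length)
}

#' Full metrics report for a prediction
#'
#' @param pred,gold Integer label tracks of equal length.
#' @param pred_segments,gold_segments Optional segment data frames for
#'   boundary metrics.
#' @param delta Boundary tolerance in bp.
#' @return List with `confusion`, `mcc5`, per-class `rates` (FPR/FNR),
#'   per-class one-vs-rest `mcc2`, and (when segments are given)
#'   `boundary`.
#' @export
evaluate_prediction <- function(pred, gold, pred_segments = NULL,
                                gold_segments = NULL, delta = 50L) {
  conf <- confusion(pred, gold)
  rates <- lapply(1:4, function(c_id) class_rates(pred, gold, c_id))
  names(rates) <- names(REPEAT_CLASSES)[2:5]
  mcc2 <- vapply(1:4, function(c_id) mcc_ovr(pred, gold, c_id), 0)
  names(mcc2) <- names(REPEAT_CLASSES)[2:5]
  out <- list(confusion = conf, mcc5 = mcc_k(conf), rates = rates,
              mcc2 = mcc2)
  if (!is.null(pred_segments) && !is.null(gold_segments))
    out$boundary <- boundary_match(pred_segments, gold_segments, delta)
  out
}

#' Write a metrics report as structured text
#'
#' @param report List from [evaluate_prediction()].
#' @param path Output path.
#' @export
write_report <- function(report, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("mcc5 = %.6f", report$mcc5), con)
  for (nm in names(report$rates)) {
    r <- report$rates[[nm]]
    writeLines(sprintf("fpr_%s = %s", tolower(nm), format(r$fpr)), con)
    writeLines(sprintf("fnr_%s = %s", tolower(nm), format(r$fnr)), con)
  }
  for (nm in names(report$mcc2))
    writeLines(sprintf("mcc2_%s = %.6f", tolower(nm),
                       report$mcc2[[nm]]), con)
  if (!is.null(report$boundary)) {
    writeLines(sprintf("boundary_sensitivity = %s",
                       format(report$boundary$sensitivity)), con)
    writeLines(sprintf("boundary_specificity = %s",
                       format(report$boundary$specificity)), con)
  }
  writeLines("", con)
  writeLines("# confusion (rows = gold, cols = predicted)", con)
  utils::write.table(unclass(report$confusion), con, sep = "\t",
                     quote = FALSE, col.names = NA)
  invisible(path)
}
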