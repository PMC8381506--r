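test_that("confusion counts gold rows against prediction columns", {
  gold <- c(0L, 0L, 3L, 3L, 4L)
  expect_equal(unname(diag(confusion(gold, gold))), c(2L, 0L, 0L, 2L, 1L))
  m <- confusion(rep(0L, 5L), rep(3L, 5L))
  expect_equal(unname(m["ALU", "NOREP"]), 5L)
  expect_equal(sum(m), 5L)

  gold <- c(0L, 0L, 0L, 1L, 1L, 2L, 3L, 3L, 4L, 4L)
  pred <- c(0L, 1L, 0L, 1L, 0L, 2L, 3L, 4L, 4L, 4L)
  m <- confusion(pred, gold)
  expect_equal(unname(m["NOREP", ]), c(2L, 1L, 0L, 0L, 0L))
  expect_equal(unname(m["HSAT23", ]), c(1L, 1L, 0L, 0L, 0L))
  expect_equal(unname(m["ALU", ]), c(0L, 0L, 0L, 1L, 1L))
  expect_equal(unname(m["LINE1", "LINE1"]), 2L)
  expect_error(confusion(1:3, 1:4), "length")
})

test_that("class_rates implements the set-theoretic FPR/FNR", {
  gold <- c(rep(3L, 5L), rep(0L, 5L))
  perfect <- class_rates(gold, gold, 3L)
  expect_equal(perfect$fpr, 0)
  expect_equal(perfect$fnr, 0)
  # gold c at positions 0-4 of 10; pred c at 0-3 and 5
  pred <- c(rep(3L, 4L), 0L, 3L, rep(0L, 4L))
  r <- class_rates(pred, gold, 3L)
  expect_equal(r$fpr, 0.2)  # |P\A| = 1, |A_not| = 5
  expect_equal(r$fnr, 0.2)  # |A\P| = 1, |A| = 5
  # never-predicted class
  r <- class_rates(rep(0L, 10L), gold, 3L)
  expect_equal(r$fnr, 1.0)
  # undefined denominators flagged as NA
  expect_true(is.na(class_rates(gold, rep(0L, 10L), 3L)$fnr))
  expect_true(is.na(class_rates(gold, rep(3L, 10L), 3L)$fpr))
})

test_that("multi-class MCC matches the covariance formulation", {
  gold <- rep(0:4, times = c(30, 10, 10, 25, 25))
  expect_equal(mcc_k(confusion(gold, gold)), 1.0)
  set.seed(41)
  pred <- sample(0:4, length(gold), replace = TRUE)
  expect_equal(mcc_k(confusion(pred, gold)),
               mcc_cov_oracle(pred, gold), tolerance = 1e-12)
  expect_lt(abs(mcc_k(confusion(pred, gold))), 0.25)  # no-association limit
  # 3-class toy matrix embedded in 5 classes
  gold3 <- c(rep(0L, 6L), rep(1L, 6L), rep(2L, 6L))
  pred3 <- c(rep(0L, 5L), 1L, rep(1L, 4L), 2L, 0L, rep(2L, 4L), 0L, 1L)
  expect_equal(mcc_k(confusion(pred3, gold3)),
               mcc_cov_oracle(pred3, gold3), tolerance = 1e-12)
  # degenerate constant prediction -> 0 by convention
  expect_equal(mcc_k(confusion(rep(0L, 10L), gold[1:10])), 0)
  expect_error(mcc_k(matrix(0, 5, 5)), "empty")
})

test_that("MCC is invariant under joint row/column permutation", {
  set.seed(42)
  gold <- sample(0:4, 400, replace = TRUE)
  pred <- ifelse(stats::runif(400) < 0.7, gold,
                 sample(0:4, 400, replace = TRUE))
  m <- confusion(pred, gold)
  perm <- sample(5)
  expect_equal(mcc_k(m), mcc_k(unclass(m)[perm, perm]), tolerance = 1e-12)
})

test_that("FNR agrees with the confusion diagonal", {
  set.seed(43)
  gold <- sample(0:4, 500, replace = TRUE)
  pred <- ifelse(stats::runif(500) < 0.6, gold,
                 sample(0:4, 500, replace = TRUE))
  m <- confusion(pred, gold)
  for (c_id in 1:4) {
    t_c <- sum(gold == c_id)
    if (t_c == 0) next
    expect_equal(class_rates(pred, gold, c_id)$fnr,
                 1 - unclass(m)[c_id + 1L, c_id + 1L] / t_c)
  }
})

test_that("one-vs-rest MCC collapses the joint prediction per class", {
  gold <- rep(c(0L, 3L), each = 20L)
  pred <- gold; pred[c(1, 21)] <- c(3L, 0L)
  byhand <- mcc_cov_oracle(as.integer(pred == 3L), as.integer(gold == 3L))
  expect_equal(mcc_ovr(pred, gold, 3L), byhand, tolerance = 1e-12)
})

test_that("boundary matching honors the inclusive delta tolerance", {
  gold <- data.frame(start = c(100L, 500L), end = c(400L, 900L),
                     class_id = c(3L, 4L))
  same <- boundary_match(gold, gold, delta = 50L)
  expect_equal(same$sensitivity, 1)
  expect_equal(same$specificity, 1)

  shift51 <- transform(gold, start = start + 51L, end = end + 51L)
  off <- boundary_match(shift51, gold, delta = 50L)
  expect_equal(off$sensitivity, 0)
  expect_equal(off$specificity, 0)

  shift50 <- transform(gold, start = start + 50L, end = end + 50L)
  on <- boundary_match(shift50, gold, delta = 50L)
  expect_equal(on$sensitivity, 1)
  expect_equal(on$specificity, 1)

  # class mismatch never matches
  wrong <- transform(gold, class_id = c(4L, 3L))
  expect_equal(boundary_match(wrong, gold, delta = 50L)$sensitivity, 0)

  # greedy matching is one-to-one
  dup <- gold[c(1L, 1L), ]
  res <- boundary_match(dup, gold[1L, ], delta = 50L)
  expect_equal(res$specificity, 0.5)
})

test_that("evaluate_prediction assembles the full report", {
  gold <- rep(c(0L, 1L, 3L), times = c(50, 20, 30))
  report <- evaluate_prediction(gold, gold)
  expect_equal(report$mcc5, 1.0)
  expect_equal(report$rates$ALU$fnr, 0)
  expect_equal(unname(report$mcc2["HSAT23"]), 1.0)
  empty_pred <- rep(0L, length(gold))
  report <- evaluate_prediction(empty_pred, gold)
  expect_equal(report$rates$HSAT23$fnr, 1.0)
  expect_equal(report$rates$ALU$fnr, 1.0)
  path <- tempfile()
  write_report(report, path)
  expect_true(any(grepl("^mcc5 = ", readLines(path))))
})
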