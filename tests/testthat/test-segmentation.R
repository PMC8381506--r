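test_that("score transform matches the logit closed forms", {
  # max prob 0.5 gives score 0 on both branches
  t0 <- matrix(c(0.5, 0.2, 0.1, 0.1, 0.1), 1)        # argmax NOREP
  t1 <- matrix(c(0.2, 0.5, 0.1, 0.1, 0.1), 1)        # argmax HSAT23
  expect_equal(probabilities_to_scores(t0)$score, 0)
  expect_equal(probabilities_to_scores(t1)$score, 0)
  # saturated repeat probability is capped at 0.99 -> ln 99
  tcap <- matrix(c(0, 0, 0, 1, 0), 1)
  s <- probabilities_to_scores(tcap)
  expect_equal(s$q, 0.99)
  expect_equal(s$score, log(99))
  expect_equal(s$class_id, 3L)
  # confident no-repeat: -10 * ln 9
  tno <- matrix(c(0.9, 0.02, 0.02, 0.03, 0.03), 1)
  expect_equal(probabilities_to_scores(tno)$score, -10 * log(9))
})

test_that("score transform is monotone in q on both branches", {
  qs <- seq(0.05, 0.99, by = 0.01)
  rep_scores <- vapply(qs, function(q)
    probabilities_to_scores(matrix(c(1 - q, q, 0, 0, 0) / 1, 1))$score, 0)
  expect_true(all(diff(rep_scores) > 0))
  norep_scores <- vapply(qs[qs > 0.5], function(q)
    probabilities_to_scores(matrix(c(q, 1 - q, 0, 0, 0), 1))$score, 0)
  expect_true(all(diff(norep_scores) < 0))
})

test_that("argmax ties break to the smallest class id", {
  t2 <- matrix(c(0.1, 0.4, 0.4, 0.05, 0.05), 1)
  expect_equal(probabilities_to_scores(t2)$class_id, 1L)
  t3 <- matrix(rep(0.2, 5), 1)
  expect_equal(probabilities_to_scores(t3)$class_id, 0L)
})

test_that("max_scoring_segments reproduces the worked examples", {
  expect_equal(nrow(max_scoring_segments(c(-1, -2, -0.5),
                                         mss_params(min_score = -Inf,
                                                    xdrop = Inf))), 0L)
  got <- max_scoring_segments(c(2, -1, 3),
                              mss_params(min_score = 1, xdrop = 100))
  expect_equal(got, data.frame(start = 0L, end = 3L, score = 4))
  got <- max_scoring_segments(c(5, -10, 5),
                              mss_params(min_score = 1, xdrop = 3))
  expect_equal(got, data.frame(start = c(0L, 2L), end = c(1L, 3L),
                               score = c(5, 5)))
  expect_equal(nrow(max_scoring_segments(numeric(0), mss_params())), 0L)
  expect_error(max_scoring_segments(c(1, NaN), mss_params()), "finite")
})

test_that("with xdrop = Inf the segmentation equals the classic decomposition", {
  relaxed <- mss_params(min_score = -Inf, xdrop = Inf)
  set.seed(31)
  for (i in 1:300) {
    scores <- stats::runif(sample.int(60, 1), -10, 10)
    got <- max_scoring_segments(scores, relaxed)
    expect_equal(got, rt_oracle(scores), tolerance = 1e-9)
  }
})

test_that("finite xdrop/min_score matches the quadratic reference", {
  set.seed(32)
  for (i in 1:150) {
    scores <- stats::runif(sample.int(50, 1), -10, 10)
    ms <- stats::runif(1, 0, 8)
    xd <- stats::runif(1, 0, 15)
    got <- max_scoring_segments(scores, mss_params(min_score = ms,
                                                   xdrop = xd))
    expect_equal(got, mss_reference(scores, ms, xd), tolerance = 1e-9)
  }
})

test_that("segment output is sorted and non-overlapping", {
  set.seed(33)
  for (i in 1:30) {
    scores <- stats::runif(200, -4, 4)
    got <- max_scoring_segments(scores, mss_params(min_score = 1,
                                                   xdrop = 6))
    if (nrow(got) > 1L) {
      expect_true(all(diff(got$start) > 0))
      expect_true(all(got$start[-1] >= got$end[-nrow(got)]))
    }
    expect_true(all(got$end > got$start))
  }
})

scored_from_classes <- function(cls, score = 1) {
  data.frame(q = 0.9, class_id = cls, score = rep(score, length(cls)))
}

test_that("classify_segments inherits the majority class and splits runs", {
  alu <- 3L; l1 <- 4L
  sc <- scored_from_classes(c(alu, alu, 0L, alu))
  got <- classify_segments(data.frame(start = 0L, end = 4L, score = 4), sc)
  expect_equal(got$start, 0L)
  expect_equal(got$end, 4L)
  expect_equal(got$class_id, alu)

  sc <- scored_from_classes(c(alu, alu, 0L, l1, l1, l1))
  got <- classify_segments(data.frame(start = 0L, end = 6L, score = 6), sc)
  expect_equal(got$start, c(0L, 2L))
  expect_equal(got$end, c(2L, 6L))
  expect_equal(got$class_id, c(alu, l1))
  expect_equal(got$score, c(2, 4))  # recomputed per split segment

  sc <- scored_from_classes(alu)
  got <- classify_segments(data.frame(start = 0L, end = 1L, score = 1), sc)
  expect_equal(got$class_id, alu)
  expect_equal(got$length, 1L)
})

test_that("classify_segments drops all-no-repeat segments with a warning", {
  sc <- scored_from_classes(c(0L, 0L, 0L))
  expect_warning(got <- classify_segments(
    data.frame(start = 0L, end = 3L, score = 3), sc),
    "no repeat-class position")
  expect_equal(nrow(got), 0L)
})

test_that("classification conserves covered bp and majority ties pick smallest id", {
  set.seed(34)
  for (i in 1:20) {
    n <- sample(10:60, 1)
    cls <- sample(0:4, n, replace = TRUE, prob = c(0.3, rep(0.175, 4)))
    if (all(cls == 0L)) cls[1] <- 1L
    sc <- scored_from_classes(cls)
    raw <- data.frame(start = 0L, end = n, score = n)
    got <- classify_segments(raw, sc)
    expect_equal(sum(got$end - got$start), n)
    expect_true(all(diff(got$start) > 0))
  }
  # explicit tie: one ALU, one LINE1 -> positions relabel to ALU (smaller id)
  sc <- scored_from_classes(c(3L, 0L, 4L))
  got <- classify_segments(data.frame(start = 0L, end = 3L, score = 3), sc)
  expect_equal(got$class_id, c(3L, 4L))
  expect_equal(got$end - got$start, c(2L, 1L))
})

test_that("filter_by_length keeps segments strictly longer than the threshold", {
  seg <- data.frame(start = c(0L, 100L), end = c(50L, 151L),
                    class_id = c(1L, 2L), score = c(1, 2),
                    length = c(50L, 51L))
  expect_equal(filter_by_length(seg, 50L)$length, 51L)
  expect_equal(nrow(filter_by_length(seg, 0L)), 2L)
  expect_equal(nrow(filter_by_length(seg[0, ], 50L)), 0L)
})
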