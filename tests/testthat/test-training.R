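# Batch composition floors, early-stopping bookkeeping, and seeded
# training behaviour on a miniature model.

make_pool <- function(labels, w = 20L, step = 5L) {
  training_windows(labels, window_length = w, step = step)
}

# A label track where every class is present but with very different
# abundances (LINE1 common, HSAT23 rare).
skewed_labels <- function(n = 2000L) {
  lab <- integer(n)
  lab[1:60] <- 1L
  lab[201:320] <- 2L
  lab[501:800] <- 3L
  lab[1001:1800] <- 4L
  lab
}

test_that("training_windows records which classes a window contains", {
  lab <- c(rep(0L, 10L), rep(3L, 5L), rep(0L, 10L))
  pool <- make_pool(lab, w = 10L, step = 5L)
  expect_equal(pool$start, c(0L, 5L, 10L, 15L))
  # ALU occupies positions 10..14, so windows at 5 and 10 contain it
  expect_equal(pool$has_3, c(FALSE, TRUE, TRUE, FALSE))
  expect_equal(pool$any_repeat, pool$has_3)
})

test_that("compose_batch honors the repeat and per-class floors", {
  pool <- make_pool(skewed_labels())
  for (r in c(0, 0.25, 0.5, 1)) {
    set.seed(100 + r * 100)
    for (rep_i in 1:25) {
      idx <- compose_batch(pool, n = 16L, r = r)
      expect_length(idx, 16L)
      expect_gte(sum(pool$any_repeat[idx]), floor(16 * r))
      for (c_id in 1:4)
        expect_gte(sum(pool[[paste0("has_", c_id)]][idx]),
                   floor(16 * r / 4))
    }
  }
})

test_that("compose_batch with r = 0 imposes no constraint", {
  pool <- make_pool(skewed_labels())
  set.seed(101)
  idx <- compose_batch(pool, n = 8L, r = 0)
  expect_length(idx, 8L)
})

test_that("compose_batch fails naming the class it cannot satisfy", {
  lab <- skewed_labels()
  lab[lab == 2L] <- 0L  # remove ALPHOID entirely
  pool <- make_pool(lab)
  set.seed(102)
  expect_error(compose_batch(pool, n = 16L, r = 1), "ALPHOID")
})

test_that("rare classes are enriched relative to their pool frequency", {
  pool <- make_pool(skewed_labels())
  pool_freq <- mean(pool$has_1)  # HSAT23 is the rarest
  set.seed(103)
  hits <- replicate(200, {
    idx <- compose_batch(pool, n = 16L, r = 0.5)
    mean(pool$has_1[idx])
  })
  expect_gte(mean(hits), pool_freq)
})

test_that("early stopping halts after a patience-long stall at the best epoch", {
  losses <- c(1.0, 0.9, rep(0.95, 10))
  expect_equal(repeatnet:::best_epoch(losses), 2L)
  expect_true(repeatnet:::should_stop(losses, patience = 10L))
  expect_false(repeatnet:::should_stop(c(1.0, 0.9, rep(0.95, 9)),
                                       patience = 10L))
  # improvement must be strictly lower than the best so far
  expect_true(repeatnet:::should_stop(c(1.0, 1.0, 1.0), patience = 2L))
  expect_false(repeatnet:::should_stop(c(1.0, 0.999), patience = 2L))
})

tiny_training_setup <- function(n = 1200L, seed = 55L) {
  set.seed(seed)
  seq <- paste(sample(c("A", "C", "G", "T"), n, TRUE), collapse = "")
  lab <- integer(n)
  lab[101:200] <- 1L; lab[301:400] <- 2L
  lab[501:650] <- 3L; lab[801:1000] <- 4L
  # make the repeat stretches compositionally distinct so the tiny
  # model has something to latch onto
  chars <- strsplit(seq, "")[[1]]
  chars[lab == 1L] <- "A"; chars[lab == 2L] <- "C"
  chars[lab == 3L] <- "G"; chars[lab == 4L] <- "T"
  list(seq = paste(chars, collapse = ""), lab = lab)
}

test_that("train runs one epoch when max_epochs = 1 and learns a toy signal", {
  d <- tiny_training_setup()
  m <- build_model(model_config(recurrent_units = 6L, attention_units = 4L,
                                window_length = 30L), seed = 1L)
  cfg <- train_config(batch_size = 8L, repeat_fraction = 0.5,
                      max_epochs = 1L, train_step = 10L,
                      batches_per_epoch = 5L, seed = 1L)
  fit <- train(m, d$seq, d$lab, d$seq, d$lab, cfg)
  expect_equal(nrow(fit$history), 1L)
  expect_true(all(is.finite(fit$history$train_loss)))
})

test_that("training is reproducible given the same seed and data", {
  d <- tiny_training_setup()
  cfg <- train_config(batch_size = 8L, repeat_fraction = 0.5,
                      max_epochs = 3L, train_step = 10L,
                      batches_per_epoch = 4L, seed = 9L)
  run <- function() {
    m <- build_model(model_config(recurrent_units = 5L,
                                  attention_units = 3L,
                                  window_length = 30L), seed = 2L)
    train(m, d$seq, d$lab, d$seq, d$lab, cfg)
  }
  f1 <- run(); f2 <- run()
  expect_equal(f1$history, f2$history)
  expect_equal(f1$model$params, f2$model$params)
})

test_that("the returned model carries the best-validation parameters", {
  d <- tiny_training_setup()
  m <- build_model(model_config(recurrent_units = 5L, attention_units = 3L,
                                window_length = 30L), seed = 4L)
  cfg <- train_config(batch_size = 8L, repeat_fraction = 0.25,
                      max_epochs = 6L, train_step = 10L,
                      batches_per_epoch = 4L, seed = 3L)
  fit <- train(m, d$seq, d$lab, d$seq, d$lab, cfg)
  best <- which.min(fit$history$val_loss)
  expect_lte(best, nrow(fit$history))
  # retraining up to the best epoch reproduces the returned parameters
  m2 <- build_model(model_config(recurrent_units = 5L, attention_units = 3L,
                                 window_length = 30L), seed = 4L)
  cfg2 <- cfg; cfg2$max_epochs <- best
  fit2 <- train(m2, d$seq, d$lab, d$seq, d$lab, cfg2)
  expect_equal(fit2$model$params, fit$model$params)
})
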