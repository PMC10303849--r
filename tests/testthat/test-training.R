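test_that("random splits cut at the requested fractions", {
  d <- labeled_dataset(
    tibble::tibble(id = sprintf("s%03d", 1:100),
                   sequence = random_dna(100, 20, seed = 1),
                   bound = rep(c(1, 0), 50)),
    task_type = "binary_multitask"
  )
  sp <- split_dataset(d, split_spec(), seed = 5)
  expect_equal(vapply(sp, nrow, integer(1)),
               c(train = 80L, val = 10L, test = 10L))
  expect_length(intersect(sp$train$id, sp$val$id), 0)
  expect_setequal(c(sp$train$id, sp$val$id, sp$test$id), d$id)
})

test_that("stratified splits preserve the class ratio within one record", {
  d <- labeled_dataset(
    tibble::tibble(id = sprintf("s%04d", 1:1000),
                   sequence = random_dna(1000, 15, seed = 2),
                   bound = rep(c(1, 0), each = 500)),
    task_type = "binary_multitask"
  )
  sp <- split_dataset(d, split_spec(stratify = TRUE), seed = 5)
  for (s in sp) {
    expect_lte(abs(sum(dataset_labels(s)) - nrow(s) / 2), 1)
  }
})

test_that("chromosome splits assign records by membership", {
  d <- labeled_dataset(
    tibble::tibble(id = sprintf("s%02d", 1:30),
                   sequence = random_dna(30, 15, seed = 3),
                   chrom = rep(c("chr1", "chr2", "chr10"), each = 10),
                   bound = rep(c(0, 1), 15)),
    task_type = "binary_multitask"
  )
  sp <- split_dataset(
    d, split_spec(mode = "by_chromosome", val_chroms = "chr1",
                  test_chroms = "chr10")
  )
  expect_setequal(unique(sp$train$chrom), "chr2")
  expect_setequal(unique(sp$val$chrom), "chr1")
  expect_setequal(unique(sp$test$chrom), "chr10")
  expect_error(split_spec(val_chroms = "chr1", test_chroms = "chr1"),
               "disjoint")
})

test_that("losses match hand-computed values", {
  # bce: preds (0, 1, -1, 2, -2) against labels (1, 1, 0, 0, 1)
  expect_equal(
    compute_loss(matrix(c(0, 1, -1, 2, -2)), matrix(c(1, 1, 0, 0, 1)),
                 "bce"),
    1.1147061, tolerance = 1e-6
  )
  expect_equal(compute_loss(matrix(c(1, 2, 3)), matrix(c(0, 2, 5)), "mse"),
               5 / 3, tolerance = 1e-12)
  # softmax cross-entropy: rows (1,0) vs class 1 and (0,0) vs class 2
  expect_equal(
    compute_loss(matrix(c(1, 0, 0, 0), 2, 2), matrix(c(1, 0, 0, 1), 2, 2),
                 "cross_entropy"),
    (0.3132617 + 0.6931472) / 2, tolerance = 1e-6
  )
  # perfect predictions
  expect_equal(compute_loss(matrix(c(30, -30)), matrix(c(1, 0)), "bce"), 0,
               tolerance = 1e-6)
  expect_identical(compute_loss(matrix(1:3), matrix(1:3), "mse"), 0)
})

test_that("reverse-complement augmentation doubles and closes the set", {
  d <- labeled_dataset(
    tibble::tibble(id = sprintf("s%03d", 1:100),
                   sequence = random_dna(100, 30, seed = 4),
                   bound = rep(c(0, 1), 50)),
    task_type = "binary_multitask"
  )
  aug <- seqnam:::rc_augmented(d)
  expect_equal(nrow(aug), 200)
  expect_setequal(aug$sequence, reverse_complement(aug$sequence))
  expect_equal(dataset_labels(aug)[1:100, ], dataset_labels(aug)[101:200, ])
})

test_that("training decreases the loss and stops per the patience rule", {
  toy <- toy_planted()
  m <- tiny_model(U = 4, L = 60, seed = 2)
  cfgt <- train_config(max_epochs = 8, patience = 3, seed = 5)
  fit <- train_model(m, toy$splits$train, toy$splits$val, cfgt)
  h <- fit$history
  expect_lt(tail(h$train_loss, 1), h$train_loss[1])
  expect_equal(fit$meta$best_val_loss, min(h$val_loss))
  expect_lte(nrow(h), 8)
  if (nrow(h) < 8) { # early-stopped: the final `patience` epochs are stale
    stale <- tail(h$val_loss, cfgt$patience)
    expect_true(all(stale >= fit$meta$best_val_loss))
    expect_equal(fit$meta$best_epoch, which.min(h$val_loss))
  }
})

test_that("training with equal seeds is bit-reproducible", {
  toy <- toy_planted()
  cfgt <- train_config(max_epochs = 2, seed = 11)
  f1 <- train_model(tiny_model(U = 2, L = 60, seed = 3),
                    toy$splits$train, toy$splits$val, cfgt)
  f2 <- train_model(tiny_model(U = 2, L = 60, seed = 3),
                    toy$splits$train, toy$splits$val, cfgt)
  expect_identical(f1$history, f2$history)
  expect_identical(f1$params, f2$params)
})

test_that("loss/task-type mismatches are rejected", {
  toy <- toy_planted()
  m <- tiny_model(U = 2, L = 60, seed = 3)
  expect_error(
    train_model(m, toy$splits$train, toy$splits$val,
                train_config(loss = "mse", max_epochs = 1)),
    "incompatible"
  )
})

test_that("quantile normalization is a rank-preserving uniform transform", {
  expect_equal(quantile_normalize(c(0.25, 0.5, 0.75, 1) * 4),
               c(0.125, 0.375, 0.625, 0.875))
  out <- quantile_normalize(c(10, 1000, 20))
  expect_identical(order(out), order(c(10, 1000, 20)))
  # ties share the average rank: (5, 5, 1) -> ranks (2.5, 2.5, 1)
  expect_equal(quantile_normalize(c(5, 5, 1)),
               c(2 / 3, 2 / 3, 1 / 6))
  expect_equal(quantile_normalize(rep(7, 5)), rep(0.5, 5))
  expect_error(quantile_normalize(c(1, NA)), "finite")
})
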