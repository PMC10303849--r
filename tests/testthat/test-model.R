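test_that("convolution/pooling geometry follows the valid-conv arithmetic", {
  expect_equal(conv_geometry(200, 19, 7, 7), list(conv_len = 182L,
                                                  pooled_len = 26L))
  expect_equal(conv_geometry(201, 19, 7, 7), list(conv_len = 183L,
                                                  pooled_len = 26L))
  expect_equal(conv_geometry(19, 19, 1, 1), list(conv_len = 1L,
                                                 pooled_len = 1L))
  expect_error(conv_geometry(19, 19, 7, 7), "pool_size")
  expect_error(seqnam_config(1, 19, 1), "pool_size 7")
})

test_that("unit head dimensions follow the configuration", {
  m <- build_model(seqnam_config(100, 200, 50), seed = 1)
  expect_equal(dim(m$params$W1), c(26, 100, 100)) # first FC input width 26
  m2 <- build_model(seqnam_config(4, 600, 12), seed = 1)
  expect_equal(dim(m2$params$W1)[1], 83)
  expect_equal(dim(m2$params$Wf), c(4, 12))
})

test_that("geometry matches the shapes observed in actual forward passes", {
  withr::with_seed(11, {
    for (i in 1:20) {
      L <- sample(30:200, 1)
      W <- sample(4:25, 1)
      if (L - W + 1 < 7) next
      geo <- conv_geometry(L, W, 7, 7)
      m <- build_model(seqnam_config(2, L, 1, filter_width = W), seed = i)
      X <- seqnam:::encode_batch(random_dna(3, L))
      fwd <- seqnam:::nn_forward(m, X, mode = "train", need_cache = TRUE)
      expect_equal(nrow(fwd$cache$bn1$xhat), 3 * geo$conv_len)
      expect_equal(ncol(fwd$cache$pool_mats[[1]]), geo$pooled_len)
    }
  })
})

test_that("equal seeds give equal parameters; different seeds differ", {
  a <- build_model(seqnam_config(3, 50, 2), seed = 42)
  b <- build_model(seqnam_config(3, 50, 2), seed = 42)
  c_ <- build_model(seqnam_config(3, 50, 2), seed = 43)
  expect_identical(a$params, b$params)
  expect_false(identical(a$params$filters, c_$params$filters))
})

test_that("predictions are exactly the linear combination of unit outputs", {
  m <- tiny_model(U = 4, L = 50, T_ = 3, seed = 2)
  seqs <- random_dna(20, 50, seed = 3)
  pr <- predict(m, seqs, units = TRUE)
  recon <- pr$unit_outputs %*% m$params$Wf +
    matrix(m$params$bf, 20, 3, byrow = TRUE)
  expect_lt(max(abs(pr$predictions - recon)), 1e-10)
  # zero weights: predictions collapse to the bias
  m$params$Wf[] <- 0
  m$params$bf <- c(0.3, -1, 2)
  p <- predict(m, seqs)
  expect_equal(p, matrix(c(0.3, -1, 2), 20, 3, byrow = TRUE))
})

test_that("plugged stub units feed the final layer directly", {
  m <- tiny_model(U = 2, L = 30, T_ = 1, seed = 5)
  m <- plug_unit(m, 1, function(x) 1.0, head = "none")
  m <- plug_unit(m, 2, function(x) 2.0, head = "none")
  m$params$Wf <- matrix(c(0.5, -1.0), 2, 1)
  m$params$bf <- 0.1
  p <- predict(m, random_dna(3, 30, seed = 1))
  expect_equal(as.vector(p), rep(-1.4, 3), tolerance = 1e-12)
})

test_that("an fc head transforms the plugged submodel output", {
  m <- tiny_model(U = 1, L = 30, seed = 5)
  m <- plug_unit(m, 1, function(x) 3.0, head = "fc_head_200", seed = 2)
  pr <- predict(m, random_dna(2, 30, seed = 1), units = TRUE)
  expect_false(isTRUE(all.equal(pr$unit_outputs[1, 1], 3.0)))
  # and model predictions are a linear map of stub outputs when head = none
  m2 <- tiny_model(U = 2, L = 30, seed = 6)
  m2 <- plug_unit(m2, 1, function(x) sum(x[, 1]), head = "none")
  m2 <- plug_unit(m2, 2, function(x) sum(x[, 3]), head = "none")
  seqs <- random_dna(10, 30, seed = 2)
  x1 <- vapply(seqs, function(s) sum(strsplit(s, "")[[1]] == "A"), numeric(1))
  x2 <- vapply(seqs, function(s) sum(strsplit(s, "")[[1]] == "G"), numeric(1))
  p <- predict(m2, seqs)[, 1]
  fit <- lm(p ~ x1 + x2)
  expect_lt(max(abs(residuals(fit))), 1e-8)
})

test_that("evaluation mode is deterministic", {
  m <- tiny_model(U = 3, L = 40, seed = 7)
  X <- seqnam:::encode_batch(random_dna(8, 40, seed = 8))
  e1 <- seqnam:::nn_eval(m, X)
  e2 <- seqnam:::nn_eval(m, X)
  expect_identical(e1$predictions, e2$predictions)
})

test_that("units are independent: perturbing one leaves the others fixed", {
  m <- tiny_model(U = 4, L = 60, seed = 9)
  seqs <- random_dna(100, 60, seed = 10)
  base <- predict(m, seqs, units = TRUE)$unit_outputs
  m2 <- m
  m2$params$filters[, 2] <- m2$params$filters[, 2] + 0.5
  m2$params$W1[, , 2] <- m2$params$W1[, , 2] * 2
  m2$params$W2[, 2] <- m2$params$W2[, 2] + 1
  pert <- predict(m2, seqs, units = TRUE)$unit_outputs
  expect_identical(base[, -2], pert[, -2])
  expect_false(identical(base[, 2], pert[, 2]))
})

test_that("the global-max-pool unit output is the max window activation", {
  m <- build_global_maxpool_variant(seqnam_config(1, 40, 1, filter_width = 7),
                                    seed = 3)
  seqs <- random_dna(5, 40, seed = 4)
  pr <- predict(m, seqs, units = TRUE)
  for (i in 1:5) {
    oracle <- max(naive_unit_activation(m, seqs[i]))
    expect_equal(pr$unit_outputs[i, 1], oracle, tolerance = 1e-10)
  }
  # zero filter: constant output across sequences
  m$params$filters[] <- 0
  pr0 <- predict(m, seqs, units = TRUE)$unit_outputs
  expect_equal(max(pr0) - min(pr0), 0)
})

test_that("nullifying a unit zeroes exactly its additive contribution", {
  m <- tiny_model(U = 3, L = 40, T_ = 2, seed = 12)
  seqs <- random_dna(15, 40, seed = 13)
  pr <- predict(m, seqs, units = TRUE)
  for (u in 1:3) {
    d <- predict(nullify_unit(m, u), seqs) - pr$predictions
    expected <- -outer(pr$unit_outputs[, u], m$params$Wf[u, ])
    expect_lt(max(abs(d - expected)), 1e-10)
  }
  # one-unit model collapses to the bias
  m1 <- tiny_model(U = 1, L = 40, seed = 1)
  m1$params$bf <- 0.7
  p <- predict(nullify_unit(m1, 1), seqs)
  expect_equal(as.vector(p), rep(0.7, 15))
  expect_error(nullify_unit(m1, 5), "out of range")
})

test_that("shape errors identify the offending sequence", {
  m <- tiny_model(U = 1, L = 40, seed = 1)
  expect_error(
    predict(m, tibble::tibble(id = c("ok", "bad"),
                              sequence = c(strrep("A", 40), "ACGT"))),
    "'bad' has length 4"
  )
})

test_that("checkpoints round-trip through save and load", {
  m <- tiny_model(U = 2, L = 30, seed = 14)
  path <- withr::local_tempfile(fileext = ".rds")
  save_model(m, path)
  m2 <- load_model(path)
  expect_identical(m$params, m2$params)
  expect_s3_class(m2, "seqnam_model")
  saveRDS(list(), path)
  expect_error(load_model(path), "schema_version")
})
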