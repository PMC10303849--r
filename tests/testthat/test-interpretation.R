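# A 1-unit model whose filter is set to the converted poly-A profile, with
# the final layer arranged so every sequence is predicted "bound": gives
# full control over which windows activate and which sequences qualify.
polyA_model <- function(L = 30, W = 7) {
  m <- build_model(seqnam_config(1, L, 1, filter_width = W), seed = 1)
  probs <- matrix(0.01 / 3, 4, W, dimnames = list(c("A", "C", "G", "T"), NULL))
  probs[1, ] <- 0.99
  m$params$filters[, 1] <- as.vector(probs - 0.25)
  m$params$Wf[] <- 0
  m$params$bf <- 5 # sigmoid(5) > 0.5: every sequence predicted positive
  m
}

test_that("activation maxima and argmax match a naive window scan", {
  m <- polyA_model()
  seqs <- c(
    paste0(strrep("C", 10), strrep("A", 7), strrep("G", 13)),
    random_dna(4, 30, seed = 2)
  )
  act <- collect_activations(m, seqs)
  for (i in seq_along(seqs)) {
    oracle <- naive_unit_activation(m, seqs[i])
    expect_equal(act$max[i, 1], max(oracle), tolerance = 1e-10)
    # the reported argmax attains the maximum (exact ties between equal-
    # scoring windows may resolve differently at float precision)
    expect_equal(oracle[act$pos[i, 1]], max(oracle), tolerance = 1e-10)
  }
  expect_equal(act$pos[1, 1], 11) # the planted poly-A window
  expect_equal(act$unit_max, max(act$max[, 1]))
})

test_that("argmax ties resolve to the lowest position", {
  m <- polyA_model()
  m$params$filters[] <- 0 # every window activates identically
  act <- collect_activations(m, random_dna(3, 30, seed = 3))
  expect_true(all(act$pos == 1L))
})

test_that("filter PFMs count the aligned argmax windows of qualifying sequences", {
  m <- polyA_model(L = 20, W = 4)
  seqs <- c(
    paste0("AAAA", strrep("C", 16)),
    paste0("CC", "AAAA", strrep("G", 14)),
    paste0(strrep("G", 10), "CAAA", strrep("T", 6))
  )
  d <- labeled_dataset(
    tibble::tibble(id = c("a", "b", "c"), sequence = seqs, bound = c(1, 1, 1)),
    task_type = "binary_multitask"
  )
  p <- filter_to_pfm(m, 1, d, fraction = 0) # all correct, all qualify
  expect_equal(p$n_sites, 3)
  expect_equal(colSums(p$counts), rep(3, 4)) # column sums = n_sites
  expect_equal(unname(p$counts[, 1]), c(2, 1, 0, 0)) # A:2 C:1 from hand count
  # fraction = 1 keeps only the sequence attaining the dataset-wide max
  act <- collect_activations(m, d)
  p1 <- filter_to_pfm(m, 1, d, activations = act, fraction = 1)
  expect_equal(p1$n_sites, sum(act$max[, 1] == act$unit_max))
})

test_that("no qualifying sequences flags an empty PFM", {
  m <- polyA_model(L = 20, W = 4)
  d <- labeled_dataset(
    tibble::tibble(id = c("a", "b"),
                   sequence = random_dna(2, 20, seed = 4),
                   bound = c(0, 0)), # predicted 1, labelled 0: all incorrect
    task_type = "binary_multitask"
  )
  p <- filter_to_pfm(m, 1, d)
  expect_true(attr(p, "empty"))
  expect_equal(p$n_sites, 0)
  expect_error(pfm_to_pwm(p), "no sites")
})

test_that("raising the activation fraction never increases n_sites", {
  toy <- toy_planted()
  m <- tiny_model(U = 2, L = 60, seed = 5)
  m <- train_model(m, toy$splits$train, toy$splits$val,
                   train_config(max_epochs = 3, seed = 6))
  act <- collect_activations(m, toy$splits$test)
  ns <- vapply(c(0, 0.25, 0.5, 0.75, 1), function(f) {
    filter_to_pfm(m, 1, toy$splits$test, activations = act,
                  fraction = f)$n_sites
  }, numeric(1))
  expect_true(all(diff(ns) <= 0))
})

test_that("unit importance is the median activation-weight product", {
  # stub unit with constant output 2.0 and weight 0.5: median product 1.0
  m <- tiny_model(U = 1, L = 30, seed = 1)
  m <- plug_unit(m, 1, function(x) 2.0, head = "none")
  m$params$Wf[] <- 0.5
  m$params$bf <- 5
  d <- labeled_dataset(
    tibble::tibble(id = "a", sequence = random_dna(1, 30, seed = 2),
                   bound = 1),
    task_type = "binary_multitask"
  )
  imp <- unit_importance(m, d, fraction = 0)
  expect_equal(imp$medians[1, 1], 1.0)
  # five hand-set activations: median of products, negative weight flips sign
  acts <- c(1, 2, 3, 4, 10)
  m5 <- tiny_model(U = 1, L = 30, seed = 1)
  counter <- local({
    i <- 0
    function(x) {
      i <<- i + 1
      acts[(i - 1) %% 5 + 1]
    }
  })
  m5 <- plug_unit(m5, 1, counter, head = "none")
  m5$params$Wf[] <- -0.5
  m5$params$bf <- 5
  d5 <- labeled_dataset(
    tibble::tibble(id = letters[1:5], sequence = random_dna(5, 30, seed = 3),
                   bound = rep(1, 5)),
    task_type = "binary_multitask"
  )
  imp5 <- unit_importance(m5, d5, fraction = 0)
  expect_equal(imp5$medians[1, 1], median(acts * -0.5)) # = -1.5
  expect_lt(imp5$medians[1, 1], 0)
})

test_that("empty qualifying sets flag an undefined median, not zero", {
  m <- polyA_model(L = 20, W = 4)
  d <- labeled_dataset(
    tibble::tibble(id = c("a", "b"),
                   sequence = random_dna(2, 20, seed = 5),
                   bound = c(0, 0)),
    task_type = "binary_multitask"
  )
  imp <- unit_importance(m, d)
  expect_true(is.na(imp$medians[1, 1]))
  expect_equal(imp$n_qualifying[1, 1], 0L)
})

test_that("internal annotation finds self and reverse-complement matches", {
  dm <- demo_motifs(c("GATA_SYN", "EBOX_SYN"))
  ann <- annotate_units(list(dm$GATA_SYN), dm)
  expect_equal(ann$motif_id[1], "GATA_SYN")
  expect_equal(ann$similarity[1], 1.0)
  rcq <- reverse_complement_pwm(dm$GATA_SYN)
  ann_rc <- annotate_units(list(rcq), dm)
  expect_equal(ann_rc$motif_id[1], "GATA_SYN")
  expect_equal(ann_rc$similarity[1], 1.0)
  expect_equal(ann_rc$strand[1], "-")
  # a uniform query has no defined correlation with anything
  unif <- pwm_from_probs(matrix(0.25, 4, 8), id = "unif")
  expect_equal(nrow(annotate_units(list(unif), dm)), 0)
})

test_that("final-layer weights round-trip and expose the linear map", {
  m <- tiny_model(U = 2, L = 30, T_ = 3, seed = 4)
  fl <- final_layer_weights(m)
  expect_equal(dim(fl$weights), c(2, 3))
  seqs <- random_dna(6, 30, seed = 5)
  pr <- predict(m, seqs, units = TRUE)
  expect_lt(max(abs(pr$predictions -
                      (pr$unit_outputs %*% fl$weights +
                         matrix(fl$bias, 6, 3, byrow = TRUE)))), 1e-10)
})
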