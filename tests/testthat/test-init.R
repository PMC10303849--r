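test_that("pfm_to_pwm follows the pseudocount arithmetic", {
  u <- pfm(matrix(10, 4, 3), id = "u")
  p <- pfm_to_pwm(u, pseudocount = 1)
  expect_equal(unname(p$probs), matrix(0.25, 4, 3))
  expect_equal(unname(p$log_odds), matrix(0, 4, 3))
  a <- pfm(matrix(c(3, 0, 0, 0), 4, 1), id = "a")
  pa <- pfm_to_pwm(a, pseudocount = 1)
  expect_equal(as.numeric(pa$probs[1, 1]), 3.25 / 4)
  expect_equal(as.numeric(pa$log_odds[1, 1]), log2(3.25),
               tolerance = 1e-9)
  withr::with_seed(5, {
    for (i in 1:20) {
      counts <- matrix(rpois(4 * 6, 5), 4, 6)
      pp <- pfm_to_pwm(pfm(counts, id = "x"))
      expect_equal(unname(colSums(pp$probs)), rep(1, 6), tolerance = 1e-12)
    }
  })
})

test_that("profile resizing pads with background and trims by information", {
  dm <- demo_motifs("GATA_SYN")[[1]]
  base <- pfm(dm$probs * 100, id = "g")
  expect_identical(resize_profile(resize_profile(base, 19), 19)$counts,
                   resize_profile(base, 19)$counts)
  # width 8 -> 19: padded columns are uniform
  r <- resize_profile(base, 19)
  expect_equal(ncol(r$counts), 19)
  lead <- floor((19 - 8) / 2)
  expect_equal(unname(r$counts[, 1]), rep(25, 4))
  expect_equal(unname(r$counts[, lead + 1]), unname(base$counts[, 1]))
  # odd parity: the extra background column goes to the right
  r18 <- resize_profile(pfm(matrix(1, 4, 17), id = "x"), 18)
  expect_equal(ncol(r18$counts), 18)
  # trim: information concentrated off-centre is found by the IC scan
  wide <- cbind(matrix(25, 4, 1), dm$probs * 100, matrix(25, 4, 1),
                matrix(25, 4, 1))
  w <- pfm(wide, id = "w") # width 11, info in columns 2..9
  tr <- resize_profile(w, 9)
  ic <- function(m) {
    p <- sweep(m, 2, colSums(m), "/")
    sum(2 + colSums(ifelse(p > 0, p * log2(p), 0)))
  }
  best_ic <- max(vapply(1:3, function(s) ic(wide[, s:(s + 8)]), numeric(1)))
  expect_equal(ic(tr$counts), best_ic, tolerance = 1e-9)
})

test_that("profile-to-filter conversion subtracts the background", {
  expect_equal(profile_to_filter(matrix(0.25, 4, 1)), matrix(0, 4, 1))
  expect_equal(unname(profile_to_filter(matrix(c(1, 0, 0, 0), 4, 1))),
               matrix(c(0.75, -0.25, -0.25, -0.25), 4, 1))
  withr::with_seed(6, {
    for (i in 1:50) {
      probs <- matrix(rgamma(4 * 19, 1), 4, 19)
      probs <- sweep(probs, 2, colSums(probs), "/")
      fw <- profile_to_filter(probs)
      expect_lt(max(abs(colSums(fw))), 1e-12)
    }
  })
  expect_error(profile_to_filter(matrix(0.3, 4, 2)), "sum to 1")
})

test_that("reverse-complementing profiles doubles the set and is an involution", {
  dm <- demo_motifs()
  profs <- lapply(dm[1:3], function(m) pfm(m$probs * 50, id = m$id))
  doubled <- add_reverse_complements(profs)
  expect_length(doubled, 6)
  rc2 <- seqnam:::rc_matrix(seqnam:::rc_matrix(profs[[1]]$counts))
  expect_equal(rc2, profs[[1]]$counts)
  # a palindromic profile equals its reverse complement, ids stay distinct
  pal <- pfm(matrix(c(40, 5, 5, 10, 10, 5, 5, 40), 4, 2), id = "pal") # A..T
  d2 <- add_reverse_complements(list(pal))
  expect_equal(d2[[2]]$counts, pal$counts)
  expect_false(identical(d2[[2]]$id, pal$id))
})


test_that("farthest point sampling picks the most dissimilar profile first", {
  s <- matrix(c(1, .9, .1, .9, 1, .1, .1, .1, 1), 3, 3,
              dimnames = list(c("p1", "p2", "p3"), c("p1", "p2", "p3")))
  expect_identical(farthest_point_sample(s, 2), c("p3", "p1"))
  expect_setequal(farthest_point_sample(s, 3), c("p1", "p2", "p3"))
  # duplicated profiles: never pick both before everything else
  s2 <- diag(4)
  s2[1, 2] <- s2[2, 1] <- 1 # profiles 1 and 2 identical
  dimnames(s2) <- list(letters[1:4], letters[1:4])
  picked <- farthest_point_sample(s2, 3)
  expect_false(all(c("a", "b") %in% picked))
  expect_error(farthest_point_sample(s2, 9), "exceeds")
})

test_that("farthest point sampling matches brute-force greedy on toys", {
  withr::with_seed(8, {
    for (i in 1:10) {
      n <- 6
      s <- matrix(runif(n * n, 0, 0.9), n, n)
      s <- (s + t(s)) / 2
      diag(s) <- 1
      dimnames(s) <- list(paste0("m", 1:n), paste0("m", 1:n))
      for (k in c(2, 4, 6)) {
        expect_identical(farthest_point_sample(s, k), fps_oracle(s, k))
      }
    }
  })
})

test_that("filter initialization writes converted profiles into the units", {
  dm <- demo_motifs()
  profs <- lapply(dm[1:2], function(m) pfm(m$probs * 100, id = m$id))
  m <- tiny_model(U = 2, L = 60, seed = 3)
  m <- init_filters(m, profs, freeze = FALSE)
  for (u in 1:2) {
    expected <- profile_to_filter(pfm_to_pwm(resize_profile(profs[[u]], 19)))
    expect_equal(m$params$filters[, u], as.vector(expected))
  }
  expect_identical(m$filter_init$profile_id, c("GATA_SYN", "EBOX_SYN"))
  expect_error(init_filters(m, profs[1]), "counts must match")
})

test_that("frozen filters are bit-identical after training, unfrozen move", {
  toy <- toy_planted()
  dm <- demo_motifs()
  profs <- lapply(dm[1:2], function(m) pfm(m$probs * 100, id = m$id))
  cfgt <- train_config(max_epochs = 3, seed = 5)
  mf <- init_filters(tiny_model(U = 2, L = 60, seed = 3), profs,
                     freeze = TRUE)
  f0 <- mf$params$filters
  w0 <- mf$params$Wf
  mf <- train_model(mf, toy$splits$train, toy$splits$val, cfgt)
  expect_identical(mf$params$filters, f0)
  expect_false(identical(mf$params$Wf, w0))
  mu <- init_filters(tiny_model(U = 2, L = 60, seed = 3), profs,
                     freeze = FALSE)
  mu <- train_model(mu, toy$splits$train, toy$splits$val, cfgt)
  expect_false(identical(mu$params$filters, f0))
  # refinement keeps the planted-motif filter recognizable or helps the fit
  refined <- pwm_from_probs(
    apply(matrix(mu$params$filters[, 1], 4, 19) + 0.25, 2,
          function(x) pmax(x, 1e-6) / sum(pmax(x, 1e-6))),
    id = "refined"
  )
  keeps_motif <- motif_similarity(refined, dm$GATA_SYN)$similarity >= 0.8
  improves <- mu$meta$best_val_loss <= mf$meta$best_val_loss
  expect_true(keeps_motif || improves)
})
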