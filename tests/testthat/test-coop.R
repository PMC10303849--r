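test_that("backbones match the requested GC content and are seeded", {
  b <- generate_backbones(1000, 100, gc = 0.5, seed = 1)
  expect_lt(abs(mean(gc_content(b)) - 0.5), 0.02)
  expect_identical(b, generate_backbones(1000, 100, gc = 0.5, seed = 1))
  expect_false(identical(b, generate_backbones(1000, 100, gc = 0.5,
                                               seed = 2)))
  hot <- generate_backbones(50, 200, gc = 0.999, seed = 3)
  expect_gt(mean(gc_content(hot)), 0.99)
  expect_error(generate_backbones(10, 50, gc = 1), "strictly between")
})

test_that("embedding replaces exactly the targeted window", {
  expect_identical(embed_instance("AAAAA", "TTT", 1), "TTTAA")
  expect_identical(embed_instance("AAAAAAAAAA", "CGCG",
                                  center_start(10, 4)), "AAACGCGAAA")
  expect_equal(center_start(10, 4), 4L) # 0-based start 3
  expect_error(embed_instance("AAAA", "TTT", 3), "out of bounds")
  # replacement semantics: the later embed wins on overlaps
  s <- embed_instance(embed_instance(strrep("A", 8), "CCC", 2), "GG", 3)
  expect_identical(s, "ACGGAAAA")
})

# A purely additive oracle predictor: a linear functional of the one-hot
# matrix (weighted base counts per position block).
linear_predictor <- function(L) {
  w <- sin(seq_len(L)) # arbitrary fixed per-position weights
  function(seqs) {
    vapply(seqs, function(s) {
      code <- match(strsplit(s, "")[[1]], c("A", "C", "G", "T"))
      sum(w * (code == 2)) - 0.5 * sum(w * (code == 1))
    }, numeric(1), USE.NAMES = FALSE) |> matrix(ncol = 1)
  }
}

test_that("any linear predictor gives residual fold change exactly 1", {
  prof <- distance_dependence(
    linear_predictor(60), "TGATAAGA", "CACCTG",
    n_backbones = 16, input_length = 60, seed = 5
  )
  expect_lt(max(abs(prof$mean_log2_residual)), 1e-12)
  expect_equal(prof$fold_change, rep(1, nrow(prof)), tolerance = 1e-12)
})

# Oracle with a known interaction: counts exact occurrences of the motif
# and adds `bonus` when two occurrences lie within `window` bp edge-to-edge.
bonus_predictor <- function(motif, bonus, window) {
  function(seqs) {
    vapply(seqs, function(s) {
      hits <- gregexpr(motif, s, fixed = TRUE)[[1]]
      if (hits[1] == -1) {
        return(0)
      }
      y <- length(hits)
      if (length(hits) >= 2) {
        gaps <- diff(hits) - nchar(motif)
        if (any(gaps <= window)) y <- y + bonus
      }
      y
    }, numeric(1), USE.NAMES = FALSE) |> matrix(ncol = 1)
  }
}

test_that("a pairwise-bonus predictor yields fold change 2^bonus in range", {
  motif <- "TGATAAGA"
  pred <- bonus_predictor(motif, bonus = 0.5, window = 10)
  prof <- homotypic_profile(pred, motif, n_backbones = 24,
                            input_length = 80, seed = 6,
                            control_kmer = NULL)
  inwin <- abs(prof$distance) <= 10
  expect_equal(prof$mean_log2_residual[inwin],
               rep(0.5, sum(inwin)), tolerance = 0.05)
  expect_equal(prof$mean_log2_residual[abs(prof$distance) > 12],
               rep(0, sum(abs(prof$distance) > 12)), tolerance = 0.05)
})

test_that("the control k-mer profile is flat on an additive predictor", {
  prof <- distance_dependence(
    linear_predictor(70), "TGATAAGA", "CACCTGGT",
    n_backbones = 32, input_length = 70, seed = 7
  )
  ctrl <- prof[prof$series == "control", ]
  expect_gt(nrow(ctrl), 0)
  expect_lt(max(abs(ctrl$mean_log2_residual)), 1e-12)
})

test_that("heterotypic profiles are symmetric under motif swap", {
  motif_a <- "TGATAAGA"
  motif_b <- "CACCTGGT"
  predfun <- function(seqs) {
    ca <- vapply(gregexpr(motif_a, seqs, fixed = TRUE),
                 function(h) sum(h > 0), numeric(1))
    cb <- vapply(gregexpr(motif_b, seqs, fixed = TRUE),
                 function(h) sum(h > 0), numeric(1))
    # interaction depending only on co-occurrence
    matrix(ca + 2 * cb + 0.25 * (ca > 0 & cb > 0), ncol = 1)
  }
  d <- c(-15, -5, 0, 5, 15)
  p1 <- distance_dependence(predfun, motif_a, motif_b, distances = d,
                            n_backbones = 16, input_length = 80, seed = 8,
                            control_kmer = NULL)
  p2 <- distance_dependence(predfun, motif_b, motif_a, distances = -d,
                            n_backbones = 16, input_length = 80, seed = 8,
                            control_kmer = NULL)
  expect_equal(sort(p1$mean_log2_residual), sort(p2$mean_log2_residual),
               tolerance = 1e-10)
})

test_that("infeasible distances are skipped and reported", {
  prof <- distance_dependence(
    linear_predictor(40), "TGATAAGA", "CACCTGGT",
    distances = c(0, 5, 300, -300), n_backbones = 4, input_length = 40,
    seed = 9, control_kmer = NULL
  )
  expect_setequal(prof$distance, c(0, 5))
  expect_setequal(attr(prof, "skipped")$pair, c(300, -300))
})

test_that("coop_summary contrasts close against far distances", {
  prof <- tibble::tibble(
    series = "pair",
    distance = c(-30, -5, 0, 5, 30),
    mean_log2_residual = c(0, 1, 1, 1, 0),
    fold_change = 2^c(0, 1, 1, 1, 0),
    sd = rep(0.1, 5), se = rep(0.01, 5), n = 10
  )
  class(prof) <- c("coop_profile", class(prof))
  cs <- coop_summary(prof, "pair", close = 10, far = 25)
  expect_equal(cs$close_mean, 1)
  expect_equal(cs$far_mean, 0)
  expect_equal(cs$contrast, 1)
  expect_error(coop_summary(prof, "nope"), "no series")
})
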