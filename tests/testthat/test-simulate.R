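test_that("presence labels equal ledger-derived presence exactly", {
  gen <- generate_dataset(plant_spec(demo_motifs("GATA_SYN"), n = 100,
                                     length = 60, rule = "presence_binary",
                                     seed = 1))
  planted <- gen$data$id %in% gen$ledger$id
  expect_identical(as.numeric(planted), dataset_labels(gen$data)[, 1])
  expect_equal(sum(planted), 50)
})

test_that("linear labels reproduce the weighted ledger counts", {
  dm <- demo_motifs(c("GATA_SYN", "EBOX_SYN"))
  gen <- generate_dataset(plant_spec(dm, n = 200, length = 100,
                                     rule = "linear_counts",
                                     weights = c(GATA_SYN = 2,
                                                 EBOX_SYN = -1),
                                     noise_sd = 0, seed = 2))
  counts <- table(factor(gen$ledger$id, levels = gen$data$id),
                  factor(gen$ledger$motif, levels = names(dm)))
  expected <- as.numeric(counts[, "GATA_SYN"]) * 2 -
    as.numeric(counts[, "EBOX_SYN"])
  expect_equal(dataset_labels(gen$data)[, 1], expected)
})

test_that("pairwise bonuses follow the edge-to-edge window rule", {
  dm <- demo_motifs(c("GATA_SYN", "EBOX_SYN"))
  gen <- generate_dataset(plant_spec(dm, n = 300, length = 100,
                                     rule = "heterotypic_pairwise",
                                     bonus = 1, pair_window = 10,
                                     noise_sd = 0, seed = 3))
  counts <- table(factor(gen$ledger$id, levels = gen$data$id),
                  factor(gen$ledger$motif, levels = names(dm)))
  base <- as.numeric(counts[, 1]) + as.numeric(counts[, 2])
  bonus <- dataset_labels(gen$data)[, 1] - base
  expect_true(all(bonus %in% c(0, 1)))
  # recompute the indicator from the ledger independently
  by_id <- split(gen$ledger, gen$ledger$id)
  w <- 8L
  for (sid in names(by_id)) {
    lg <- by_id[[sid]]
    a <- lg$start[lg$motif == "GATA_SYN"]
    b <- lg$start[lg$motif == "EBOX_SYN"]
    hit <- FALSE
    for (x in a) {
      for (y in b) {
        gap <- max(x, y) - min(x + w - 1L, y + w - 1L) - 1L
        if (gap <= 10) hit <- TRUE
      }
    }
    expect_equal(bonus[match(sid, gen$data$id)], as.numeric(hit))
  }
  # sequences with no pair get no bonus
  expect_true(all(bonus[!gen$data$id %in% gen$ledger$id] == 0))
})

test_that("every ledger entry is present in its sequence", {
  gen <- generate_dataset(plant_spec(demo_motifs("GATA_SYN"), n = 150,
                                     length = 80, rule = "presence_binary",
                                     consensus_only = TRUE, seed = 4))
  for (i in seq_len(nrow(gen$ledger))) {
    row <- gen$ledger[i, ]
    s <- gen$data$sequence[match(row$id, gen$data$id)]
    expect_identical(substr(s, row$start, row$start + nchar(row$instance) - 1),
                     row$instance)
    expect_identical(row$instance, "TGATAAGA") # consensus planting
  }
})

test_that("generation is seeded and deterministic", {
  sp <- plant_spec(demo_motifs("GATA_SYN"), n = 50, length = 60,
                   rule = "presence_binary", seed = 9)
  g1 <- generate_dataset(sp)
  g2 <- generate_dataset(sp)
  expect_identical(g1$data$sequence, g2$data$sequence)
  expect_identical(g1$ledger, g2$ledger)
})

test_that("GC-matched negatives reproduce the positive GC histogram", {
  withr::with_seed(11, {
    pos <- tibble::tibble(
      id = sprintf("p%03d", 1:200),
      sequence = generate_backbones(200, 100, gc = 0.6, seed = 12)
    )
    pool <- tibble::tibble(
      id = sprintf("n%04d", 1:4000),
      sequence = c(
        generate_backbones(2000, 100, gc = 0.4, seed = 13),
        generate_backbones(2000, 100, gc = 0.65, seed = 14)
      )
    )
  })
  neg <- gc_matched_negatives(pos, pool, ratio = 1, seed = 15)
  expect_equal(nrow(neg), 200)
  expect_length(intersect(neg$id, pos$id), 0)
  breaks <- seq(0, 1, 0.05)
  hp <- table(cut(gc_content(pos$sequence), breaks))
  hn <- table(cut(gc_content(neg$sequence), breaks))
  keep <- hp + hn > 0
  suppressWarnings(
    p <- chisq.test(rbind(hp[keep], hn[keep]))$p.value
  )
  expect_gt(p, 0.05)
})

test_that("an exhausted pool reports the per-bin deficit", {
  pos <- tibble::tibble(id = c("a", "b", "c"),
                        sequence = rep(strrep("G", 40), 3))
  pool <- tibble::tibble(id = "x", sequence = strrep("A", 40))
  expect_error(gc_matched_negatives(pos, pool), "deficit")
})

test_that("dinucleotide shuffling preserves the dinucleotide counts", {
  expect_identical(dinucleotide_shuffle("AAAA", seed = 1), "AAAA")
  seqs <- random_dna(50, 40, seed = 21)
  for (s in seqs) {
    sh <- dinucleotide_shuffle(s, seed = 22)
    expect_identical(nchar(sh), nchar(s))
    expect_identical(substr(sh, 1, 1), substr(s, 1, 1))
    expect_identical(dinucleotide_counts(sh), dinucleotide_counts(s))
  }
  outs <- vapply(1:20, function(i) {
    dinucleotide_shuffle("AAGCTTAGGATCCTAAGG", seed = i)
  }, character(1))
  expect_gt(length(unique(outs)), 1)
  expect_true(all(vapply(outs, function(o) {
    identical(dinucleotide_counts(o),
              dinucleotide_counts("AAGCTTAGGATCCTAAGG"))
  }, logical(1))))
  expect_error(dinucleotide_shuffle("A"), "length >= 2")
})
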