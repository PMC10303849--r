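#' Specification for a synthetic planted-motif dataset
#'
#' Describes how to draw fixed-length background sequences, embed motif
#' instances sampled from PWMs, and derive labels from the planted
#' occurrences. Four label rules are supported:
#' \describe{
#'   \item{presence_binary}{label 1 iff the sequence carries at least one
#'     planted instance (positives receive instances per
#'     `positive_fraction`; negatives none).}
#'   \item{linear_counts}{`y = sum_k weight_k * count_k + N(0, noise_sd)`.}
#'   \item{homotypic_pairwise}{`linear_counts` plus `bonus` when two
#'     instances of `pair_motifs[1]` lie within `pair_window` bp
#'     (edge-to-edge).}
#'   \item{heterotypic_pairwise}{`linear_counts` plus `bonus` when an
#'     instance of `pair_motifs[1]` and one of `pair_motifs[2]` lie within
#'     `pair_window` bp.}
#' }
#'
#' @param motifs Named list of `pwm` objects to plant.
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc Background GC fraction.
#' @param rule Label rule (see above).
#' @param positive_fraction For `presence_binary`: fraction of sequences
#'   that receive one instance of each motif (default 0.5).
#' @param instance_probs For count-based rules: named list mapping motif id
#'   to the probability vector of carrying 0, 1, 2, ... instances
#'   (default `c(0.3, 0.4, 0.3)` for every motif).
#' @param weights Named per-motif weights for the linear label part
#'   (default 1 for each motif).
#' @param bonus Interaction bonus added by the pairwise rules (default 1).
#' @param pair_window Edge-to-edge distance window in bp for the pairwise
#'   bonus: a scalar `w` (gap at most `w`, default 10) or a range
#'   `c(lo, hi)` (gap between `lo` and `hi`), e.g. a range that keeps the
#'   interacting pair wider than one filter window.
#' @param pair_motifs Character vector of 1 or 2 motif ids entering the
#'   pairwise bonus; defaults to the first motif (homotypic) or the first
#'   two (heterotypic).
#' @param noise_sd Gaussian label noise standard deviation (default 0).
#' @param positions `"uniform"` (default), `"center"`, or a fixed integer
#'   start.
#' @param strands `"+"` (default) or `"both"` (instances placed on a
#'   random strand).
#' @param consensus_only Plant consensus strings instead of PWM-sampled
#'   realizations (default FALSE).
#' @param seed Integer seed.
#' @return An object of class `plant_spec`.
#' @export
plant_spec <- function(motifs, n, length = 100L, gc = 0.5,
                       rule = c("presence_binary", "linear_counts",
                                "homotypic_pairwise",
                                "heterotypic_pairwise"),
                       positive_fraction = 0.5, instance_probs = NULL,
                       weights = NULL, bonus = 1, pair_window = 10L,
                       pair_motifs = NULL, noise_sd = 0,
                       positions = "uniform", strands = c("+", "both"),
                       consensus_only = FALSE, seed = 1L) {
  rule <- match.arg(rule)
  strands <- match.arg(strands)
  if (is.null(names(motifs))) {
    names(motifs) <- vapply(motifs, `[[`, character(1), "id")
  }
  widths <- vapply(motifs, function(m) ncol(m$probs), integer(1))
  if (any(widths > length)) abort("a motif is longer than the sequences")
  if (noise_sd < 0) abort("noise_sd must be >= 0")
  ids <- names(motifs)
  if (is.null(instance_probs)) {
    instance_probs <- setNames(rep(list(c(0.3, 0.4, 0.3)), length(ids)), ids)
  }
  if (is.null(weights)) weights <- setNames(rep(1, length(ids)), ids)
  if (is.null(pair_motifs)) {
    pair_motifs <- if (rule == "heterotypic_pairwise") ids[1:2] else ids[1]
  }
  structure(list(
    motifs = motifs, n = as.integer(n), length = as.integer(length),
    gc = gc, rule = rule, positive_fraction = positive_fraction,
    instance_probs = instance_probs, weights = weights, bonus = bonus,
    pair_window = as.integer(if (length(pair_window) == 1L) {
      c(0L, pair_window)
    } else {
      pair_window
    }), pair_motifs = pair_motifs,
    noise_sd = noise_sd, positions = positions, strands = strands,
    consensus_only = isTRUE(consensus_only), seed = as.integer(seed)
  ), class = "plant_spec")
}

#' Generate a synthetic planted-motif dataset
#'
#' Draws background sequences at the specified GC content, embeds motif
#' instances (non-overlapping, positions uniform unless specified), and
#' derives labels exactly from the planted occurrences per the rule in the
#' spec. Every planted instance is recorded in a ground-truth ledger
#' (sequence id, motif id, 1-based start, strand, instance string), so
#' labels can be re-derived and checked from the ledger alone.
#'
#' @param spec A [plant_spec()].
#' @return A list with `data` (a [labeled_dataset()]), `ledger` (tibble),
#'   and `spec`.
#' @export
generate_dataset <- function(spec) {
  stopifnot(inherits(spec, "plant_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n
  L <- spec$length
  ids <- sprintf("seq%05d", seq_len(n))
  seqs <- generate_backbones(n, L, gc = spec$gc, seed = spec$seed + 1L)

  motif_ids <- names(spec$motifs)
  counts <- matrix(0L, n, length(motif_ids),
                   dimnames = list(NULL, motif_ids))
  if (spec$rule == "presence_binary") {
    n_pos <- round(n * spec$positive_fraction)
    is_pos <- seq_len(n) <= n_pos # ids are arbitrary; no need to shuffle
    counts[is_pos, ] <- 1L
  } else {
    for (m in motif_ids) {
      pr <- spec$instance_probs[[m]]
      counts[, m] <- sample(seq_along(pr) - 1L, n, replace = TRUE, prob = pr)
    }
  }

  ledger <- list()
  for (i in seq_len(n)) {
    placed <- matrix(numeric(0), 0, 2) # start, end of placed instances
    for (m in motif_ids) {
      k <- counts[i, m]
      if (k == 0L) next
      pw <- spec$motifs[[m]]
      w <- ncol(pw$probs)
      for (r in seq_len(k)) {
        start <- place_instance(L, w, placed, spec$positions)
        if (is.na(start)) next # no room; count corrected below
        strand <- if (spec$strands == "both" && runif(1) < 0.5) "-" else "+"
        inst <- sample_instance(pw, consensus_only = spec$consensus_only)
        embedded <- if (strand == "-") reverse_complement(inst) else inst
        seqs[i] <- embed_instance(seqs[i], embedded, start)
        placed <- rbind(placed, c(start, start + w - 1L))
        ledger[[length(ledger) + 1L]] <- tibble(
          id = ids[i], motif = m, start = start, strand = strand,
          instance = embedded
        )
      }
    }
  }
  ledger <- if (length(ledger) > 0L) {
    dplyr::bind_rows(ledger)
  } else {
    tibble(id = character(), motif = character(), start = integer(),
           strand = character(), instance = character())
  }

  # Recount from the ledger so dropped placements cannot skew the labels.
  counts <- ledger_counts(ledger, ids, motif_ids)

  if (spec$rule == "presence_binary") {
    labels <- tibble(bound = as.numeric(rowSums(counts) > 0))
    task_type <- "binary_multitask"
  } else {
    y <- as.vector(counts %*% spec$weights[motif_ids])
    if (spec$rule != "linear_counts") {
      y <- y + spec$bonus * pair_indicator(ledger, ids, spec)
    }
    if (spec$noise_sd > 0) y <- y + rnorm(n, 0, spec$noise_sd)
    labels <- tibble(activity = y)
    task_type <- "regression"
  }

  data <- labeled_dataset(
    dplyr::bind_cols(tibble(id = ids, sequence = seqs), labels),
    task_type = task_type
  )
  list(data = data, ledger = ledger, spec = spec)
}

place_instance <- function(L, w, placed, positions, max_tries = 200L) {
  candidate_ok <- function(s) {
    if (nrow(placed) == 0L) return(TRUE)
    all(s + w - 1L < placed[, 1] | s > placed[, 2])
  }
  if (identical(positions, "center")) {
    s <- center_start(L, w)
    return(if (candidate_ok(s)) s else NA_integer_)
  }
  if (is.numeric(positions)) {
    s <- as.integer(positions)
    return(if (candidate_ok(s)) s else NA_integer_)
  }
  for (try in seq_len(max_tries)) {
    s <- sample.int(L - w + 1L, 1L)
    if (candidate_ok(s)) return(s)
  }
  NA_integer_
}

ledger_counts <- function(ledger, ids, motif_ids) {
  counts <- matrix(0L, length(ids), length(motif_ids),
                   dimnames = list(ids, motif_ids))
  if (nrow(ledger) > 0L) {
    tab <- table(factor(ledger$id, levels = ids),
                 factor(ledger$motif, levels = motif_ids))
    counts[] <- as.integer(tab)
  }
  counts
}

# 1 iff the sequence has two qualifying instances within the window
# (edge-to-edge gap).
pair_indicator <- function(ledger, ids, spec) {
  ind <- setNames(numeric(length(ids)), ids)
  if (nrow(ledger) == 0L) return(unname(ind))
  widths <- vapply(spec$motifs, function(m) ncol(m$probs), integer(1))
  pm <- spec$pair_motifs
  homo <- length(pm) == 1L || pm[1] == pm[2]
  by_id <- split(ledger, ledger$id)
  for (sid in names(by_id)) {
    lg <- by_id[[sid]]
    a <- lg[lg$motif == pm[1], ]
    b <- if (homo) a else lg[lg$motif == pm[length(pm)], ]
    if (nrow(a) == 0L || nrow(b) == 0L) next
    hit <- FALSE
    for (i in seq_len(nrow(a))) {
      js <- if (homo) setdiff(seq_len(nrow(b)), i) else seq_len(nrow(b))
      for (j in js) {
        end_i <- a$start[i] + widths[[a$motif[i]]] - 1L
        end_j <- b$start[j] + widths[[b$motif[j]]] - 1L
        gap <- max(a$start[i], b$start[j]) - min(end_i, end_j) - 1L
        if (gap >= spec$pair_window[1] && gap <= spec$pair_window[2]) {
          hit <- TRUE
          break
        }
      }
      if (hit) break
    }
    ind[sid] <- as.numeric(hit)
  }
  unname(ind)
}

#' GC-matched negative sampling
#'
#' Samples negatives from a pool, without replacement, so that the
#' per-GC-bin counts match the positives' distribution (bins of
#' `bin_width` GC fraction, default 5 percentage points) times `ratio`.
#' When a bin's pool runs short, the shortfall is borrowed from the
#' nearest adjacent bins and logged in the `borrowed` attribute; if the
#' pool is exhausted even with borrowing, an error reports the per-bin
#' deficit.
#'
#' @param positives,pool Data frames with `id` and `sequence` columns (or
#'   character vectors).
#' @param ratio Negatives per positive (default 1: a 50:50 set).
#' @param bin_width GC bin width as a fraction (default 0.05).
#' @param seed Integer seed.
#' @return A tibble of sampled negatives (columns `id`, `sequence`), with
#'   a `borrowed` attribute describing any bin borrowing.
#' @export
gc_matched_negatives <- function(positives, pool, ratio = 1,
                                 bin_width = 0.05, seed = 1L) {
  as_tbl <- function(x) {
    if (is.character(x)) {
      tibble(id = names(x) %||% as.character(seq_along(x)),
             sequence = unname(x))
    } else {
      as_tibble(x[, c("id", "sequence")])
    }
  }
  positives <- as_tbl(positives)
  pool <- as_tbl(pool)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  breaks <- seq(0, 1, by = bin_width)
  bin_of <- function(seqs) {
    as.integer(cut(gc_content(seqs), breaks = breaks, include.lowest = TRUE))
  }
  pos_bin <- bin_of(positives$sequence)
  pool_bin <- bin_of(pool$sequence)
  want <- round(table(factor(pos_bin, levels = seq_along(breaks[-1]))) * ratio)
  nb <- length(want)

  avail <- lapply(seq_len(nb), function(b) sample(which(pool_bin == b)))
  taken <- integer(0)
  borrowed <- list()
  deficit <- integer(nb)
  for (b in seq_len(nb)) {
    need <- want[b]
    if (need == 0L) next
    take <- head(avail[[b]], need)
    avail[[b]] <- setdiff(avail[[b]], take)
    short <- need - length(take)
    # borrow from adjacent bins, nearest first
    if (short > 0L) {
      for (off in seq_len(nb)) {
        for (nbr in c(b - off, b + off)) {
          if (short == 0L || nbr < 1L || nbr > nb) next
          extra <- head(avail[[nbr]], short)
          if (length(extra) > 0L) {
            avail[[nbr]] <- setdiff(avail[[nbr]], extra)
            take <- c(take, extra)
            borrowed[[length(borrowed) + 1L]] <- tibble(
              bin = b, from_bin = nbr, n = length(extra)
            )
            short <- short - length(extra)
          }
        }
        if (short == 0L) break
      }
    }
    deficit[b] <- short
    taken <- c(taken, take)
  }
  if (sum(deficit) > 0L) {
    bad <- which(deficit > 0L)
    abort(paste0(
      "pool exhausted even with borrowing; per-bin deficit: ",
      paste(sprintf("bin %d (GC %.2f-%.2f): %d", bad, breaks[bad],
                    breaks[bad + 1L], deficit[bad]), collapse = ", ")
    ))
  }
  out <- pool[sort(taken), , drop = FALSE]
  attr(out, "borrowed") <- if (length(borrowed) > 0L) {
    dplyr::bind_rows(borrowed)
  } else {
    tibble(bin = integer(), from_bin = integer(), n = integer())
  }
  out
}

#' Dinucleotide shuffle
#'
#' Random shuffle preserving the exact dinucleotide count multiset of the
#' input (Altschul-Erickson Eulerian-path method): the output has the same
#' length, the same first and last base, and identical dinucleotide
#' counts. Seeded and deterministic.
#'
#' @param sequence A DNA string of length at least 2.
#' @param seed Optional integer seed.
#' @return A shuffled DNA string.
#' @export
dinucleotide_shuffle <- function(sequence, seed = NULL) {
  if (nchar(sequence) < 2L) abort("sequence must have length >= 2")
  if (!is.null(seed)) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
  }
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  verts <- unique(chars)
  last <- chars[n]
  # outgoing edge multiset per vertex
  edges <- split(chars[-1], chars[-n])
  has_out <- names(edges)

  # Pick one outgoing "last edge" per non-terminal vertex such that the
  # last-edge graph reaches the terminal vertex from every vertex.
  non_term <- setdiff(has_out, last)
  repeat {
    last_edge <- vapply(non_term, function(v) {
      e <- edges[[v]]
      e[[sample.int(length(e), 1L)]]
    }, character(1))
    ok <- all(vapply(non_term, function(v) {
      seen <- character(0)
      while (v != last) {
        if (v %in% seen || !(v %in% non_term)) return(FALSE)
        seen <- c(seen, v)
        v <- last_edge[[v]]
      }
      TRUE
    }, logical(1)))
    if (ok || length(non_term) == 0L) break
  }

  # Permute the remaining edges; append the designated last edge.
  shuffled <- lapply(has_out, function(v) {
    e <- edges[[v]]
    if (v %in% non_term) {
      drop <- match(last_edge[[v]], e)
      e <- e[-drop]
      c(if (length(e) > 0L) sample(e) else character(0), last_edge[[v]])
    } else {
      if (length(e) > 1L) sample(e) else e
    }
  })
  names(shuffled) <- has_out

  # Walk the Eulerian path from the first character.
  out <- character(n)
  out[1] <- chars[1]
  ptr <- setNames(rep(1L, length(has_out)), has_out)
  v <- chars[1]
  for (i in 2:n) {
    nxt <- shuffled[[v]][ptr[[v]]]
    ptr[[v]] <- ptr[[v]] + 1L
    out[i] <- nxt
    v <- nxt
  }
  paste(out, collapse = "")
}

#' Dinucleotide counts of a sequence
#'
#' @param sequence A DNA string.
#' @return Named integer vector of overlapping 2-mer counts.
#' @export
dinucleotide_counts <- function(sequence) {
  chars <- strsplit(toupper(sequence), "")[[1]]
  n <- length(chars)
  if (n < 2L) return(integer(0))
  di <- paste0(chars[-n], chars[-1])
  table(di)
}
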