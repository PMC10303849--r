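#' Generate random backbone sequences
#'
#' I.i.d. sequences with per-position base probabilities
#' `((1-gc)/2, gc/2, gc/2, (1-gc)/2)` for A, C, G, T; seeded and
#' deterministic.
#'
#' @param n Number of sequences.
#' @param length Sequence length in bp.
#' @param gc GC fraction in (0, 1).
#' @param seed Integer seed.
#' @return Character vector of `n` sequences.
#' @export
generate_backbones <- function(n, length, gc = 0.5, seed = 1L) {
  if (n < 1L) abort("n must be >= 1")
  if (gc <= 0 || gc >= 1) abort("gc must be strictly between 0 and 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  probs <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  draws <- matrix(sample(DNA_BASES, n * length, replace = TRUE, prob = probs),
                  nrow = n)
  apply(draws, 1L, paste, collapse = "")
}

#' Embed a subsequence
#'
#' Replaces the bases at `start .. start + nchar(instance) - 1` (1-based)
#' with `instance`; the rest of the sequence is unchanged. Overlapping
#' embeds are resolved by replacement order: the later call wins on the
#' overlap.
#'
#' @param sequence A DNA string.
#' @param instance The subsequence to place.
#' @param start 1-based start position.
#' @return The modified sequence.
#' @export
embed_instance <- function(sequence, instance, start) {
  L <- nchar(sequence)
  w <- nchar(instance)
  if (start < 1L || start + w - 1L > L) {
    abort(sprintf("embedding at %d..%d is out of bounds for length %d",
                  start, start + w - 1L, L))
  }
  paste0(substr(sequence, 1L, start - 1L), instance,
         substr(sequence, start + w, L))
}

#' Center placement of a motif
#'
#' 1-based start that puts the motif midpoint at the sequence midpoint,
#' shifted left on odd parity.
#'
#' @param L Sequence length.
#' @param w Motif width.
#' @return Integer start position.
#' @export
center_start <- function(L, w) {
  if (w > L) abort("motif is longer than the sequence")
  as.integer(floor((L - w) / 2) + 1L)
}

coop_motif_string <- function(x) {
  if (inherits(x, "pwm")) consensus(x) else if (inherits(x, "pfm")) {
    consensus(x)
  } else {
    toupper(as.character(x))
  }
}

coop_predict <- function(predictor, sequences, task) {
  p <- if (inherits(predictor, "seqnam_model")) {
    predict(predictor, sequences)
  } else {
    predictor(sequences)
  }
  p <- as.matrix(p)
  p[, task]
}

#' Motif distance-dependence (cooperativity) analysis
#'
#' Fixes `motif_a` at the center of random backbone sequences and slides
#' `motif_b` (and, separately, a control k-mer) to signed edge-to-edge
#' distances `d` (negative = left of center). For each backbone and
#' distance the residual, on the predictor's output scale, is the
#' double difference
#' `p(both) - p(A alone) - p(B alone) + p(backbone)`,
#' which is exactly zero for any predictor that is additive in motif
#' occurrences; the residual fold change is `2^residual`. With
#' `scale = "ratio"` the ratio form
#' `p(both) * p(backbone) / (p(A alone) * p(B alone))` is used instead
#' (for strictly positive outputs).
#'
#' @param predictor A `seqnam_model` or a function mapping a character
#'   vector of sequences to an n x T prediction matrix.
#' @param motif_a,motif_b `pwm`s (their consensus is embedded) or DNA
#'   strings.
#' @param distances Signed edge-to-edge distances in bp; defaults to every
#'   feasible distance. Infeasible (out-of-bounds) distances are skipped
#'   and reported via the `skipped` attribute.
#' @param n_backbones Number of random backbones (default 256).
#' @param input_length Backbone length; defaults to the model's input
#'   length.
#' @param gc Backbone GC fraction.
#' @param task Output task index analyzed.
#' @param control_kmer Control subsequence slid in place of `motif_b`
#'   (default `"GGGCT"`); set to `NULL` to skip the control.
#' @param seed Integer seed (backbones are shared across distances and
#'   between the pair and control analyses).
#' @param scale `"log2"` (double difference, default) or `"ratio"`.
#' @return A tibble of class `coop_profile`: columns `series` ("pair" or
#'   "control"), `distance`, `mean_log2_residual`, `fold_change`, `sd`,
#'   `se`, `n`.
#' @export
distance_dependence <- function(predictor, motif_a, motif_b,
                                distances = NULL, n_backbones = 256L,
                                input_length = NULL, gc = 0.5, task = 1L,
                                control_kmer = "GGGCT", seed = 1L,
                                scale = c("log2", "ratio")) {
  scale <- match.arg(scale)
  a <- coop_motif_string(motif_a)
  b <- coop_motif_string(motif_b)
  L <- input_length %||% (if (inherits(predictor, "seqnam_model")) {
    predictor$config$input_length
  } else {
    abort("input_length is required for a function predictor")
  })
  wa <- nchar(a)
  start_a <- center_start(L, wa)

  backbones <- generate_backbones(n_backbones, L, gc = gc, seed = seed)
  p_bb <- coop_predict(predictor, backbones, task)
  seq_a <- vapply(backbones, embed_instance, character(1),
                  instance = a, start = start_a, USE.NAMES = FALSE)
  p_a <- coop_predict(predictor, seq_a, task)

  series <- list(pair = b)
  if (!is.null(control_kmer)) series$control <- toupper(control_kmer)

  out <- list()
  skipped <- list()
  for (nm in names(series)) {
    mb <- series[[nm]]
    wb <- nchar(mb)
    dists <- distances %||% feasible_distances(L, start_a, wa, wb)
    starts_b <- vapply(dists, function(d) {
      if (d >= 0) start_a + wa + d else start_a - (-d) - wb
    }, numeric(1))
    ok <- starts_b >= 1 & starts_b + wb - 1 <= L
    if (any(!ok)) skipped[[nm]] <- dists[!ok]
    dists <- dists[ok]
    starts_b <- starts_b[ok]
    # Batch all (backbone x distance) variants into single predictor calls.
    nd <- length(dists)
    seq_b <- character(n_backbones * nd)
    seq_ab <- character(n_backbones * nd)
    for (j in seq_len(nd)) {
      idx <- (j - 1L) * n_backbones + seq_len(n_backbones)
      seq_b[idx] <- vapply(backbones, embed_instance, character(1),
                           instance = mb, start = starts_b[j],
                           USE.NAMES = FALSE)
      seq_ab[idx] <- vapply(seq_a, embed_instance, character(1),
                            instance = mb, start = starts_b[j],
                            USE.NAMES = FALSE)
    }
    p_b <- coop_predict(predictor, seq_b, task)
    p_ab <- coop_predict(predictor, seq_ab, task)
    res <- matrix(p_ab - p_a - p_b + p_bb, n_backbones, nd)
    if (scale == "ratio") {
      rm_ <- matrix(p_ab * p_bb / (p_a * p_b), n_backbones, nd)
      res <- log2(rm_)
    }
    out[[nm]] <- tibble(
      series = nm,
      distance = dists,
      mean_log2_residual = colMeans(res),
      fold_change = 2^colMeans(res),
      sd = apply(res, 2L, sd),
      se = apply(res, 2L, sd) / sqrt(n_backbones),
      n = n_backbones
    )
  }
  prof <- dplyr::bind_rows(out)
  attr(prof, "motif_a") <- a
  attr(prof, "motif_b") <- b
  attr(prof, "skipped") <- skipped
  attr(prof, "scale") <- scale
  class(prof) <- c("coop_profile", class(prof))
  prof
}

feasible_distances <- function(L, start_a, wa, wb) {
  # right side: start_b = start_a + wa + d <= L - wb + 1
  max_right <- L - wb + 1L - start_a - wa
  right <- if (max_right >= 0L) 0L:max_right else integer(0)
  # left side: start_b = start_a - d' - wb >= 1 (d' = |d|)
  max_left <- start_a - wb - 1L
  left <- if (max_left >= 1L) seq_len(max_left) else integer(0)
  if (length(right) + length(left) == 0L) {
    abort("no feasible non-overlapping placements; sequences too short")
  }
  sort(c(-left, right))
}

#' @rdname distance_dependence
#' @param motif The motif whose homotypic (same-motif pair) distance
#'   dependence is analyzed.
#' @param ... Passed on to [distance_dependence()].
#' @export
homotypic_profile <- function(predictor, motif, ...) {
  distance_dependence(predictor, motif_a = motif, motif_b = motif, ...)
}

#' Summarize a cooperativity profile
#'
#' Close-range versus long-range contrast of the mean log2 residual, the
#' standard flatness diagnostics for one series of a [distance_dependence()]
#' profile.
#'
#' @param profile A `coop_profile`.
#' @param series Which series to summarize (default `"pair"`).
#' @param close Distances with `|d| <= close` count as close (default 10).
#' @param far Distances with `|d| > far` count as far (default 25).
#' @return A one-row tibble: `close_mean`, `far_mean`, `contrast`
#'   (close - far), `max_abs` (largest per-distance |mean log2 residual|),
#'   and `max_abs_over_se` (the same, in units of its standard error).
#' @export
coop_summary <- function(profile, series = "pair", close = 10, far = 25) {
  p <- profile[profile$series == series, ]
  if (nrow(p) == 0L) abort(sprintf("no series '%s' in profile", series))
  close_mean <- mean(p$mean_log2_residual[abs(p$distance) <= close])
  far_mean <- mean(p$mean_log2_residual[abs(p$distance) > far])
  i <- which.max(abs(p$mean_log2_residual))
  tibble(
    series = series,
    close_mean = close_mean,
    far_mean = far_mean,
    contrast = close_mean - far_mean,
    max_abs = abs(p$mean_log2_residual[i]),
    max_abs_over_se = abs(p$mean_log2_residual[i]) / p$se[i]
  )
}
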