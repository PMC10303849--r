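#' Position frequency and weight matrices
#'
#' A PFM is a 4 x W matrix of non-negative per-position base counts (rows
#' A, C, G, T) together with the number of contributing sites; a PWM holds
#' the pseudocount-smoothed probability matrix and its log2 odds against a
#' uniform 0.25 background.
#'
#' @param counts 4 x W numeric matrix of counts (rows A, C, G, T).
#' @param id Motif identifier.
#' @param name Optional display name.
#' @param n_sites Number of contributing sites; defaults to the (common)
#'   column sum.
#' @return An object of class `pfm`.
#' @export
pfm <- function(counts, id = "motif", name = id, n_sites = NULL) {
  counts <- as.matrix(counts)
  if (nrow(counts) != 4L) abort("a PFM has 4 rows (A, C, G, T)")
  if (any(counts < 0)) abort("PFM counts must be non-negative")
  rownames(counts) <- DNA_BASES
  if (is.null(n_sites)) n_sites <- max(colSums(counts))
  structure(
    list(counts = counts, n_sites = n_sites, id = id, name = name),
    class = "pfm"
  )
}

#' @export
print.pfm <- function(x, ...) {
  cat(sprintf("<pfm> %s (%s), width %d, %s sites%s\n", x$id, x$name,
              ncol(x$counts), format(x$n_sites),
              if (isTRUE(attr(x, "empty"))) " [empty]" else ""))
  invisible(x)
}

#' @export
print.pwm <- function(x, ...) {
  cat(sprintf("<pwm> %s, width %d, consensus %s\n", x$id, ncol(x$probs),
              consensus(x)))
  invisible(x)
}

#' Convert a PFM to a PWM
#'
#' Per column, probabilities are `(count + pseudocount/4) /
#' (column_total + pseudocount)` and log odds are `log2(prob / 0.25)`
#' (uniform background), so a uniform column has all-zero log odds.
#'
#' @param x A [pfm()] (or a bare 4 x W count matrix).
#' @param pseudocount Total pseudocount distributed uniformly over the four
#'   bases (default 1).
#' @return An object of class `pwm` with elements `probs` and `log_odds`.
#' @examples
#' p <- pfm(matrix(c(3, 0, 0, 0), 4, 1), id = "ex")
#' pfm_to_pwm(p)$probs[1, 1] # 3.25 / 4
#' @export
pfm_to_pwm <- function(x, pseudocount = 1) {
  if (is.matrix(x)) x <- pfm(x)
  stopifnot(inherits(x, "pfm"))
  if (isTRUE(attr(x, "empty")) || all(colSums(x$counts) == 0)) {
    abort(sprintf("PFM '%s' has no sites; cannot form a PWM", x$id))
  }
  tot <- colSums(x$counts)
  probs <- sweep(x$counts, 2L, tot + pseudocount, "/") +
    (pseudocount / 4) / rep(tot + pseudocount, each = 4L)
  log_odds <- log2(probs / 0.25)
  structure(
    list(probs = probs, log_odds = log_odds, id = x$id, name = x$name,
         n_sites = x$n_sites),
    class = "pwm"
  )
}

#' Construct a PWM from a probability matrix
#'
#' @param probs 4 x W matrix with columns summing to 1.
#' @param id,name Identifiers.
#' @return An object of class `pwm`.
#' @export
pwm_from_probs <- function(probs, id = "motif", name = id) {
  probs <- as.matrix(probs)
  if (nrow(probs) != 4L) abort("a PWM has 4 rows (A, C, G, T)")
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    abort("PWM probability columns must sum to 1")
  }
  rownames(probs) <- DNA_BASES
  structure(
    list(probs = probs, log_odds = log2(pmax(probs, 1e-9) / 0.25), id = id,
         name = name, n_sites = NA_real_),
    class = "pwm"
  )
}

#' Consensus sequence of a motif
#'
#' The argmax base per column (ties broken in A, C, G, T order).
#'
#' @param x A `pwm` or `pfm`.
#' @return A string of width W.
#' @export
consensus <- function(x) {
  m <- if (inherits(x, "pwm")) x$probs else x$counts
  paste(DNA_BASES[apply(m, 2L, which.max)], collapse = "")
}

# Per-column information content in bits (0log0 = 0), on probabilities.
column_ic <- function(probs) {
  pl <- probs * log2(pmax(probs, .Machine$double.xmin))
  2 + colSums(ifelse(probs > 0, pl, 0))
}

#' Resize a motif profile to a fixed width
#'
#' Profiles wider than `target_width` are trimmed to the window with the
#' highest total information content (ties broken by centeredness, then
#' leftmost); narrower profiles are padded on both sides with uniform
#' (background) columns, the extra column going to the right on odd parity.
#'
#' @param x A [pfm()].
#' @param target_width Output width in bp (default 19, the filter width).
#' @param strategy `"max_ic"` (default) or `"center"` (symmetric trim).
#' @return A `pfm` of width exactly `target_width`.
#' @export
resize_profile <- function(x, target_width = 19L,
                           strategy = c("max_ic", "center")) {
  stopifnot(inherits(x, "pfm"))
  strategy <- match.arg(strategy)
  w <- ncol(x$counts)
  tw <- as.integer(target_width)
  if (w == tw) {
    return(x)
  }
  if (w > tw) {
    if (strategy == "center") {
      lead <- floor((w - tw) / 2)
      keep <- (lead + 1L):(lead + tw)
    } else {
      tot <- colSums(x$counts)
      probs <- sweep(x$counts, 2L, pmax(tot, 1e-12), "/")
      ic <- column_ic(probs)
      wins <- seq_len(w - tw + 1L)
      win_ic <- vapply(wins, function(s) sum(ic[s:(s + tw - 1L)]), numeric(1))
      center_dist <- abs(wins + (tw - 1) / 2 - (w + 1) / 2)
      best <- order(-win_ic, center_dist, wins)[1L]
      keep <- best:(best + tw - 1L)
    }
    out <- x$counts[, keep, drop = FALSE]
  } else {
    pad <- tw - w
    left <- floor(pad / 2)
    right <- pad - left # extra column on the right when parity is odd
    fill <- mean(colSums(x$counts)) / 4
    unif <- matrix(fill, 4L, 1L)
    out <- cbind(
      unif[, rep(1L, left), drop = FALSE],
      x$counts,
      unif[, rep(1L, right), drop = FALSE]
    )
  }
  pfm(out, id = x$id, name = x$name, n_sites = x$n_sites)
}

#' Convert motif probabilities to convolutional filter weights
#'
#' Filter weights are the probabilities minus the uniform background 0.25,
#' so every filter column sums to zero and a background column contributes
#' nothing.
#'
#' @param x A `pwm`, `pfm`, or 4 x W probability matrix with columns
#'   summing to 1.
#' @return A 4 x W weight matrix.
#' @export
profile_to_filter <- function(x) {
  probs <- if (inherits(x, "pwm")) {
    x$probs
  } else if (inherits(x, "pfm")) {
    pfm_to_pwm(x)$probs
  } else {
    as.matrix(x)
  }
  if (nrow(probs) != 4L) abort("expected 4 rows (A, C, G, T)")
  if (any(abs(colSums(probs) - 1) > 1e-6)) {
    abort("probability columns must sum to 1")
  }
  probs - 0.25
}

#' Reverse complement motif profiles
#'
#' Doubles a profile list by adding, for each profile, its reverse
#' complement (columns reversed, A swapped with T and C with G) under a
#' derived id with suffix `"::rc"`.
#'
#' @param profiles A list of [pfm()]s.
#' @return A list of length `2 * length(profiles)`.
#' @export
add_reverse_complements <- function(profiles) {
  stopifnot(all(vapply(profiles, inherits, logical(1), "pfm")))
  rcs <- lapply(profiles, function(p) {
    pfm(rc_matrix(p$counts), id = paste0(p$id, "::rc"),
        name = paste0(p$name, "::rc"), n_sites = p$n_sites)
  })
  c(profiles, rcs)
}

rc_matrix <- function(m) {
  out <- m[c(4L, 3L, 2L, 1L), rev(seq_len(ncol(m))), drop = FALSE]
  rownames(out) <- DNA_BASES
  out
}

#' Reverse complement a PWM
#'
#' @param x A `pwm`.
#' @return The reverse-complemented `pwm`.
#' @export
reverse_complement_pwm <- function(x) {
  stopifnot(inherits(x, "pwm"))
  structure(
    list(probs = rc_matrix(x$probs), log_odds = rc_matrix(x$log_odds),
         id = paste0(x$id, "::rc"), name = paste0(x$name, "::rc"),
         n_sites = x$n_sites),
    class = "pwm"
  )
}

#' Similarity between two motifs
#'
#' Maximum Pearson correlation of aligned probability columns over all
#' ungapped offsets of the query against the target, on both strands, with
#' a minimum column overlap. Identical motifs score 1; a motif and its
#' reverse complement also score 1 (via the strand flip).
#'
#' @param query,target `pwm` objects (or `pfm`s, converted internally).
#' @param min_overlap Minimum number of aligned columns (default 5, capped
#'   at the narrower motif's width).
#' @return A list with `similarity`, `offset` (query start relative to
#'   target start, 0-based), and `strand` (`"+"` or `"-"`).
#' @export
motif_similarity <- function(query, target, min_overlap = 5L) {
  as_pwm <- function(x) if (inherits(x, "pfm")) pfm_to_pwm(x) else x
  q <- as_pwm(query)
  t_ <- as_pwm(target)
  stopifnot(inherits(q, "pwm"), inherits(t_, "pwm"))
  mo <- min(min_overlap, ncol(q$probs), ncol(t_$probs))
  best <- list(similarity = -Inf, offset = NA_integer_, strand = NA_character_)
  for (strand in c("+", "-")) {
    qp <- if (strand == "+") q$probs else rc_matrix(q$probs)
    wq <- ncol(qp)
    wt <- ncol(t_$probs)
    for (off in (-(wq - mo)):(wt - mo)) {
      qi <- max(1L, 1L - off):min(wq, wt - off)
      ti <- qi + off
      a <- as.vector(qp[, qi, drop = FALSE])
      b <- as.vector(t_$probs[, ti, drop = FALSE])
      if (sd(a) < 1e-12 || sd(b) < 1e-12) next
      r <- cor(a, b)
      if (r > best$similarity) {
        best <- list(similarity = r, offset = off, strand = strand)
      }
    }
  }
  best
}

#' Best-hit PWM score of sequences
#'
#' Scans the PWM's log-odds matrix along both strands of each sequence and
#' keeps the best (maximum) window score: the sum of per-position log odds.
#' Windows containing `N` are skipped.
#'
#' @param x A `pwm`.
#' @param sequences Character vector of DNA sequences, each at least as
#'   long as the motif.
#' @return Numeric vector of best-hit scores.
#' @examples
#' m <- pwm_from_probs(matrix(c(.97, .01, .01, .01), 4, 1), id = "A1")
#' scan_best_hit(m, c("AAAA", "CCCC"))
#' @export
scan_best_hit <- function(x, sequences) {
  stopifnot(inherits(x, "pwm"), is.character(sequences))
  W <- ncol(x$log_odds)
  len <- nchar(sequences)
  if (any(len < W)) {
    abort(sprintf("sequence %d is shorter than the motif width %d",
                  which(len < W)[1], W))
  }
  los <- list(`+` = x$log_odds, `-` = rc_matrix(x$log_odds))
  vapply(sequences, function(s) {
    code <- seq_codes(toupper(s))
    L <- length(code)
    nw <- L - W + 1L
    best <- -Inf
    for (lo in los) {
      sc <- numeric(nw)
      for (k in seq_len(W)) {
        v <- lo[code[k:(k + nw - 1L)], k]
        sc <- sc + ifelse(is.na(v), -Inf, v)
      }
      best <- max(best, sc)
    }
    best
  }, numeric(1), USE.NAMES = FALSE)
}

#' Built-in synthetic demonstration motifs
#'
#' A small set of synthetic 8-bp PWMs (constructed for examples, tests and
#' simulations; not derived from any motif database). Each column gives the
#' consensus base probability 0.94 (a sharp, strong-TF-like site: instances
#' sampled from the PWM are reliably detectable by the PWM itself), the
#' rest split evenly.
#'
#' The 8-bp motifs suit planted-presence and count tasks; the 12-bp pair
#' (`ZNF_SYN`, `TBX_SYN`) is meant for distance-dependence analyses, where
#' two instances (span at least 24 bp) can never fit inside one
#' filter-width window.
#'
#' @param ids Which motifs to return (default all).
#' @return A named list of `pwm` objects.
#' @export
demo_motifs <- function(ids = c("GATA_SYN", "EBOX_SYN", "FKH_SYN",
                                "HOMEO_SYN", "ZNF_SYN", "TBX_SYN")) {
  cons <- c(
    GATA_SYN = "TGATAAGA", EBOX_SYN = "CACCTGGT",
    FKH_SYN = "TGTTTACA", HOMEO_SYN = "CTAATTAG",
    ZNF_SYN = "TGCGTGGGCGTA", TBX_SYN = "AGGTGTGAAATG"
  )
  ids <- match.arg(ids, several.ok = TRUE)
  out <- lapply(ids, function(id) {
    chars <- strsplit(cons[[id]], "")[[1]]
    probs <- matrix(0.02, 4L, length(chars), dimnames = list(DNA_BASES, NULL))
    probs[cbind(match(chars, DNA_BASES), seq_along(chars))] <- 0.94
    pwm_from_probs(probs, id = id)
  })
  setNames(out, ids)
}

#' Sample a motif instance from a PWM
#'
#' @param x A `pwm`.
#' @param consensus_only If TRUE, return the consensus string instead of a
#'   stochastic realization.
#' @return A DNA string of the motif's width.
#' @export
sample_instance <- function(x, consensus_only = FALSE) {
  stopifnot(inherits(x, "pwm"))
  if (consensus_only) {
    return(consensus(x))
  }
  paste(apply(x$probs, 2L, function(p) sample(DNA_BASES, 1L, prob = p)),
        collapse = "")
}
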