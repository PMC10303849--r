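#' Pairwise similarity matrix of motif profiles
#'
#' Symmetric matrix of [motif_similarity()] scores with unit diagonal,
#' used as the input to [farthest_point_sample()]. Externally computed
#' similarities (e.g. from a motif comparison tool) can be supplied
#' instead via [read_similarity_tsv()].
#'
#' @param profiles A list of [pfm()]s or `pwm`s.
#' @param min_overlap Minimum aligned columns.
#' @return A named numeric matrix.
#' @export
profile_similarity_matrix <- function(profiles, min_overlap = 5L) {
  pwms <- lapply(profiles, function(p) {
    if (inherits(p, "pfm")) pfm_to_pwm(p) else p
  })
  ids <- vapply(pwms, `[[`, character(1), "id")
  n <- length(pwms)
  sim <- diag(1, n)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        s <- motif_similarity(pwms[[i]], pwms[[j]],
                              min_overlap = min_overlap)$similarity
        sim[i, j] <- sim[j, i] <- if (is.finite(s)) s else 0
      }
    }
  }
  dimnames(sim) <- list(ids, ids)
  sim
}

#' Read a similarity table
#'
#' Three-column TSV (`query`, `target`, `score`) as produced by external
#' motif comparison tools; symmetrized by the maximum of the two
#' directions, missing pairs 0, diagonal 1.
#'
#' @param path File path.
#' @return A symmetric similarity matrix.
#' @export
read_similarity_tsv <- function(path) {
  tab <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  if (!all(c("query", "target", "score") %in% names(tab))) {
    abort("similarity TSV needs columns query, target, score")
  }
  ids <- sort(unique(c(tab$query, tab$target)))
  sim <- matrix(0, length(ids), length(ids), dimnames = list(ids, ids))
  for (k in seq_len(nrow(tab))) {
    i <- tab$query[k]
    j <- tab$target[k]
    sim[i, j] <- max(sim[i, j], tab$score[k])
    sim[j, i] <- sim[i, j]
  }
  diag(sim) <- 1
  sim
}

#' Farthest point sampling of motif profiles
#'
#' Greedy redundancy removal on a similarity matrix (distance = 1 -
#' similarity). The first pick is the most dissimilar profile -- the one
#' with the largest mean distance to all others; every subsequent pick
#' maximizes the minimum distance to the already-selected set.
#' Deterministic: ties are broken by id (column) order.
#'
#' @param similarity Symmetric similarity matrix with unit diagonal, ids as
#'   dimnames (or indices are used).
#' @param k Number of profiles to select.
#' @return Character vector of `k` selected ids, in pick order.
#' @export
farthest_point_sample <- function(similarity, k) {
  similarity <- as.matrix(similarity)
  n <- ncol(similarity)
  if (k > n) abort(sprintf("k = %d exceeds the %d available profiles", k, n))
  if (max(abs(similarity - t(similarity))) > 1e-8) {
    abort("similarity matrix must be symmetric")
  }
  ids <- colnames(similarity) %||% as.character(seq_len(n))
  dist <- 1 - similarity
  mean_to_others <- (rowSums(dist)) / (n - 1)
  picked <- integer(k)
  picked[1] <- which.max(mean_to_others) # ties: lowest index = id order
  if (k > 1L) {
    min_dist <- dist[, picked[1]]
    for (i in 2:k) {
      min_dist[picked[seq_len(i - 1L)]] <- -Inf
      picked[i] <- which.max(min_dist)
      min_dist <- pmin(min_dist, dist[, picked[i]])
    }
  }
  ids[picked]
}

#' Initialize unit filters from motif profiles
#'
#' Sets unit i's convolutional filter to the converted profile i
#' (resized to the filter width, then probabilities minus 0.25), records
#' the unit-to-profile mapping so unit annotations are known a priori, and
#' optionally freezes the filters: frozen filters receive nullified
#' gradients during training and are bit-identical afterwards, while the
#' fully connected and final linear layers keep learning.
#'
#' @param model A `seqnam_model` with as many units as profiles.
#' @param profiles A list of [pfm()]s (length `num_units`).
#' @param freeze Freeze the initialized filters (default FALSE).
#' @param pseudocount Pseudocount for the probability conversion.
#' @return The model, with a `filter_init` tibble (unit, profile id)
#'   attached.
#' @export
init_filters <- function(model, profiles, freeze = FALSE, pseudocount = 1) {
  stopifnot(inherits(model, "seqnam_model"))
  U <- model$config$num_units
  if (length(profiles) != U) {
    abort(sprintf("got %d profiles for %d units; counts must match",
                  length(profiles), U))
  }
  W <- model$config$filter_width
  for (u in seq_len(U)) {
    p <- profiles[[u]]
    if (!inherits(p, "pfm")) abort("profiles must be pfm objects")
    p <- resize_profile(p, target_width = W)
    fw <- profile_to_filter(pfm_to_pwm(p, pseudocount = pseudocount))
    # filter column layout is position-major (pos1 A,C,G,T, pos2 ...)
    model$params$filters[, u] <- as.vector(fw)
  }
  model$frozen_filters <- rep(isTRUE(freeze), U)
  model$filter_init <- tibble(
    unit = seq_len(U),
    profile_id = unname(vapply(profiles, `[[`, character(1), "id"))
  )
  model
}
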