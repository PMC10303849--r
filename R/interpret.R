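#' Collect per-unit filter activations
#'
#' For every unit and sequence, records the maximum of the unit's
#' post-activation convolution signal (evaluation mode) over all positions
#' and its argmax position (ties resolved to the lowest position), plus the
#' dataset-wide per-unit maximum. These are the quantities thresholded when
#' visualizing filters as motifs.
#'
#' @param model A `seqnam_model`.
#' @param data Sequences: character vector or data frame with `id` and
#'   `sequence`.
#' @param batch_size Internal batch size.
#' @return An object of class `activation_table` with elements `max`
#'   (n x U), `pos` (n x U, 1-based window starts), `unit_max` (length U),
#'   and `ids`.
#' @export
collect_activations <- function(model, data, batch_size = 1000L) {
  stopifnot(inherits(model, "seqnam_model"))
  seqs <- if (is.data.frame(data)) data$sequence else data
  ids <- if (is.data.frame(data) && "id" %in% names(data)) {
    data$id
  } else {
    as.character(seq_along(seqs))
  }
  check_lengths(seqs, model$config$input_length, ids)
  X <- encode_batch(seqs, ids)
  n <- nrow(X)
  U <- model$config$num_units
  mx <- matrix(0, n, U)
  pos <- matrix(0L, n, U)
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    res <- conv_activations_cpp(model$params, model$stats,
                                unclass(model$config),
                                X[rows, , drop = FALSE])
    mx[rows, ] <- res$max
    pos[rows, ] <- res$pos
  }
  structure(
    list(max = mx, pos = pos, unit_max = apply(mx, 2L, max), ids = ids),
    class = "activation_table"
  )
}

#' @export
print.activation_table <- function(x, ...) {
  cat(sprintf("<activation_table> %d sequences x %d units\n",
              nrow(x$max), ncol(x$max)))
  invisible(x)
}

#' Which sequences are correctly predicted
#'
#' The correctness predicate used to select sequences for filter
#' visualization and importance scoring. Binary tasks compare the
#' post-sigmoid prediction at 0.5 against the label (a sequence can be
#' correct on one task and not another); multiclass compares argmax
#' classes; regression with several tasks uses a per-sequence Pearson
#' correlation threshold, and single-output regression counts the better
#' half (absolute error at most the median absolute error).
#'
#' @param predictions n x T matrix of linear model outputs.
#' @param labels n x T label matrix.
#' @param task_type Task type string.
#' @param scope `"any_task"` (default; correct on at least one task),
#'   `"all_tasks"`, or a task index for per-task correctness.
#' @param regression_r Pearson threshold for multi-output regression
#'   (default 0.75).
#' @return Logical vector of length n.
#' @export
correct_predictions <- function(predictions, labels, task_type,
                                scope = "any_task", regression_r = 0.75) {
  predictions <- as.matrix(predictions)
  labels <- as.matrix(labels)
  n <- nrow(predictions)
  per_task <- switch(task_type,
    binary_multitask = (sigmoid(predictions) >= 0.5) == (labels >= 0.5),
    multiclass = {
      hit <- max.col(predictions, ties.method = "first") ==
        max.col(labels, ties.method = "first")
      matrix(hit, n, ncol(labels))
    },
    regression = {
      if (ncol(labels) >= 2L) {
        r <- vapply(seq_len(n), function(i) {
          suppressWarnings(cor(predictions[i, ], labels[i, ]))
        }, numeric(1))
        matrix(!is.na(r) & r >= regression_r, n, ncol(labels))
      } else {
        err <- abs(predictions[, 1] - labels[, 1])
        matrix(err <= median(err), n, 1L)
      }
    },
    abort(sprintf("unknown task type '%s'", task_type))
  )
  if (identical(scope, "any_task")) {
    rowSums(per_task) > 0
  } else if (identical(scope, "all_tasks")) {
    rowSums(per_task) == ncol(per_task)
  } else {
    per_task[, as.integer(scope)]
  }
}

#' Build a PFM from the sequences activating a unit
#'
#' Aligns the filter-width subsequence at the argmax activation position of
#' every sequence that (a) is correctly predicted and (b) activates the
#' unit at or above `fraction` of its dataset-wide maximum activation, and
#' counts bases per position. Reverse-complement copies present in `data`
#' count as their own sequences. If no sequence qualifies the returned PFM
#' is empty (zero sites, `attr(, "empty")` set) and the unit is not
#' interpretable.
#'
#' @param model A `seqnam_model`.
#' @param unit Unit index.
#' @param data A [labeled_dataset()] (the interpretation set, e.g. the
#'   held-out split, with reverse complements if they were used).
#' @param activations Optional precomputed [collect_activations()] result.
#' @param predictions Optional precomputed prediction matrix.
#' @param fraction Activation threshold as a fraction of the unit's
#'   dataset-wide maximum (default 0.5).
#' @param scope Correctness scope passed to [correct_predictions()].
#' @return A [pfm()] of the model's filter width.
#' @export
filter_to_pfm <- function(model, unit, data, activations = NULL,
                          predictions = NULL, fraction = 0.5,
                          scope = "any_task") {
  stopifnot(inherits(model, "seqnam_model"))
  unit <- as.integer(unit)
  tt <- dataset_task_type(data)
  if (is.null(activations)) activations <- collect_activations(model, data)
  if (is.null(predictions)) predictions <- predict(model, data)
  correct <- correct_predictions(predictions, dataset_labels(data), tt,
                                 scope = scope)
  qualifying <- correct &
    activations$max[, unit] >= fraction * activations$unit_max[unit]
  W <- model$config$filter_width
  counts <- matrix(0, 4L, W, dimnames = list(DNA_BASES, NULL))
  idx <- which(qualifying)
  for (i in idx) {
    kmer <- substr(toupper(data$sequence[i]), activations$pos[i, unit],
                   activations$pos[i, unit] + W - 1L)
    code <- seq_codes(kmer)
    ok <- !is.na(code)
    counts[cbind(code[ok], which(ok))] <-
      counts[cbind(code[ok], which(ok))] + 1
  }
  out <- pfm(counts, id = sprintf("unit%03d", unit), n_sites = length(idx))
  if (length(idx) == 0L) attr(out, "empty") <- TRUE
  out
}

#' Unit importance scores
#'
#' For each unit u and task t, the importance is the median over qualifying
#' sequences of `unit_output(u, s) * final_weight(u, t)` -- the unit's
#' exact additive contribution to the prediction. A sequence qualifies for
#' (u, t) when it is correctly predicted (per task for binary tasks) and
#' activates u's filter at or above `fraction` of its dataset-wide maximum
#' activation. Units with an empty qualifying set get an undefined (NA)
#' median, flagged rather than zeroed.
#'
#' @inheritParams filter_to_pfm
#' @param per_task_correct For binary tasks, use per-task correctness
#'   (default TRUE); otherwise the `"any_task"` rule.
#' @return An object of class `importance_matrix`: list with `medians`
#'   (U x T), `n_qualifying` (U x T), and `weights` (U x T).
#' @export
unit_importance <- function(model, data, activations = NULL,
                            predictions = NULL, fraction = 0.5,
                            per_task_correct = TRUE) {
  stopifnot(inherits(model, "seqnam_model"))
  tt <- dataset_task_type(data)
  if (is.null(activations)) activations <- collect_activations(model, data)
  pr <- predict(model, data, units = TRUE)
  if (is.null(predictions)) predictions <- pr$predictions
  O <- pr$unit_outputs
  labels <- dataset_labels(data)
  U <- model$config$num_units
  Tt <- model$config$num_tasks
  Wf <- model$params$Wf
  medians <- matrix(NA_real_, U, Tt)
  nq <- matrix(0L, U, Tt)
  act_ok <- activations$max >=
    matrix(activations$unit_max * fraction, nrow(O), U, byrow = TRUE)
  for (t_ in seq_len(Tt)) {
    correct <- if (tt == "binary_multitask" && per_task_correct) {
      correct_predictions(predictions, labels, tt, scope = t_)
    } else {
      correct_predictions(predictions, labels, tt, scope = "any_task")
    }
    for (u in seq_len(U)) {
      rows <- which(correct & act_ok[, u])
      nq[u, t_] <- length(rows)
      if (length(rows) > 0L) {
        medians[u, t_] <- median(O[rows, u] * Wf[u, t_])
      }
    }
  }
  structure(
    list(medians = medians, n_qualifying = nq, weights = Wf,
         fraction = fraction),
    class = "importance_matrix"
  )
}

#' @export
print.importance_matrix <- function(x, ...) {
  cat(sprintf("<importance_matrix> %d units x %d tasks (%d undefined)\n",
              nrow(x$medians), ncol(x$medians), sum(is.na(x$medians))))
  invisible(x)
}

#' Nullification impact of every unit
#'
#' Runs the model with each unit nullified in turn and reports the mean
#' prediction change on a dataset, the classical (and for this additive
#' architecture, exactly linear) unit-ablation oracle: the per-sequence
#' delta equals `-unit_output * final_weight`.
#'
#' @param model A `seqnam_model`.
#' @param data Sequences (character vector or data frame).
#' @param task Task index (default 1).
#' @return A tibble with columns `unit`, `mean_delta`, and `mean_abs_delta`.
#' @export
nullification_impact <- function(model, data, task = 1L) {
  base <- predict(model, data)[, task]
  out <- purrr::map(seq_len(model$config$num_units), function(u) {
    delta <- predict(nullify_unit(model, u), data)[, task] - base
    tibble(unit = u, mean_delta = mean(delta),
           mean_abs_delta = mean(abs(delta)))
  })
  dplyr::bind_rows(out)
}

#' Annotate unit motifs against a motif database
#'
#' Maps each query PWM to database profiles either with the external
#' `tomtom` comparator (matches kept at q-value below the threshold) or
#' with the built-in similarity (maximum Pearson correlation of aligned
#' probability columns over all offsets and both strands; matches kept at
#' or above the threshold).
#'
#' @param pwms A list of `pwm` objects (e.g. one per unit); `NULL` entries
#'   and empty PFMs are skipped.
#' @param motif_db A list of `pfm`/`pwm` objects (e.g. from
#'   [read_jaspar()]).
#' @param backend `"internal_similarity"` (default) or `"tomtom_external"`.
#' @param threshold Similarity threshold (default 0.8) or tomtom q-value
#'   cutoff (default 0.05).
#' @param min_overlap Minimum aligned columns for the internal backend.
#' @return A tibble with columns `unit`, `query_id`, `motif_id`,
#'   `similarity` (or `q_value`), `strand`; zero or more rows per unit.
#' @export
annotate_units <- function(pwms, motif_db,
                           backend = c("internal_similarity",
                                       "tomtom_external"),
                           threshold = NULL, min_overlap = 5L) {
  backend <- match.arg(backend)
  if (backend == "tomtom_external") {
    return(annotate_tomtom(pwms, motif_db, threshold %||% 0.05))
  }
  threshold <- threshold %||% 0.8
  db <- lapply(motif_db, function(m) if (inherits(m, "pfm")) pfm_to_pwm(m) else m)
  rows <- list()
  for (u in seq_along(pwms)) {
    q <- pwms[[u]]
    if (is.null(q)) next
    if (inherits(q, "pfm")) {
      if (isTRUE(attr(q, "empty"))) next
      q <- pfm_to_pwm(q)
    }
    for (m in db) {
      s <- motif_similarity(q, m, min_overlap = min_overlap)
      if (is.finite(s$similarity) && s$similarity >= threshold) {
        rows[[length(rows) + 1L]] <- tibble(
          unit = u, query_id = q$id, motif_id = m$id,
          similarity = s$similarity, strand = s$strand
        )
      }
    }
  }
  if (length(rows) == 0L) {
    return(tibble(unit = integer(), query_id = character(),
                  motif_id = character(), similarity = numeric(),
                  strand = character()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$unit, desc(.data$similarity))
}

annotate_tomtom <- function(pwms, motif_db, q_threshold) {
  if (Sys.which("tomtom") == "") {
    abort(paste0(
      "the 'tomtom' executable is not on the PATH; install the MEME suite ",
      "or use backend = \"internal_similarity\""
    ))
  }
  td <- tempfile("tomtom")
  dir.create(td)
  on.exit(unlink(td, recursive = TRUE), add = TRUE)
  keep <- !vapply(pwms, function(q) {
    is.null(q) || isTRUE(attr(q, "empty"))
  }, logical(1))
  qlist <- pwms[keep]
  units <- which(keep)
  for (i in seq_along(qlist)) {
    if (inherits(qlist[[i]], "pfm")) qlist[[i]] <- pfm_to_pwm(qlist[[i]])
    qlist[[i]]$id <- sprintf("q%d", units[i])
  }
  qf <- file.path(td, "query.meme")
  tf <- file.path(td, "targets.meme")
  write_meme(qlist, qf)
  write_meme(motif_db, tf)
  status <- system2("tomtom",
                    c("-norc", "-thresh", "1", "-oc", td, qf, tf),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0) abort("tomtom exited with a non-zero status")
  res <- readr::read_tsv(file.path(td, "tomtom.tsv"), comment = "#",
                         show_col_types = FALSE, progress = FALSE)
  res <- res[!is.na(res$`q-value`) & res$`q-value` <= q_threshold, ]
  tibble(
    unit = as.integer(sub("^q", "", res$Query_ID)),
    query_id = res$Query_ID, motif_id = res$Target_ID,
    q_value = res$`q-value`, strand = res$Orientation
  )
}
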