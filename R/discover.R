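#' Area under the precision-recall curve
#'
#' Step-wise (no linear interpolation): thresholds sweep the unique score
#' values in descending order; the area is the sum over threshold steps of
#' precision times the recall increment. A constant scorer therefore gets
#' the positive prevalence, and a perfect ranking gets 1.
#'
#' @param scores Numeric scores (higher = more positive).
#' @param labels Binary labels (0/1), same length; both classes must be
#'   present.
#' @return AUPRC in `[0, 1]`.
#' @examples
#' auprc(c(4, 3, 2, 1), c(1, 1, 0, 0)) # 1
#' @export
auprc <- function(scores, labels) {
  labels <- as.numeric(labels)
  if (length(scores) != length(labels)) abort("length mismatch")
  if (!all(labels %in% c(0, 1))) abort("labels must be 0/1")
  npos <- sum(labels == 1)
  nneg <- sum(labels == 0)
  if (npos == 0L || nneg == 0L) {
    abort("AUPRC needs at least one positive and one negative label")
  }
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  grp_end <- which(c(s[-1] != s[-length(s)], TRUE)) # last index per tie group
  tp <- cumsum(y)[grp_end]
  fp <- cumsum(1 - y)[grp_end]
  precision <- tp / (tp + fp)
  recall <- tp / npos
  sum(precision * diff(c(0, recall)))
}

#' Evaluate a PWM on a binary-labeled dataset
#'
#' Scores every sequence by its best PWM hit on either strand
#' ([scan_best_hit()]) and computes the AUPRC against the labels.
#'
#' @param x A `pwm`.
#' @param data A binary [labeled_dataset()] (single task).
#' @return AUPRC of the best-hit scores.
#' @export
evaluate_pwm <- function(x, data) {
  labels <- dataset_labels(data)
  if (ncol(labels) != 1L) abort("evaluate_pwm expects a single binary task")
  auprc(scan_best_hit(x, data$sequence), labels[, 1])
}

#' De novo motif discovery by importance-ranked filter extraction
#'
#' Trains one many-unit model on the training set, converts every unit's
#' filter to a PWM from its activating subsequences on the (augmented)
#' validation set, ranks the PWMs by unit importance, and scores each
#' surviving PWM by best-hit scanning on the validation set (AUPRC for
#' classification; Pearson correlation of best-hit scores against the
#' labels for regression). The best PWM is the one with the highest
#' validation score. Units with empty PFMs are excluded and logged in the
#' result table.
#'
#' @param train_set,val_set [labeled_dataset()]s. Binary single-task
#'   (bound/unbound), multiclass (enrichment cycles as classes), or
#'   single-output regression.
#' @param num_units Units in the discovery model (default 100).
#' @param config A [train_config()].
#' @param model_seed Seed for model initialization.
#' @param fraction Activation fraction for PFM construction.
#' @return An object of class `discovery_result`: list with `pwms` (ranked
#'   list), `table` (tibble: rank, unit, importance, n_sites, val_metric),
#'   `best` (index into `pwms`), and `model`.
#' @export
discover <- function(train_set, val_set, num_units = 100L,
                     config = train_config(), model_seed = 1L,
                     fraction = 0.5) {
  tt <- dataset_task_type(train_set)
  L <- nchar(train_set$sequence[1])
  Tt <- length(dataset_label_cols(train_set))
  cfg <- seqnam_config(num_units = num_units, input_length = L,
                       num_tasks = Tt)
  model <- build_model(cfg, seed = model_seed)
  model <- train_model(model, train_set, val_set, config)

  # Interpretation set: the validation split, with reverse complements when
  # they were part of training/validation.
  interp <- if (config$rc_augment) rc_augmented(val_set) else val_set
  act <- collect_activations(model, interp)
  preds <- predict(model, interp)
  imp <- unit_importance(model, interp, activations = act,
                         predictions = preds, fraction = fraction)
  # Ranking task: positive class for single-task problems, the last class
  # (highest enrichment cycle) for multiclass.
  rank_task <- if (tt == "multiclass") Tt else 1L
  importance <- imp$medians[, rank_task]

  pfms <- lapply(seq_len(num_units), function(u) {
    filter_to_pfm(model, u, interp, activations = act, predictions = preds,
                  fraction = fraction)
  })
  empty <- vapply(pfms, function(p) isTRUE(attr(p, "empty")), logical(1))

  metric <- rep(NA_real_, num_units)
  pwms <- vector("list", num_units)
  for (u in which(!empty)) {
    pwms[[u]] <- pfm_to_pwm(pfms[[u]])
    metric[u] <- if (tt == "regression") {
      suppressWarnings(cor(scan_best_hit(pwms[[u]], val_set$sequence),
                           dataset_labels(val_set)[, 1]))
    } else {
      lab <- if (tt == "multiclass") {
        as.numeric(dataset_labels(val_set)[, Tt] == 1)
      } else {
        dataset_labels(val_set)[, 1]
      }
      auprc(scan_best_hit(pwms[[u]], val_set$sequence), lab)
    }
  }

  ord <- order(!is.na(importance) * 1, importance, -seq_len(num_units),
               decreasing = TRUE)
  ord <- ord[!empty[ord]]
  if (length(ord) == 0L) {
    abort("every unit produced an empty PFM; train longer or add units")
  }
  table <- tibble(
    rank = seq_along(ord),
    unit = ord,
    importance = importance[ord],
    n_sites = vapply(pfms[ord], function(p) as.numeric(p$n_sites),
                     numeric(1)),
    val_metric = metric[ord]
  )
  structure(
    list(
      pwms = setNames(pwms[ord], sprintf("unit%03d", ord)),
      table = table,
      best = which.max(table$val_metric),
      excluded_units = which(empty),
      model = model
    ),
    class = "discovery_result"
  )
}

#' @export
print.discovery_result <- function(x, ...) {
  cat(sprintf(
    "<discovery_result> %d PWMs (%d units excluded); best: rank %d (unit %d, val %.3f)\n",
    nrow(x$table), length(x$excluded_units), x$best, x$table$unit[x$best],
    x$table$val_metric[x$best]
  ))
  invisible(x)
}

#' Best PWM from a discovery result
#'
#' @param x A `discovery_result`.
#' @return The `pwm` with the highest validation metric.
#' @export
best_pwm <- function(x) {
  stopifnot(inherits(x, "discovery_result"))
  x$pwms[[x$best]]
}
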