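#' Construct a labeled sequence dataset
#'
#' A labeled dataset is a tibble with an `id` column, a `sequence` column,
#' and one numeric column per task, tagged with the task type. Binary
#' multi-task labels are 0/1 per task; multiclass labels are one-hot over
#' classes; regression labels are real-valued.
#'
#' @param data Data frame with columns `id`, `sequence`, and label columns.
#' @param task_type One of `"binary_multitask"`, `"multiclass"`,
#'   `"regression"`.
#' @param label_cols Character vector naming the label columns; defaults to
#'   every column other than `id`, `sequence`, and `chrom`.
#' @return A tibble of class `seqnam_dataset`.
#' @export
labeled_dataset <- function(data, task_type = c("binary_multitask",
                                                "multiclass", "regression"),
                            label_cols = NULL) {
  task_type <- match.arg(task_type)
  stopifnot(all(c("id", "sequence") %in% names(data)))
  if (anyDuplicated(data$id)) {
    abort(sprintf("duplicate sequence id '%s'",
                  data$id[anyDuplicated(data$id)]))
  }
  if (is.null(label_cols)) {
    label_cols <- setdiff(names(data), c("id", "sequence", "chrom", "start",
                                         "end", "strand"))
  }
  if (length(label_cols) == 0L) abort("no label columns found")
  lab <- as.matrix(data[, label_cols, drop = FALSE])
  storage.mode(lab) <- "double"
  if (anyNA(lab)) abort("labels must be finite (no NA)")
  if (task_type == "binary_multitask" && !all(lab %in% c(0, 1))) {
    abort("binary_multitask labels must be 0/1")
  }
  if (task_type == "multiclass" &&
      !all(abs(rowSums(lab) - 1) < 1e-9 & lab %in% c(0, 1))) {
    abort("multiclass labels must be one-hot over classes")
  }
  out <- as_tibble(data)
  structure(out,
    class = c("seqnam_dataset", class(out)),
    task_type = task_type, label_cols = label_cols
  )
}

#' Dataset accessors
#'
#' Task type, label column names, and the numeric label matrix of a
#' [labeled_dataset()].
#'
#' @param data A [labeled_dataset()].
#' @return `dataset_task_type` a string; `dataset_label_cols` a character
#'   vector; `dataset_labels` an n x T numeric matrix.
#' @export
dataset_task_type <- function(data) {
  tt <- attr(data, "task_type")
  if (is.null(tt)) abort("not a labeled dataset (missing task_type)")
  tt
}

#' @rdname dataset_task_type
#' @export
dataset_label_cols <- function(data) {
  lc <- attr(data, "label_cols")
  if (is.null(lc)) abort("not a labeled dataset (missing label_cols)")
  lc
}

#' @rdname dataset_task_type
#' @export
dataset_labels <- function(data) {
  lab <- as.matrix(data[, dataset_label_cols(data), drop = FALSE])
  storage.mode(lab) <- "double"
  lab
}

# Rebuild the seqnam_dataset class/attrs after a row subset.
reclass_dataset <- function(rows_df, template) {
  structure(as_tibble(rows_df),
    class = class(template),
    task_type = attr(template, "task_type"),
    label_cols = attr(template, "label_cols")
  )
}

#' Split specification
#'
#' @param mode `"random_fractions"` (default) or `"by_chromosome"`.
#' @param fractions Train/validation/test fractions summing to 1
#'   (default 0.8/0.1/0.1).
#' @param stratify Preserve the class ratio of a binary label in every
#'   split (within one record per class).
#' @param val_chroms,test_chroms Chromosome names for the chromosome-held-out
#'   mode; must be disjoint. Remaining chromosomes train.
#' @return An object of class `split_spec`.
#' @export
split_spec <- function(mode = c("random_fractions", "by_chromosome"),
                       fractions = c(0.8, 0.1, 0.1), stratify = FALSE,
                       val_chroms = character(), test_chroms = character()) {
  mode <- match.arg(mode)
  if (mode == "random_fractions") {
    if (length(fractions) != 3L || any(fractions <= 0) ||
        abs(sum(fractions) - 1) > 1e-8) {
      abort("fractions must be 3 positive numbers summing to 1")
    }
  }
  if (length(intersect(val_chroms, test_chroms)) > 0L) {
    abort("val_chroms and test_chroms must be disjoint")
  }
  structure(list(mode = mode, fractions = fractions, stratify = stratify,
                 val_chroms = val_chroms, test_chroms = test_chroms),
            class = "split_spec")
}

#' Split a dataset into train/validation/test
#'
#' Random splitting draws a seeded permutation and cuts it at the requested
#' fractions (optionally stratified by a binary label so each split keeps
#' the class ratio within one record per class). Chromosome splitting
#' assigns records by membership of their `chrom` column.
#'
#' @param data A [labeled_dataset()].
#' @param spec A [split_spec()].
#' @param seed Integer seed.
#' @return A list with elements `train`, `val`, `test`.
#' @export
split_dataset <- function(data, spec = split_spec(), seed = 1L) {
  stopifnot(inherits(spec, "split_spec"))
  tt <- dataset_task_type(data)
  n <- nrow(data)
  if (n == 0L) abort("dataset is empty")

  if (spec$mode == "by_chromosome") {
    if (!"chrom" %in% names(data)) {
      abort("by_chromosome splitting requires a 'chrom' column")
    }
    in_val <- data$chrom %in% spec$val_chroms
    in_test <- data$chrom %in% spec$test_chroms
    idx <- list(
      train = which(!in_val & !in_test),
      val = which(in_val), test = which(in_test)
    )
  } else {
    cut3 <- function(ids) {
      m <- length(ids)
      n_tr <- floor(m * spec$fractions[1])
      n_va <- floor(m * spec$fractions[2])
      list(
        train = ids[seq_len(n_tr)],
        val = ids[n_tr + seq_len(n_va)],
        test = ids[(n_tr + n_va + 1):m]
      )
    }
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    if (isTRUE(spec$stratify)) {
      lab <- dataset_labels(data)
      if (ncol(lab) != 1L || !all(lab %in% c(0, 1))) {
        abort("stratified splitting requires a single binary label")
      }
      pos <- sample(which(lab[, 1] == 1))
      neg <- sample(which(lab[, 1] == 0))
      cp <- cut3(pos)
      cn <- cut3(neg)
      idx <- list(
        train = c(cp$train, cn$train),
        val = c(cp$val, cn$val),
        test = c(cp$test, cn$test)
      )
    } else {
      perm <- sample(n)
      idx <- cut3(perm)
    }
  }
  if (any(lengths(idx) == 0L)) {
    abort("a split came out empty; use a larger dataset or other fractions")
  }
  lapply(idx, function(i) reclass_dataset(data[sort(i), , drop = FALSE], data))
}

#' Training configuration
#'
#' @param learning_rate Adam learning rate (default 0.003).
#' @param batch_size Mini-batch size (default 100).
#' @param loss `"auto"` (from the task type), `"bce"` (binary cross-entropy
#'   on post-sigmoid outputs; the model's final layer stays linear and the
#'   sigmoid lives in the loss), `"mse"`, or `"cross_entropy"` (softmax over
#'   classes).
#' @param patience Early-stopping patience in epochs (default 10): stop when
#'   validation loss has not improved for this many consecutive epochs.
#' @param max_epochs Maximum epochs (default 100).
#' @param rc_augment Add the reverse complement of every training and
#'   validation sequence with identical labels (default TRUE).
#' @param seed Integer seed controlling shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(learning_rate = 0.003, batch_size = 100L,
                         loss = c("auto", "bce", "mse", "cross_entropy"),
                         patience = 10L, max_epochs = 100L,
                         rc_augment = TRUE, seed = 1L) {
  loss <- match.arg(loss)
  if (learning_rate <= 0) abort("learning_rate must be > 0")
  if (patience < 1L) abort("patience must be >= 1")
  structure(list(
    learning_rate = learning_rate, batch_size = as.integer(batch_size),
    loss = loss, patience = as.integer(patience),
    max_epochs = as.integer(max_epochs), rc_augment = isTRUE(rc_augment),
    seed = as.integer(seed)
  ), class = "train_config")
}

loss_for_task <- function(task_type) {
  switch(task_type,
    binary_multitask = "bce",
    multiclass = "cross_entropy",
    regression = "mse",
    abort(sprintf("unknown task type '%s'", task_type))
  )
}

sigmoid <- function(x) 1 / (1 + exp(-x))

# Loss value and gradient wrt predictions (linear outputs).
loss_grad <- function(pred, lab, loss) {
  n <- nrow(pred)
  if (loss == "bce") {
    p <- sigmoid(pred)
    eps <- 1e-12
    val <- -mean(lab * log(p + eps) + (1 - lab) * log(1 - p + eps))
    list(loss = val, dY = (p - lab) / length(lab))
  } else if (loss == "mse") {
    d <- pred - lab
    list(loss = mean(d * d), dY = 2 * d / length(lab))
  } else if (loss == "cross_entropy") {
    z <- pred - apply(pred, 1L, max)
    ez <- exp(z)
    sm <- ez / rowSums(ez)
    val <- -mean(log(rowSums(sm * lab) + 1e-12))
    list(loss = val, dY = (sm - lab) / n)
  } else {
    abort(sprintf("unknown loss '%s'", loss))
  }
}

#' Compute a training loss
#'
#' Reference implementation of the supported losses on linear model outputs
#' (the sigmoid/softmax used by `bce`/`cross_entropy` is applied inside).
#'
#' @param predictions n x T matrix of linear outputs.
#' @param labels n x T label matrix.
#' @param loss `"bce"`, `"mse"`, or `"cross_entropy"`.
#' @return The scalar loss.
#' @export
compute_loss <- function(predictions, labels, loss) {
  predictions <- as.matrix(predictions)
  labels <- as.matrix(labels)
  stopifnot(identical(dim(predictions), dim(labels)))
  loss_grad(predictions, labels, loss)$loss
}

# Reverse-complement augmentation of a labeled dataset.
rc_augmented <- function(data) {
  rc <- data
  rc$sequence <- reverse_complement(data$sequence)
  rc$id <- paste0(data$id, "_rc")
  reclass_dataset(dplyr::bind_rows(as_tibble(data), as_tibble(rc)), data)
}

#' Train a model
#'
#' Mini-batch Adam on the configured loss, with reverse-complement
#' augmentation of the training and validation sets, per-epoch validation,
#' and early stopping: training halts when the validation loss has not
#' improved for `patience` consecutive epochs (or at `max_epochs`), and the
#' parameters from the best validation epoch are returned. Filters flagged
#' as frozen receive nullified gradients and are bit-identical afterwards.
#'
#' @param model A `seqnam_model` whose input length matches the data.
#' @param train_set,val_set [labeled_dataset()]s of equal-length sequences.
#' @param config A [train_config()].
#' @return The trained model, with a `history` element (tibble of per-epoch
#'   train/validation loss) and training metadata in `meta`.
#' @export
train_model <- function(model, train_set, val_set, config = train_config()) {
  stopifnot(inherits(model, "seqnam_model"))
  tt <- dataset_task_type(train_set)
  loss <- if (config$loss == "auto") loss_for_task(tt) else config$loss
  ok <- switch(tt,
    binary_multitask = loss == "bce",
    multiclass = loss == "cross_entropy",
    regression = loss == "mse"
  )
  if (!isTRUE(ok)) {
    abort(sprintf("loss '%s' is incompatible with task type '%s'", loss, tt))
  }

  if (config$rc_augment) {
    train_set <- rc_augmented(train_set)
    val_set <- rc_augmented(val_set)
  }
  check_lengths(train_set$sequence, model$config$input_length, train_set$id)
  check_lengths(val_set$sequence, model$config$input_length, val_set$id)

  Xtr <- encode_batch(train_set$sequence, train_set$id)
  Ytr <- dataset_labels(train_set)
  Xva <- encode_batch(val_set$sequence, val_set$id)
  Yva <- dataset_labels(val_set)
  n <- nrow(Xtr)
  bs <- min(config$batch_size, n)

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)

  opt <- adam_init(model$params)
  popt <- list()
  best <- list(val = Inf, params = model$params, stats = model$stats,
               epoch = 0L)
  history <- vector("list", config$max_epochs)
  stale <- 0L

  for (epoch in seq_len(config$max_epochs)) {
    perm <- sample(n)
    starts <- seq(1L, n, by = bs)
    ep_loss <- 0
    ep_n <- 0L
    fast <- use_fast_path(model)
    for (s in starts) {
      rows <- perm[s:min(s + bs - 1L, n)]
      Xb <- Xtr[rows, , drop = FALSE]
      Yb <- Ytr[rows, , drop = FALSE]
      if (fast) {
        res <- nn_train_batch_cpp(
          model$params, model$stats, unclass(model$config), Xb, Yb, loss,
          model$frozen_filters, model$nullified
        )
        batch_loss <- res$loss
        grads <- res$grads
        new_stats <- res$new_stats
      } else {
        fwd <- nn_forward(model, Xb, mode = "train", need_cache = TRUE)
        lg <- loss_grad(fwd$predictions, Yb, loss)
        batch_loss <- lg$loss
        new_stats <- fwd$new_stats
        grads <- nn_backward(model, Xb, fwd, lg$dY)
      }
      if (!is.finite(batch_loss)) {
        abort(sprintf(
          "training diverged: non-finite loss at epoch %d; lower the learning rate",
          epoch
        ))
      }
      model$stats[names(new_stats)] <- new_stats
      step <- adam_step(model$params, grads, opt, config$learning_rate)
      model$params <- step$params
      opt <- step$state
      if (!is.null(grads$plug_heads)) {
        ps <- adam_step_plug(model, grads$plug_heads, popt,
                             config$learning_rate)
        model <- ps$model
        popt <- ps$pstate
      }
      ep_loss <- ep_loss + batch_loss * length(rows)
      ep_n <- ep_n + length(rows)
    }
    val_loss <- eval_loss(model, Xva, Yva, loss)
    history[[epoch]] <- tibble(
      epoch = epoch, train_loss = ep_loss / ep_n, val_loss = val_loss
    )
    if (val_loss < best$val) {
      best <- list(val = val_loss, params = model$params,
                   stats = model$stats, epoch = epoch)
      stale <- 0L
    } else {
      stale <- stale + 1L
    }
    if (stale >= config$patience) break
  }

  model$params <- best$params
  model$stats <- best$stats
  model$history <- dplyr::bind_rows(history)
  model$meta$trained <- TRUE
  model$meta$best_epoch <- best$epoch
  model$meta$best_val_loss <- best$val
  model$meta$loss <- loss
  model$meta$train_seed <- config$seed
  model
}

check_lengths <- function(sequences, L, ids) {
  len <- nchar(sequences)
  bad <- which(len != L)
  if (length(bad) > 0L) {
    abort(sprintf(
      "sequence '%s' has length %d but the model expects %d",
      ids[bad[1]], len[bad[1]], L
    ))
  }
  invisible(TRUE)
}

# Mean loss over a dataset in evaluation mode, computed in batches.
eval_loss <- function(model, X, Y, loss, batch = 1000L) {
  n <- nrow(X)
  total <- 0
  for (s in seq(1L, n, by = batch)) {
    rows <- s:min(s + batch - 1L, n)
    fwd <- nn_eval(model, X[rows, , drop = FALSE])
    total <- total + loss_grad(fwd$predictions,
                               Y[rows, , drop = FALSE], loss)$loss *
      length(rows)
  }
  total / n
}

#' Predict from a model
#'
#' Evaluation-mode forward pass (deterministic: dropout off, batch norm uses
#' running statistics). Predictions are always exactly the linear
#' combination of unit outputs and final-layer weights.
#'
#' @param object A `seqnam_model`.
#' @param data Character vector of sequences, a data frame with a
#'   `sequence` column, or a pre-encoded n x 4L batch matrix.
#' @param type `"link"` (linear outputs, default) or `"response"`
#'   (sigmoid-transformed, for binary tasks).
#' @param units If TRUE, also return per-sequence unit outputs.
#' @param batch_size Internal batch size.
#' @param ... Unused.
#' @return An n x T matrix of predictions, or (with `units = TRUE`) a list
#'   with `predictions` and `unit_outputs`.
#' @export
predict.seqnam_model <- function(object, data, type = c("link", "response"),
                                 units = FALSE, batch_size = 1000L, ...) {
  type <- match.arg(type)
  X <- as_encoded_batch(object, data)
  n <- nrow(X)
  preds <- matrix(0, n, object$config$num_tasks)
  O <- if (units) matrix(0, n, object$config$num_units) else NULL
  for (s in seq(1L, n, by = batch_size)) {
    rows <- s:min(s + batch_size - 1L, n)
    fwd <- nn_eval(object, X[rows, , drop = FALSE])
    preds[rows, ] <- fwd$predictions
    if (units) O[rows, ] <- fwd$unit_outputs
  }
  if (type == "response") preds <- sigmoid(preds)
  if (units) list(predictions = preds, unit_outputs = O) else preds
}

as_encoded_batch <- function(model, data) {
  if (is.matrix(data)) {
    if (ncol(data) != 4L * model$config$input_length) {
      abort("encoded batch has wrong width for this model")
    }
    return(data)
  }
  seqs <- if (is.data.frame(data)) data$sequence else data
  ids <- if (is.data.frame(data) && "id" %in% names(data)) data$id else NULL
  check_lengths(seqs, model$config$input_length,
                ids %||% as.character(seq_along(seqs)))
  encode_batch(seqs, ids)
}

#' Quantile-normalize a numeric vector
#'
#' Monotone rank-preserving transform mapping the empirical distribution to
#' uniform quantiles: value i maps to `(rank_i - 0.5) / n`, with ties given
#' their average rank (so tied inputs stay tied). An all-identical input
#' maps to the median target quantile 0.5.
#'
#' @param values Finite numeric vector.
#' @return Numeric vector of the same length in (0, 1).
#' @export
quantile_normalize <- function(values) {
  if (!all(is.finite(values))) abort("values must be finite")
  n <- length(values)
  r <- rank(values, ties.method = "average")
  (r - 0.5) / n
}
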