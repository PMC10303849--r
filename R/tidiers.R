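#' Tidy a fitted model
#'
#' One row per (unit, task) with the final linear-layer weight -- the
#' model's global explanation -- plus the unit's initializing profile id
#' when filters were database-initialized.
#'
#' @param x A `seqnam_model`.
#' @param ... Unused.
#' @return A tibble with columns `unit`, `task`, `weight` (and
#'   `profile_id` if available).
#' @method tidy seqnam_model
#' @export
tidy.seqnam_model <- function(x, ...) {
  Wf <- x$params$Wf
  out <- tidyr::expand_grid(
    unit = seq_len(nrow(Wf)), task = seq_len(ncol(Wf))
  )
  out$weight <- Wf[cbind(out$unit, out$task)]
  if (!is.null(x$filter_init)) {
    out <- left_join(out, x$filter_init, by = "unit")
  }
  out
}

#' Model summary
#'
#' @param x A `seqnam_model`.
#' @param ... Unused.
#' @return A one-row tibble of architecture and training facts.
#' @method glance seqnam_model
#' @export
glance.seqnam_model <- function(x, ...) {
  tibble(
    num_units = x$config$num_units,
    num_tasks = x$config$num_tasks,
    input_length = x$config$input_length,
    filter_width = x$config$filter_width,
    unit_head = x$config$unit_head,
    n_parameters = sum(vapply(x$params, length, integer(1))),
    trained = x$meta$trained,
    best_epoch = x$meta$best_epoch %||% NA_integer_,
    best_val_loss = x$meta$best_val_loss %||% NA_real_
  )
}

#' Tidy an importance matrix
#'
#' @param x An `importance_matrix` from [unit_importance()].
#' @param ... Unused.
#' @return A tibble with columns `unit`, `task`, `importance` (NA where
#'   the qualifying set was empty), `n_qualifying`, and `weight`.
#' @method tidy importance_matrix
#' @export
tidy.importance_matrix <- function(x, ...) {
  out <- tidyr::expand_grid(
    unit = seq_len(nrow(x$medians)), task = seq_len(ncol(x$medians))
  )
  idx <- cbind(out$unit, out$task)
  out$importance <- x$medians[idx]
  out$n_qualifying <- x$n_qualifying[idx]
  out$weight <- x$weights[idx]
  out
}

#' Tidy an activation table
#'
#' @param x An `activation_table` from [collect_activations()].
#' @param ... Unused.
#' @return A tibble with columns `id`, `unit`, `max_activation`,
#'   `position`.
#' @method tidy activation_table
#' @export
tidy.activation_table <- function(x, ...) {
  n <- nrow(x$max)
  U <- ncol(x$max)
  tibble(
    id = rep(x$ids, times = U),
    unit = rep(seq_len(U), each = n),
    max_activation = as.vector(x$max),
    position = as.vector(x$pos)
  )
}

#' Tidy a discovery result
#'
#' @param x A `discovery_result` from [discover()].
#' @param ... Unused.
#' @return The ranking table: one row per surviving PWM.
#' @method tidy discovery_result
#' @export
tidy.discovery_result <- function(x, ...) {
  x$table
}

#' Tidy a motif matrix
#'
#' @param x A `pfm` or `pwm`.
#' @param ... Unused.
#' @return A long tibble with columns `position`, `base`, and `count`
#'   (PFM) or `prob` and `log_odds` (PWM).
#' @method tidy pfm
#' @export
tidy.pfm <- function(x, ...) {
  w <- ncol(x$counts)
  tibble(
    position = rep(seq_len(w), each = 4L),
    base = rep(DNA_BASES, times = w),
    count = as.vector(x$counts)
  )
}

#' @rdname tidy.pfm
#' @method tidy pwm
#' @export
tidy.pwm <- function(x, ...) {
  w <- ncol(x$probs)
  tibble(
    position = rep(seq_len(w), each = 4L),
    base = rep(DNA_BASES, times = w),
    prob = as.vector(x$probs),
    log_odds = as.vector(x$log_odds)
  )
}

#' Plot a cooperativity profile
#'
#' Residual fold change against inter-motif distance, one line per series
#' (motif pair and control), with a ribbon of one standard error.
#'
#' @param object A `coop_profile` from [distance_dependence()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot coop_profile
#' @export
autoplot.coop_profile <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$distance, y = .data$fold_change,
                 colour = .data$series, fill = .data$series)
  ) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = 2^(.data$mean_log2_residual - .data$se),
                   ymax = 2^(.data$mean_log2_residual + .data$se)),
      alpha = 0.2, colour = NA
    ) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(
      x = "distance between motifs (bp)",
      y = "residual fold change",
      colour = NULL, fill = NULL
    ) +
    ggplot2::theme_minimal()
}

#' Heatmap of unit importances
#'
#' @param object An `importance_matrix`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot importance_matrix
#' @export
autoplot.importance_matrix <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = factor(.data$task), y = factor(.data$unit),
                 fill = .data$importance)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "task", y = "unit", fill = "importance") +
    ggplot2::theme_minimal()
}

#' Heatmap of final linear-layer weights
#'
#' @param object A `seqnam_model`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot seqnam_model
#' @export
autoplot.seqnam_model <- function(object, ...) {
  ggplot2::ggplot(
    tidy(object),
    ggplot2::aes(x = factor(.data$task), y = factor(.data$unit),
                 fill = .data$weight)
  ) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2() +
    ggplot2::labs(x = "task", y = "unit", fill = "weight") +
    ggplot2::theme_minimal()
}

#' Plot training history
#'
#' @param model A trained `seqnam_model`.
#' @return A ggplot of train and validation loss per epoch.
#' @export
plot_training_history <- function(model) {
  if (is.null(model$history)) abort("model has no training history")
  long <- tidyr::pivot_longer(model$history, -"epoch",
                              names_to = "set", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$loss,
                                     colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "epoch", y = "loss", colour = NULL) +
    ggplot2::theme_minimal()
}
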