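#' Model configuration
#'
#' Describes an additive convolutional model: `num_units` independent units,
#' each a single-filter convolution (width `filter_width`) followed by batch
#' normalization, an exponential activation, max pooling, and -- for the
#' default `two_fc_layers` head -- two fully connected layers; unit outputs
#' are combined by one linear layer with `num_tasks` outputs.
#'
#' @param num_units Number of independent units (U).
#' @param input_length Sequence length in bp (L).
#' @param num_tasks Number of outputs (T).
#' @param filter_width Convolutional filter width in bp (default 19).
#' @param pool_size,pool_stride Max-pooling kernel size and stride in
#'   positions (defaults 7 and 7).
#' @param fc_hidden Nodes in the first fully connected layer (default 100).
#' @param dropout_rate Dropout fraction on the first fully connected layer
#'   (default 0.30), in `[0, 1)`.
#' @param unit_activation Activation after the convolution: `"exponential"`
#'   (default; improves motif recovery in the filter) or `"relu"`.
#' @param unit_head `"two_fc_layers"` (default) or `"global_max_pool"`, the
#'   ablated head in which a unit's output is the maximum of its filter's
#'   activation anywhere on the sequence.
#' @return An object of class `seqnam_config`.
#' @examples
#' seqnam_config(num_units = 10, input_length = 100, num_tasks = 1)
#' @export
seqnam_config <- function(num_units, input_length, num_tasks,
                          filter_width = 19L, pool_size = 7L,
                          pool_stride = 7L, fc_hidden = 100L,
                          dropout_rate = 0.3,
                          unit_activation = c("exponential", "relu"),
                          unit_head = c("two_fc_layers", "global_max_pool")) {
  unit_activation <- match.arg(unit_activation)
  unit_head <- match.arg(unit_head)
  cfg <- list(
    num_units = as.integer(num_units),
    input_length = as.integer(input_length),
    num_tasks = as.integer(num_tasks),
    filter_width = as.integer(filter_width),
    pool_size = as.integer(pool_size),
    pool_stride = as.integer(pool_stride),
    fc_hidden = as.integer(fc_hidden),
    dropout_rate = dropout_rate,
    unit_activation = unit_activation,
    unit_head = unit_head
  )
  validate_config(cfg)
  structure(cfg, class = "seqnam_config")
}

validate_config <- function(cfg) {
  if (cfg$num_units < 1L) abort("num_units must be >= 1")
  if (cfg$num_tasks < 1L) abort("num_tasks must be >= 1")
  if (cfg$filter_width < 1L) abort("filter_width must be >= 1")
  if (cfg$dropout_rate < 0 || cfg$dropout_rate >= 1) {
    abort("dropout_rate must be in [0, 1)")
  }
  conv_len <- cfg$input_length - cfg$filter_width + 1L
  if (conv_len < cfg$pool_size) {
    abort(sprintf(
      paste0(
        "invalid geometry: convolution output length %d ",
        "(input_length %d - filter_width %d + 1) is smaller than ",
        "pool_size %d"
      ),
      conv_len, cfg$input_length, cfg$filter_width, cfg$pool_size
    ))
  }
  invisible(cfg)
}

#' Convolution/pooling shape bookkeeping
#'
#' Output lengths of an un-padded (valid) convolution of width `W` over a
#' length-`L` input followed by max pooling.
#'
#' @param L Input length (bp).
#' @param W Filter width (bp).
#' @param pool_size,pool_stride Pooling kernel and stride.
#' @return A list with `conv_len` (`L - W + 1`) and `pooled_len`
#'   (`floor((conv_len - pool_size) / pool_stride) + 1`).
#' @examples
#' conv_geometry(200, 19, 7, 7) # conv_len 182, pooled_len 26
#' @export
conv_geometry <- function(L, W, pool_size, pool_stride) {
  if (L < W) abort("input length L must be >= filter width W")
  conv_len <- as.integer(L - W + 1L)
  if (conv_len < pool_size) {
    abort(sprintf("conv output length %d < pool_size %d", conv_len, pool_size))
  }
  pooled_len <- as.integer(floor((conv_len - pool_size) / pool_stride) + 1L)
  list(conv_len = conv_len, pooled_len = pooled_len)
}

#' Build an additive convolutional model
#'
#' Constructs the model with freshly initialized parameters. Each unit is a
#' valid (un-padded) convolution with one filter of width W, batch
#' normalization, the configured activation, and max pooling; the default
#' head adds FC(`fc_hidden`) + batch norm + ReLU + dropout and FC(1) + batch
#' norm + ReLU. A single linear layer (U x T weights plus T biases, no
#' activation) combines the unit outputs, so predictions decompose exactly
#' into per-unit contributions. Equal seeds yield identical parameters.
#'
#' @param config A [seqnam_config()].
#' @param seed Integer seed for parameter initialization.
#' @return An object of class `seqnam_model`.
#' @export
build_model <- function(config, seed = 1L) {
  stopifnot(inherits(config, "seqnam_config"))
  validate_config(config)
  geo <- conv_geometry(
    config$input_length, config$filter_width,
    config$pool_size, config$pool_stride
  )
  U <- config$num_units
  H <- config$fc_hidden
  P <- geo$pooled_len
  W4 <- 4L * config$filter_width

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)

  unif <- function(nr, nc, fan_in) {
    k <- 1 / sqrt(fan_in)
    matrix(runif(nr * nc, -k, k), nr, nc)
  }
  params <- list(
    filters = unif(W4, U, W4),
    bn1_gamma = rep(1, U), bn1_beta = rep(0, U)
  )
  if (config$unit_head == "two_fc_layers") {
    params$W1 <- array(runif(P * H * U, -1 / sqrt(P), 1 / sqrt(P)),
      dim = c(P, H, U)
    )
    params$bn2_gamma <- matrix(1, H, U)
    params$bn2_beta <- matrix(0, H, U)
    params$W2 <- unif(H, U, H)
    params$bn3_gamma <- rep(1, U)
    params$bn3_beta <- rep(0, U)
  }
  params$Wf <- unif(U, config$num_tasks, U)
  params$bf <- rep(0, config$num_tasks)

  stats <- list(
    bn1_mean = rep(0, U), bn1_var = rep(1, U)
  )
  if (config$unit_head == "two_fc_layers") {
    stats$bn2_mean <- matrix(0, H, U)
    stats$bn2_var <- matrix(1, H, U)
    stats$bn3_mean <- rep(0, U)
    stats$bn3_var <- rep(1, U)
  }

  structure(
    list(
      config = config,
      geometry = geo,
      params = params,
      stats = stats,
      frozen_filters = rep(FALSE, U),
      nullified = rep(FALSE, U),
      plugged = vector("list", U),
      meta = list(seed = seed, schema_version = 1L, trained = FALSE)
    ),
    class = "seqnam_model"
  )
}

#' Build the global-max-pool ablation
#'
#' Same as [build_model()] but every unit's fully connected head is replaced
#' by a global max over positions: the unit output equals the maximum
#' (post-activation) response of its filter anywhere on the sequence. Used
#' to show that the fully connected layers, not the filters, carry
#' positional (homotypic-cooperativity) information.
#'
#' @inheritParams build_model
#' @return A `seqnam_model` with `unit_head = "global_max_pool"`.
#' @export
build_global_maxpool_variant <- function(config, seed = 1L) {
  stopifnot(inherits(config, "seqnam_config"))
  cfg <- config
  cfg$unit_head <- "global_max_pool"
  build_model(cfg, seed = seed)
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
}

.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' @export
print.seqnam_model <- function(x, ...) {
  cfg <- x$config
  cat(sprintf(
    "<seqnam_model> %d units x %d tasks, input %d bp, filter %d bp, head %s\n",
    cfg$num_units, cfg$num_tasks, cfg$input_length, cfg$filter_width,
    cfg$unit_head
  ))
  cat(sprintf(
    "  trained: %s; frozen filters: %d; nullified units: %d\n",
    x$meta$trained, sum(x$frozen_filters), sum(x$nullified)
  ))
  invisible(x)
}

#' Final linear-layer weights
#'
#' The exact U x T weight matrix and T biases of the output layer; the
#' model's global explanation, since predictions are
#' `unit_outputs %*% weights + bias` with no further transformation.
#'
#' @param model A `seqnam_model`.
#' @return A list with `weights` (U x T) and `bias` (length T).
#' @export
final_layer_weights <- function(model) {
  stopifnot(inherits(model, "seqnam_model"))
  list(weights = model$params$Wf, bias = model$params$bf)
}

#' Nullify a unit
#'
#' Returns a copy of the model in which the given unit's output is forced
#' to zero for every input (its final-layer weights are also zeroed, the
#' equivalent operation on predictions). All other units are untouched; the
#' original model is not modified. Because the final layer is linear, the
#' prediction change from nullifying unit u on sequence s is exactly
#' `-unit_output(u, s) * weight(u, t)`.
#'
#' @param model A `seqnam_model`.
#' @param unit Unit index in `1..num_units`.
#' @return The modified model.
#' @export
nullify_unit <- function(model, unit) {
  stopifnot(inherits(model, "seqnam_model"))
  unit <- as.integer(unit)
  if (unit < 1L || unit > model$config$num_units) {
    abort(sprintf("unit index %d out of range 1..%d", unit,
                  model$config$num_units))
  }
  model$nullified[unit] <- TRUE
  model$params$Wf[unit, ] <- 0
  model
}

#' Replace a unit with a pluggable submodel
#'
#' Swaps the layers of one unit for an arbitrary pretrained
#' sequence-to-scalar predictor (an R function taking an L x 4 one-hot
#' matrix and returning one number). With `head = "fc_head_200"` the
#' submodel output is passed through a trainable 200-node fully connected
#' layer with ReLU and projected back to a scalar. Plugged submodels are
#' treated as fixed feature extractors: their parameters are never updated
#' by training (the `freeze` contract holds trivially for function
#' submodels), while head parameters and the final linear layer remain
#' trainable.
#'
#' @param model A `seqnam_model`.
#' @param unit Unit index to replace.
#' @param submodel Function of one L x 4 one-hot matrix returning a scalar.
#' @param freeze Logical; kept for the freeze contract (function submodels
#'   are always fixed).
#' @param head `"none"` (unit output is `submodel(x)`) or `"fc_head_200"`.
#' @param seed Seed for head parameter initialization.
#' @return The modified model.
#' @export
plug_unit <- function(model, unit, submodel, freeze = TRUE,
                      head = c("none", "fc_head_200"), seed = 1L) {
  stopifnot(inherits(model, "seqnam_model"), is.function(submodel))
  head <- match.arg(head)
  unit <- as.integer(unit)
  if (unit < 1L || unit > model$config$num_units) {
    abort(sprintf("unit index %d out of range", unit))
  }
  probe <- matrix(0, model$config$input_length, 4L)
  probe[, 1L] <- 1
  out <- tryCatch(submodel(probe), error = function(e) {
    abort(paste0("submodel failed on a length-",
                 model$config$input_length, " one-hot input: ",
                 conditionMessage(e)))
  })
  if (!is.numeric(out) || length(out) != 1L) {
    abort("submodel must return a single numeric value")
  }
  plug <- list(fn = submodel, freeze = isTRUE(freeze), head = head)
  if (head == "fc_head_200") {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(seed)
    plug$head_params <- list(
      v1 = runif(200, -1, 1), b1 = rep(0, 200),
      v2 = runif(200, -1 / sqrt(200), 1 / sqrt(200)), b2 = 0
    )
  }
  model$plugged[[unit]] <- plug
  model
}

#' Save / load a model checkpoint
#'
#' Single-file checkpoint holding the configuration, all parameters and
#' batch-norm statistics, and training metadata, with a schema version.
#'
#' @param model A `seqnam_model`.
#' @param path File path.
#' @return `save_model` returns `path` invisibly; `load_model` returns the
#'   model.
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "seqnam_model"))
  if (any(!vapply(model$plugged, is.null, logical(1)))) {
    warn("plugged submodels are saved as closures; portability not guaranteed")
  }
  saveRDS(unclass(model), path)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  obj <- readRDS(path)
  if (is.null(obj$meta$schema_version)) {
    abort("not a seqnam model checkpoint (missing schema_version)")
  }
  structure(obj, class = "seqnam_model")
}
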