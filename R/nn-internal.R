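# Internal forward/backward engine.
#
# Batch layout: X is n x (4L), position-major (see encode_batch), so the
# convolution window starting at position w is the contiguous column block
# 4(w-1)+1 .. 4(w-1)+4W and the whole convolution is conv_len small matrix
# products against the (4W) x U filter matrix.
#
# Convolution scores are kept as an (n * conv_len) x U matrix M with rows
# grouped window-major (row (w-1)*n + i is window w of sequence i), which
# makes batch norm a per-column operation and pooling a strided row gather.

BN_EPS <- 1e-5
BN_MOMENTUM <- 0.1
EXP_CLIP <- 20 # pre-activation clip before exponentiation (overflow guard)

# Batch norm over columns. x: m x k matrix; gamma/beta/rmean/rvar length k.
# In train mode returns batch stats and normalized values plus updated
# running stats (PyTorch convention: biased variance for normalization,
# unbiased for the running update).
bn_forward <- function(x, gamma, beta, rmean, rvar, train) {
  m <- nrow(x)
  k <- ncol(x)
  colrep <- function(v) rep.int(v, rep.int(m, k))
  if (train) {
    mu <- colMeans(x)
    xc <- x - colrep(mu)
    var_b <- colMeans(xc * xc)
    ivar <- 1 / sqrt(var_b + BN_EPS)
    xhat <- xc * colrep(ivar)
    y <- xhat * colrep(gamma) + colrep(beta)
    var_u <- if (m > 1L) var_b * m / (m - 1L) else var_b
    list(
      y = y, xhat = xhat, ivar = ivar,
      rmean = (1 - BN_MOMENTUM) * rmean + BN_MOMENTUM * mu,
      rvar = (1 - BN_MOMENTUM) * rvar + BN_MOMENTUM * var_u
    )
  } else {
    ivar <- 1 / sqrt(rvar + BN_EPS)
    xhat <- (x - colrep(rmean)) * colrep(ivar)
    y <- xhat * colrep(gamma) + colrep(beta)
    list(y = y, xhat = xhat, ivar = ivar, rmean = rmean, rvar = rvar)
  }
}

# Backward through train-mode batch norm. dy: m x k; returns dx, dgamma, dbeta.
bn_backward <- function(dy, xhat, ivar, gamma) {
  m <- nrow(dy)
  k <- ncol(dy)
  colrep <- function(v) rep.int(v, rep.int(m, k))
  dgamma <- colSums(dy * xhat)
  dbeta <- colSums(dy)
  dxhat <- dy * colrep(gamma)
  s1 <- colSums(dxhat)
  s2 <- colSums(dxhat * xhat)
  dx <- (dxhat * m - colrep(s1) - xhat * colrep(s2)) * colrep(ivar / m)
  list(dx = dx, dgamma = dgamma, dbeta = dbeta)
}

unit_activation_forward <- function(z, kind) {
  if (kind == "exponential") {
    zc <- pmin(z, EXP_CLIP)
    a <- exp(zc)
    list(a = a, grad = a * (z < EXP_CLIP))
  } else {
    a <- pmax(z, 0)
    list(a = a, grad = (z > 0) * 1)
  }
}

# im2col: stack every filter window of the batch into an (n*conv_len) x 4W
# matrix with rows grouped window-major, so the whole convolution is one
# matrix product and the filter gradient one crossprod.
conv_im2col <- function(X, n, conv_len, W4) {
  Xw <- matrix(0, n * conv_len, W4)
  for (w in seq_len(conv_len)) {
    cols <- (4L * (w - 1L) + 1L):(4L * (w - 1L) + W4)
    Xw[((w - 1L) * n + 1L):(w * n), ] <- X[, cols, drop = FALSE]
  }
  Xw
}

# Strided max pooling on the window-major matrix A ((n*conv_len) x U).
# Returns pooled (n*P) x U (rows grouped pooled-window-major) and the
# argmax member k (1..pool_size) per entry.
pool_forward <- function(A, n, conv_len, pool_size, pool_stride) {
  P <- as.integer(floor((conv_len - pool_size) / pool_stride) + 1L)
  U <- ncol(A)
  best <- matrix(-Inf, n * P, U)
  argk <- matrix(1L, n * P, U)
  base <- (seq_len(P) - 1L) * pool_stride # 0-based start of each window
  for (k in seq_len(pool_size)) {
    rows <- as.vector(outer(seq_len(n), (base + k - 1L) * n, "+"))
    cand <- A[rows, , drop = FALSE]
    upd <- cand > best
    if (any(upd)) {
      best[upd] <- cand[upd]
      argk[upd] <- k
    }
  }
  list(pooled = best, argk = argk, P = P)
}

pool_backward <- function(dpooled, argk, n, conv_len, P,
                          pool_size, pool_stride, U) {
  dA <- matrix(0, n * conv_len, U)
  r <- seq_len(n * P)
  i <- (r - 1L) %% n + 1L
  g <- (r - 1L) %/% n + 1L
  for (u in seq_len(U)) {
    rows <- ((g - 1L) * pool_stride + argk[, u] - 1L) * n + i
    if (pool_stride >= pool_size) {
      dA[cbind(rows, u)] <- dpooled[, u]
    } else {
      agg <- rowsum(dpooled[, u], rows)
      dA[cbind(as.integer(rownames(agg)), u)] <- agg[, 1L]
    }
  }
  dA
}

# Full forward pass. X: n x 4L encoded batch. mode "train" uses batch stats
# and dropout (caller must manage the RNG); "eval" is deterministic.
# Returns predictions (n x T), unit_outputs (n x U), cache for backward,
# and updated running stats when training.
nn_forward <- function(model, X, mode = c("eval", "train"),
                       need_cache = FALSE) {
  mode <- match.arg(mode)
  train <- mode == "train"
  cfg <- model$config
  p <- model$params
  st <- model$stats
  n <- nrow(X)
  U <- cfg$num_units
  CL <- model$geometry$conv_len
  P <- model$geometry$pooled_len
  W4 <- 4L * cfg$filter_width
  H <- cfg$fc_hidden
  cache <- if (need_cache) list() else NULL

  Xw <- conv_im2col(X, n, CL, W4)
  M <- Xw %*% p$filters
  if (need_cache) cache$Xw <- Xw
  bn1 <- bn_forward(M, p$bn1_gamma, p$bn1_beta, st$bn1_mean, st$bn1_var, train)
  act <- unit_activation_forward(bn1$y, cfg$unit_activation)
  if (need_cache) {
    cache$bn1 <- bn1[c("xhat", "ivar")]
    cache$act_grad <- act$grad
  }
  new_stats <- list(bn1_mean = bn1$rmean, bn1_var = bn1$rvar)

  if (cfg$unit_head == "global_max_pool") {
    gp <- pool_forward(act$a, n, CL, CL, CL) # one window covering everything
    O <- gp$pooled # n x U
    if (need_cache) {
      cache$gmp_argk <- gp$argk
    }
  } else {
    pool <- pool_forward(act$a, n, CL, cfg$pool_size, cfg$pool_stride)
    if (need_cache) cache$pool <- pool["argk"]
    H1 <- matrix(0, n, H * U) # unit u occupies columns (u-1)*H + 1..u*H
    pool_mats <- vector("list", U)
    for (u in seq_len(U)) {
      pu <- matrix(pool$pooled[, u], n, P)
      pool_mats[[u]] <- pu
      H1[, ((u - 1L) * H + 1L):(u * H)] <- pu %*% p$W1[, , u]
    }
    if (need_cache) cache$pool_mats <- pool_mats
    gamma2 <- as.vector(p$bn2_gamma)
    beta2 <- as.vector(p$bn2_beta)
    bn2 <- bn_forward(H1, gamma2, beta2,
                      as.vector(st$bn2_mean), as.vector(st$bn2_var), train)
    relu2 <- pmax(bn2$y, 0)
    if (need_cache) {
      cache$bn2 <- bn2[c("xhat", "ivar")]
      cache$relu2_grad <- bn2$y > 0
    }
    new_stats$bn2_mean <- matrix(bn2$rmean, H, U)
    new_stats$bn2_var <- matrix(bn2$rvar, H, U)
    if (train && cfg$dropout_rate > 0) {
      keep <- 1 - cfg$dropout_rate
      mask <- matrix(
        (runif(n * H * U) < keep) / keep, n, H * U
      )
      h1d <- relu2 * mask
      if (need_cache) cache$drop_mask <- mask
    } else {
      h1d <- relu2
    }
    if (need_cache) cache$h1d <- h1d
    Z <- matrix(0, n, U)
    for (u in seq_len(U)) {
      Z[, u] <- h1d[, ((u - 1L) * H + 1L):(u * H), drop = FALSE] %*%
        p$W2[, u, drop = FALSE]
    }
    bn3 <- bn_forward(Z, p$bn3_gamma, p$bn3_beta, st$bn3_mean, st$bn3_var,
                      train)
    O <- pmax(bn3$y, 0)
    if (need_cache) {
      cache$bn3 <- bn3[c("xhat", "ivar")]
      cache$relu3_grad <- bn3$y > 0
    }
    new_stats$bn3_mean <- bn3$rmean
    new_stats$bn3_var <- bn3$rvar
  }

  # Plugged units override the computed unit output.
  plug_idx <- which(!vapply(model$plugged, is.null, logical(1)))
  if (length(plug_idx) > 0L) {
    L <- cfg$input_length
    for (u in plug_idx) {
      plug <- model$plugged[[u]]
      raw <- vapply(seq_len(n), function(i) {
        oh <- matrix(X[i, ], nrow = L, ncol = 4L, byrow = TRUE)
        as.numeric(plug$fn(oh))
      }, numeric(1))
      if (plug$head == "fc_head_200") {
        hp <- plug$head_params
        hpre <- outer(raw, hp$v1) + matrix(hp$b1, n, 200, byrow = TRUE)
        hrelu <- pmax(hpre, 0)
        O[, u] <- as.vector(hrelu %*% hp$v2) + hp$b2
        if (need_cache) {
          cache$plug_cache[[as.character(u)]] <-
            list(raw = raw, hrelu = hrelu, hgrad = hpre > 0)
        }
      } else {
        O[, u] <- raw
      }
    }
  }

  if (any(model$nullified)) O[, model$nullified] <- 0

  preds <- O %*% p$Wf + matrix(p$bf, n, cfg$num_tasks, byrow = TRUE)
  list(
    predictions = preds, unit_outputs = O, cache = cache,
    new_stats = if (train) new_stats else NULL
  )
}

# Backward pass from dY (n x T). Requires the cache of a train-mode forward
# on the same X. Returns gradients matching the names in model$params.
nn_backward <- function(model, X, fwd, dY) {
  cfg <- model$config
  p <- model$params
  n <- nrow(X)
  U <- cfg$num_units
  CL <- model$geometry$conv_len
  P <- model$geometry$pooled_len
  W4 <- 4L * cfg$filter_width
  H <- cfg$fc_hidden
  cache <- fwd$cache
  O <- fwd$unit_outputs

  grads <- list(
    Wf = crossprod(O, dY),
    bf = colSums(dY)
  )
  dO <- dY %*% t(p$Wf)
  if (any(model$nullified)) dO[, model$nullified] <- 0

  plug_idx <- which(!vapply(model$plugged, is.null, logical(1)))
  if (length(plug_idx) > 0L) {
    for (u in plug_idx) {
      plug <- model$plugged[[u]]
      if (plug$head == "fc_head_200") {
        pc <- cache$plug_cache[[as.character(u)]]
        hp <- plug$head_params
        dhr <- outer(dO[, u], hp$v2) * pc$hgrad
        grads$plug_heads[[as.character(u)]] <- list(
          v1 = colSums(dhr * pc$raw),
          b1 = colSums(dhr),
          v2 = colSums(pc$hrelu * dO[, u]),
          b2 = sum(dO[, u])
        )
      }
      dO[, u] <- 0 # no gradient into the (frozen) submodel or conv path
    }
  }

  if (cfg$unit_head == "global_max_pool") {
    dA <- pool_backward(dO, cache$gmp_argk, n, CL, 1L, CL, CL, U)
  } else {
    d3 <- dO * cache$relu3_grad
    bn3b <- bn_backward(d3, cache$bn3$xhat, cache$bn3$ivar, p$bn3_gamma)
    grads$bn3_gamma <- bn3b$dgamma
    grads$bn3_beta <- bn3b$dbeta
    dZ <- bn3b$dx
    dH1d <- matrix(0, n, H * U)
    grads$W2 <- matrix(0, H, U)
    for (u in seq_len(U)) {
      cols <- ((u - 1L) * H + 1L):(u * H)
      grads$W2[, u] <- crossprod(cache$h1d[, cols, drop = FALSE], dZ[, u])
      dH1d[, cols] <- outer(dZ[, u], p$W2[, u])
    }
    if (!is.null(cache$drop_mask)) dH1d <- dH1d * cache$drop_mask
    d2 <- dH1d * cache$relu2_grad
    bn2b <- bn_backward(d2, cache$bn2$xhat, cache$bn2$ivar,
                        as.vector(p$bn2_gamma))
    grads$bn2_gamma <- matrix(bn2b$dgamma, H, U)
    grads$bn2_beta <- matrix(bn2b$dbeta, H, U)
    dH1 <- bn2b$dx
    grads$W1 <- array(0, dim = c(P, H, U))
    dpooled <- matrix(0, n * P, U)
    for (u in seq_len(U)) {
      cols <- ((u - 1L) * H + 1L):(u * H)
      du <- dH1[, cols, drop = FALSE]
      grads$W1[, , u] <- crossprod(cache$pool_mats[[u]], du)
      dpooled[, u] <- as.vector(du %*% t(p$W1[, , u]))
    }
    dA <- pool_backward(dpooled, cache$pool$argk, n, CL, P,
                        cfg$pool_size, cfg$pool_stride, U)
  }

  dM <- dA * cache$act_grad
  bn1b <- bn_backward(dM, cache$bn1$xhat, cache$bn1$ivar, p$bn1_gamma)
  grads$bn1_gamma <- bn1b$dgamma
  grads$bn1_beta <- bn1b$dbeta
  dF <- crossprod(cache$Xw, bn1b$dx)
  if (any(model$frozen_filters)) {
    dF[, model$frozen_filters] <- 0 # gradient nullification freezes filters
  }
  grads$filters <- dF
  grads
}

has_plugged <- function(model) {
  any(!vapply(model$plugged, is.null, logical(1)))
}

# The compiled fast path mirrors the R reference exactly (same layouts,
# batch-norm conventions and dropout RNG order); it cannot host plugged
# function submodels, which keep the R path.
use_fast_path <- function(model) !has_plugged(model)

# Evaluation-mode forward through whichever engine applies.
nn_eval <- function(model, X) {
  if (use_fast_path(model)) {
    nn_eval_forward_cpp(model$params, model$stats, unclass(model$config),
                        X, model$nullified)
  } else {
    nn_forward(model, X, mode = "eval")
  }
}

# --- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  zero_like <- function(x) {
    if (is.list(x)) lapply(x, zero_like) else x * 0
  }
  list(m = lapply(params, zero_like), v = lapply(params, zero_like), t = 0L)
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  upd <- function(p, g, m, v) {
    m <- beta1 * m + (1 - beta1) * g
    v <- beta2 * v + (1 - beta2) * g * g
    p <- p - lr * (m / bc1) / (sqrt(v / bc2) + eps)
    list(p = p, m = m, v = v)
  }
  for (nm in names(grads)) {
    if (nm == "plug_heads") next
    if (is.null(params[[nm]])) next
    r <- upd(params[[nm]], grads[[nm]], state$m[[nm]], state$v[[nm]])
    params[[nm]] <- r$p
    state$m[[nm]] <- r$m
    state$v[[nm]] <- r$v
  }
  list(params = params, state = state)
}

# Separate Adam update for plugged-unit head parameters (nested lists).
adam_step_plug <- function(model, plug_grads, pstate, lr) {
  for (u in names(plug_grads)) {
    hp <- model$plugged[[as.integer(u)]]$head_params
    g <- plug_grads[[u]]
    if (is.null(pstate[[u]])) {
      pstate[[u]] <- list(
        m = lapply(hp, function(x) x * 0),
        v = lapply(hp, function(x) x * 0), t = 0L
      )
    }
    st <- pstate[[u]]
    st$t <- st$t + 1L
    bc1 <- 1 - 0.9^st$t
    bc2 <- 1 - 0.999^st$t
    for (nm in names(hp)) {
      st$m[[nm]] <- 0.9 * st$m[[nm]] + 0.1 * g[[nm]]
      st$v[[nm]] <- 0.999 * st$v[[nm]] + 0.001 * g[[nm]]^2
      hp[[nm]] <- hp[[nm]] - lr * (st$m[[nm]] / bc1) /
        (sqrt(st$v[[nm]] / bc2) + 1e-8)
    }
    model$plugged[[as.integer(u)]]$head_params <- hp
    pstate[[u]] <- st
  }
  list(model = model, pstate = pstate)
}
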