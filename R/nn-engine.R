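# ------------------------------------------------------------------
# In-package 1D-CNN training engine.
#
# Networks are small at the scale this package targets (a few conv blocks on
# a couple of hundred spectral points), so the engine is written in
# vectorised base R: convolutions run as a single matrix product on an
# im2col expansion, and all layer backward passes are closed-form.
# Everything is deterministic given the seed.
# ------------------------------------------------------------------

ACTIVATIONS <- list(
  ReLU = list(
    f = function(x) pmax(x, 0),
    df = function(x, y) (x > 0) * 1
  ),
  LeakyReLU = list(
    f = function(x) ifelse(x > 0, x, 0.01 * x),
    df = function(x, y) ifelse(x > 0, 1, 0.01)
  ),
  ELU = list(
    f = function(x) ifelse(x > 0, x, exp(pmin(x, 0)) - 1),
    df = function(x, y) ifelse(x > 0, 1, y + 1)
  ),
  SELU = list(
    f = function(x) {
      1.0507009873554805 * ifelse(x > 0, x, 1.6732632423543772 * (exp(pmin(x, 0)) - 1))
    },
    df = function(x, y) {
      1.0507009873554805 * ifelse(x > 0, 1, 1.6732632423543772 * exp(pmin(x, 0)))
    }
  ),
  Swish = list(
    f = function(x) x * stats::plogis(x),
    df = function(x, y) {
      s <- stats::plogis(x)
      s + x * s * (1 - s)
    }
  )
)

# conv im2col geometry: padded width, left pad and the [out_w, kernel]
# matrix of padded positions read by each output position
conv_geometry <- function(w_in, kernel, stride, padding, out_w) {
  if (padding == "Same") {
    pad_total <- max((out_w - 1L) * stride + kernel - w_in, 0L)
  } else {
    pad_total <- 0L
  }
  pl <- pad_total %/% 2L
  M <- outer(seq_len(out_w) - 1L, seq_len(kernel) - 1L,
             function(t, k) t * stride + k + 1L)
  list(pl = pl, w_pad = w_in + pad_total, M = M)
}

net_init <- function(arch, seed) {
  set.seed(seed)
  w <- arch$input_width
  ch <- arch$input_channels
  layers <- vector("list", length(arch$layers))
  for (i in seq_along(arch$layers)) {
    spec <- arch$layers[[i]]
    lay <- list(spec = spec, in_width = w, in_channels = ch)
    if (spec$layer_type == "convolutional") {
      fan_in <- spec$params$kernel * ch
      lay$W <- matrix(rnorm(fan_in * spec$params$filters, 0, sqrt(2 / fan_in)),
                      fan_in, spec$params$filters)
      lay$b <- numeric(spec$params$filters)
      lay$geom <- conv_geometry(w, spec$params$kernel, spec$params$stride,
                                spec$params$padding, spec$output_width)
    } else if (spec$layer_type == "dense") {
      fan_in <- w * ch
      lay$W <- matrix(rnorm(fan_in * spec$params$units, 0, sqrt(2 / fan_in)),
                      fan_in, spec$params$units)
      lay$b <- numeric(spec$params$units)
    } else if (spec$layer_type == "batch_norm") {
      d <- if (ch > 1L) ch else w
      lay$gamma <- rep(1, d)
      lay$beta <- rep(0, d)
      lay$run_mean <- rep(0, d)
      lay$run_var <- rep(1, d)
    } else if (spec$layer_type == "pooling") {
      lay$geom <- conv_geometry(w, spec$params$pool_size, spec$params$stride,
                                spec$params$padding, spec$output_width)
    }
    layers[[i]] <- lay
    w <- spec$output_width
    ch <- spec$output_channels
  }
  structure(list(arch = arch, layers = layers), class = "cnn_net")
}

# gather the im2col expansion: X [n, w_in, c] -> [n*out_w, kernel*c]
im2col <- function(X, geom, kernel, pad_value = 0) {
  n <- dim(X)[1]; w_in <- dim(X)[2]; c_in <- dim(X)[3]
  out_w <- nrow(geom$M)
  Xp <- array(pad_value, dim = c(n, geom$w_pad, c_in))
  Xp[, geom$pl + seq_len(w_in), ] <- X
  arr <- array(0, dim = c(n, out_w, kernel, c_in))
  for (c in seq_len(c_in)) {
    sub <- Xp[, as.vector(geom$M), c, drop = FALSE]
    dim(sub) <- c(n, out_w, kernel)
    arr[, , , c] <- sub
  }
  matrix(arr, n * out_w, kernel * c_in)
}

# scatter-add the im2col gradient back to input coordinates
col2im <- function(dXcol, geom, kernel, n, w_in, c_in) {
  out_w <- nrow(geom$M)
  arr <- array(dXcol, dim = c(n, out_w, kernel, c_in))
  dXp <- array(0, dim = c(n, geom$w_pad, c_in))
  for (c in seq_len(c_in)) {
    for (k in seq_len(kernel)) {
      pos <- geom$M[, k]
      dXp[, pos, c] <- dXp[, pos, c] + arr[, , k, c]
    }
  }
  dXp[, geom$pl + seq_len(w_in), , drop = FALSE]
}

layer_forward <- function(lay, X, training, caches_wanted = TRUE) {
  spec <- lay$spec
  type <- spec$layer_type
  cache <- NULL
  if (type == "convolutional") {
    n <- dim(X)[1]
    Xcol <- im2col(X, lay$geom, spec$params$kernel)
    Ymat <- sweep(Xcol %*% lay$W, 2L, lay$b, `+`)
    out <- array(Ymat, dim = c(n, spec$output_width, spec$params$filters))
    if (caches_wanted) cache <- list(Xcol = Xcol, n = n, dimX = dim(X))
  } else if (type == "dense") {
    out <- sweep(X %*% lay$W, 2L, lay$b, `+`)
    if (caches_wanted) cache <- list(X = X)
  } else if (type == "batch_norm") {
    conv_mode <- length(dim(X)) == 3L
    Xm <- if (conv_mode) matrix(X, prod(dim(X)[1:2]), dim(X)[3]) else X
    if (training) {
      m <- colMeans(Xm)
      v <- colMeans(Xm^2) - m^2
    } else {
      m <- lay$run_mean
      v <- lay$run_var
    }
    ivar <- 1 / sqrt(v + 1e-5)
    xhat <- sweep(sweep(Xm, 2L, m, `-`), 2L, ivar, `*`)
    Ym <- sweep(sweep(xhat, 2L, lay$gamma, `*`), 2L, lay$beta, `+`)
    out <- if (conv_mode) array(Ym, dim = dim(X)) else Ym
    if (caches_wanted) {
      cache <- list(xhat = xhat, ivar = ivar, conv_mode = conv_mode,
                    dimX = dim(X), batch_mean = m, batch_var = v,
                    training = training)
    }
  } else if (type == "activation") {
    act <- ACTIVATIONS[[spec$params$activation]]
    out_flat <- act$f(as.vector(X))
    out <- X
    out[] <- out_flat
    if (caches_wanted) cache <- list(x = X, y = out)
  } else if (type == "pooling") {
    n <- dim(X)[1]; c_in <- dim(X)[3]
    pk <- spec$params$pool_size
    G <- im2col(X, lay$geom, pk, pad_value = NA_real_)   # [n*out_w, pk*c]
    out_w <- spec$output_width
    out <- array(0, dim = c(n, out_w, c_in))
    argmax <- NULL; counts <- NULL
    if (spec$params$pool_type == "Max") {
      argmax <- matrix(0L, n * out_w, c_in)
      for (c in seq_len(c_in)) {
        sub <- G[, (c - 1L) * pk + seq_len(pk), drop = FALSE]
        sub_f <- sub
        sub_f[is.na(sub_f)] <- -Inf
        idx <- max.col(sub_f, ties.method = "first")
        argmax[, c] <- idx
        out[, , c] <- sub_f[cbind(seq_len(nrow(sub_f)), idx)]
      }
    } else {
      counts <- matrix(0L, n * out_w, c_in)
      for (c in seq_len(c_in)) {
        sub <- G[, (c - 1L) * pk + seq_len(pk), drop = FALSE]
        counts[, c] <- rowSums(!is.na(sub))
        out[, , c] <- rowMeans(sub, na.rm = TRUE)
      }
    }
    if (caches_wanted) {
      cache <- list(argmax = argmax, counts = counts, dimX = dim(X))
    }
  } else if (type == "dropout") {
    rate <- spec$params$rate
    if (training && rate > 0) {
      mask <- array(runif(length(X)) >= rate, dim = dim(X) %||% length(X))
      out <- X * mask / (1 - rate)
      if (caches_wanted) cache <- list(mask = mask, rate = rate)
    } else {
      out <- X
      if (caches_wanted) cache <- list(mask = NULL, rate = rate)
    }
  } else if (type == "flatten") {
    d <- dim(X)
    out <- matrix(X, d[1], d[2] * d[3])
    if (caches_wanted) cache <- list(dimX = d)
  } else {
    stop_spectratune(sprintf("Unknown layer type '%s'.", type),
                     "spectratune_infeasible")
  }
  list(out = out, cache = cache)
}

layer_backward <- function(lay, dY, cache) {
  spec <- lay$spec
  type <- spec$layer_type
  grads <- NULL
  if (type == "convolutional") {
    f <- spec$params$filters
    dYmat <- matrix(dY, cache$n * spec$output_width, f)
    grads <- list(W = crossprod(cache$Xcol, dYmat), b = colSums(dYmat))
    dXcol <- dYmat %*% t(lay$W)
    dX <- col2im(dXcol, lay$geom, spec$params$kernel, cache$n,
                 cache$dimX[2], cache$dimX[3])
  } else if (type == "dense") {
    grads <- list(W = crossprod(cache$X, dY), b = colSums(dY))
    dX <- dY %*% t(lay$W)
  } else if (type == "batch_norm") {
    dYm <- if (cache$conv_mode) matrix(dY, prod(cache$dimX[1:2]), cache$dimX[3]) else dY
    grads <- list(gamma = colSums(dYm * cache$xhat), beta = colSums(dYm))
    dxhat <- sweep(dYm, 2L, lay$gamma, `*`)
    if (cache$training) {
      N <- nrow(dYm)
      t1 <- sweep(dxhat, 2L, colMeans(dxhat), `-`)
      t2 <- sweep(cache$xhat, 2L, colMeans(dxhat * cache$xhat), `*`)
      dXm <- sweep(t1 - t2, 2L, cache$ivar, `*`)
    } else {
      dXm <- sweep(dxhat, 2L, cache$ivar, `*`)
    }
    dX <- if (cache$conv_mode) array(dXm, dim = cache$dimX) else dXm
  } else if (type == "activation") {
    act <- ACTIVATIONS[[spec$params$activation]]
    d <- act$df(as.vector(cache$x), as.vector(cache$y))
    dX <- cache$x
    dX[] <- as.vector(dY) * d
  } else if (type == "pooling") {
    n <- cache$dimX[1]; w_in <- cache$dimX[2]; c_in <- cache$dimX[3]
    pk <- spec$params$pool_size
    out_w <- spec$output_width
    dXp <- array(0, dim = c(n, lay$geom$w_pad, c_in))
    for (c in seq_len(c_in)) {
      dYsub <- matrix(dY[, , c], n, out_w)
      if (spec$params$pool_type == "Max") {
        idx <- matrix(cache$argmax[, c], n, out_w)
        for (k in seq_len(pk)) {
          contrib <- dYsub * (idx == k)
          pos <- lay$geom$M[, k]
          dXp[, pos, c] <- dXp[, pos, c] + contrib
        }
      } else {
        cnt <- matrix(cache$counts[, c], n, out_w)
        share <- dYsub / cnt
        for (k in seq_len(pk)) {
          pos <- lay$geom$M[, k]
          inside <- pos > lay$geom$pl & pos <= lay$geom$pl + w_in
          if (any(inside)) {
            dXp[, pos[inside], c] <- dXp[, pos[inside], c] +
              share[, inside, drop = FALSE]
          }
        }
      }
    }
    dX <- dXp[, lay$geom$pl + seq_len(w_in), , drop = FALSE]
  } else if (type == "dropout") {
    dX <- if (is.null(cache$mask)) dY else dY * cache$mask / (1 - cache$rate)
  } else if (type == "flatten") {
    dX <- array(dY, dim = cache$dimX)
  }
  list(dX = dX, grads = grads)
}

net_forward <- function(net, X, training = FALSE, keep_caches = FALSE) {
  caches <- if (keep_caches) vector("list", length(net$layers))
  for (i in seq_along(net$layers)) {
    res <- layer_forward(net$layers[[i]], X, training, keep_caches)
    X <- res$out
    if (keep_caches) caches[[i]] <- res$cache
  }
  list(out = X, caches = caches)
}

# backward pass from dOut; returns per-layer gradient lists
net_backward <- function(net, dOut, caches) {
  grads <- vector("list", length(net$layers))
  for (i in rev(seq_along(net$layers))) {
    res <- layer_backward(net$layers[[i]], dOut, caches[[i]])
    dOut <- res$dX
    grads[i] <- list(res$grads)
  }
  grads
}

# update running batch-norm statistics after a training-mode forward pass
net_update_bn <- function(net, caches, momentum = 0.9) {
  for (i in seq_along(net$layers)) {
    if (net$layers[[i]]$spec$layer_type == "batch_norm") {
      cc <- caches[[i]]
      net$layers[[i]]$run_mean <-
        momentum * net$layers[[i]]$run_mean + (1 - momentum) * cc$batch_mean
      net$layers[[i]]$run_var <-
        momentum * net$layers[[i]]$run_var + (1 - momentum) * cc$batch_var
    }
  }
  net
}

# ---- optimisers ---------------------------------------------------

PARAM_FIELDS <- c("W", "b", "gamma", "beta")

optimiser_defaults <- function(name) {
  switch(name,
    Adam = list(lr = 1e-3, beta1 = 0.9, beta2 = 0.999, eps = 1e-8),
    RMSProp = list(lr = 1e-3, rho = 0.9, eps = 1e-8),
    Adagrad = list(lr = 1e-2, eps = 1e-8),
    stop_spectratune(sprintf("Unknown optimiser '%s'.", name),
                     "spectratune_invalid_config")
  )
}

opt_state_init <- function(net) {
  lapply(net$layers, function(lay) {
    st <- list()
    for (f in PARAM_FIELDS) {
      if (!is.null(lay[[f]])) {
        z <- lay[[f]] * 0
        st[[f]] <- list(m = z, v = z, g2 = z)
      }
    }
    st
  })
}

opt_update <- function(net, grads, state, name, hp, step) {
  for (i in seq_along(net$layers)) {
    g <- grads[[i]]
    if (is.null(g)) next
    for (f in names(g)) {
      p <- net$layers[[i]][[f]]
      gr <- g[[f]]
      s <- state[[i]][[f]]
      if (name == "Adam") {
        s$m <- hp$beta1 * s$m + (1 - hp$beta1) * gr
        s$v <- hp$beta2 * s$v + (1 - hp$beta2) * gr^2
        mhat <- s$m / (1 - hp$beta1^step)
        vhat <- s$v / (1 - hp$beta2^step)
        p <- p - hp$lr * mhat / (sqrt(vhat) + hp$eps)
      } else if (name == "RMSProp") {
        s$v <- hp$rho * s$v + (1 - hp$rho) * gr^2
        p <- p - hp$lr * gr / (sqrt(s$v) + hp$eps)
      } else { # Adagrad
        s$g2 <- s$g2 + gr^2
        p <- p - hp$lr * gr / (sqrt(s$g2) + hp$eps)
      }
      net$layers[[i]][[f]] <- p
      state[[i]][[f]] <- s
    }
  }
  list(net = net, state = state)
}

# ---- training -----------------------------------------------------

#' Training settings
#'
#' Controls early stopping and optional overrides used when evaluating the
#' cross-validated objective. By default 15% of each training fold is held
#' out to monitor validation RMSE, training stops after `patience` epochs
#' without an improvement larger than `min_delta`, and the best-epoch
#' weights are restored.
#'
#' @param monitor_fraction Fraction of the training data held out for the
#'   early-stopping monitor (0 < f < 1).
#' @param patience Epochs without improvement before stopping (>= 1).
#' @param min_delta Minimum monitor-RMSE improvement that resets patience.
#' @param max_epochs Optional cap applied on top of a configuration's epoch
#'   budget (useful for fast desk-scale runs); `NULL` uses the
#'   configuration's value unchanged.
#' @param learning_rate Optional learning-rate override; `NULL` uses the
#'   per-optimiser default (Adam/RMSProp 1e-3, Adagrad 1e-2).
#' @return A `training_settings` list.
#' @export
training_settings <- function(monitor_fraction = 0.15, patience = 50L,
                              min_delta = 0, max_epochs = NULL,
                              learning_rate = NULL) {
  if (!is_number(monitor_fraction) || monitor_fraction <= 0 ||
      monitor_fraction >= 1) {
    stop_spectratune("`monitor_fraction` must be in (0, 1).",
                     "spectratune_invalid_config")
  }
  if (!is_count(patience)) {
    stop_spectratune("`patience` must be a positive integer.",
                     "spectratune_invalid_config")
  }
  structure(list(monitor_fraction = monitor_fraction,
                 patience = as.integer(patience), min_delta = min_delta,
                 max_epochs = max_epochs, learning_rate = learning_rate),
            class = "training_settings")
}

#' Train a network from an architecture specification
#'
#' Fits the network by mini-batch gradient descent on the mean squared
#' error, with early stopping on a monitor set. Targets are z-scaled
#' internally using training-set statistics and predictions are returned in
#' original units. Fully deterministic given `seed`.
#'
#' @param arch An `architecture` from [build_architecture()].
#' @param x Training inputs: array `n x width x channels` (a
#'   `channel_stack$data`).
#' @param y Training targets (original units).
#' @param monitor_x,monitor_y Held-out monitor data for early stopping;
#'   `NULL` disables early stopping.
#' @param optimiser `"Adam"`, `"RMSProp"` or `"Adagrad"`.
#' @param batch_size Mini-batch size; clamped to the training size.
#' @param max_epochs Epoch budget (>= 1).
#' @param settings A [training_settings()].
#' @param seed Integer seed for initialisation, shuffling and dropout.
#' @return A `cnn_model`: trained predictor with `epochs_run`,
#'   `monitor_rmse` trace and `status` (`"ok"` or `"failed"`).
#' @export
train_model <- function(arch, x, y, monitor_x = NULL, monitor_y = NULL,
                        optimiser = "Adam", batch_size = 32L,
                        max_epochs = 100L, settings = training_settings(),
                        seed = 1L) {
  n <- dim(x)[1]
  if (length(y) != n) {
    stop_spectratune("`y` length must match the number of samples.",
                     "spectratune_invalid_config")
  }
  if (!is_count(max_epochs)) {
    stop_spectratune("`max_epochs` must be a positive integer.",
                     "spectratune_invalid_config")
  }
  batch_size <- min(as.integer(batch_size), n)
  if (batch_size < 1L) {
    stop_spectratune("`batch_size` must be >= 1.", "spectratune_invalid_config")
  }
  y_center <- mean(y)
  y_scale <- stats::sd(y)
  if (!is.finite(y_scale) || y_scale < 1e-8) y_scale <- 1
  yt <- (y - y_center) / y_scale

  net <- net_init(arch, seed)
  hp <- optimiser_defaults(optimiser)
  if (!is.null(settings$learning_rate)) hp$lr <- settings$learning_rate
  state <- opt_state_init(net)

  monitor_on <- !is.null(monitor_x) && !is.null(monitor_y) &&
    length(monitor_y) > 0
  if (monitor_on) mt <- (monitor_y - y_center) / y_scale

  best_layers <- net$layers
  best_rmse <- Inf
  best_epoch <- 0L
  wait <- 0L
  monitor_trace <- numeric(0)
  status <- "ok"
  step <- 0L
  epochs_run <- 0L

  for (epoch in seq_len(max_epochs)) {
    perm <- sample.int(n)
    starts <- seq(1L, n, by = batch_size)
    diverged <- FALSE
    for (s in starts) {
      idx <- perm[s:min(s + batch_size - 1L, n)]
      xb <- x[idx, , , drop = FALSE]
      yb <- yt[idx]
      fw <- net_forward(net, xb, training = TRUE, keep_caches = TRUE)
      pred <- as.vector(fw$out)
      if (any(!is.finite(pred))) { diverged <- TRUE; break }
      dOut <- matrix(2 * (pred - yb) / length(yb), ncol = 1L)
      grads <- net_backward(net, dOut, fw$caches)
      net <- net_update_bn(net, fw$caches)
      step <- step + 1L
      upd <- opt_update(net, grads, state, optimiser, hp, step)
      net <- upd$net
      state <- upd$state
    }
    epochs_run <- epoch
    if (diverged) { status <- "failed"; break }
    if (monitor_on) {
      mp <- as.vector(net_forward(net, monitor_x)$out)
      if (any(!is.finite(mp))) { status <- "failed"; break }
      mr <- sqrt(mean((mp - mt)^2))
      monitor_trace <- c(monitor_trace, mr * y_scale)
      if (mr < best_rmse - settings$min_delta) {
        best_rmse <- mr
        best_layers <- net$layers
        best_epoch <- epoch
        wait <- 0L
      } else {
        wait <- wait + 1L
        if (wait >= settings$patience) break
      }
    }
  }
  if (monitor_on && is.finite(best_rmse)) net$layers <- best_layers

  structure(
    list(net = net, arch = arch, y_center = y_center, y_scale = y_scale,
         optimiser = optimiser, batch_size = batch_size,
         epochs_run = epochs_run,
         best_epoch = if (monitor_on) best_epoch else epochs_run,
         monitor_rmse = monitor_trace, status = status, seed = seed),
    class = "cnn_model"
  )
}

#' Predict from a trained network
#'
#' @param object A `cnn_model` from [train_model()].
#' @param newdata A `channel_stack` or a bare `n x width x channels` array.
#' @param ... Unused.
#' @return Numeric vector of predictions in original target units.
#' @export
predict.cnn_model <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "channel_stack")) newdata$data else newdata
  pred <- as.vector(net_forward(object$net, x)$out)
  pred * object$y_scale + object$y_center
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model> %s, %d epochs run (best %d), status %s\n",
              x$optimiser, x$epochs_run, x$best_epoch, x$status))
  invisible(x)
}
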