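#' Convert reflectance to absorbance
#'
#' Apparent absorbance `A = log10(1 / R)`, the standard chemometric
#' transform for diffuse-reflectance spectra.
#'
#' @param R Numeric vector or matrix of reflectance values, all strictly
#'   positive.
#' @return Absorbance with the same shape as `R`.
#' @examples
#' to_absorbance(c(1, 0.1, 0.01))  # 0, 1, 2
#' @export
to_absorbance <- function(R) {
  if (any(!is.finite(R)) || any(R <= 0)) {
    stop_spectratune("Reflectance must be strictly positive and finite.",
                     "spectratune_domain_error")
  }
  -log10(R)
}

#' Finite-difference spectral derivative
#'
#' Derivative with respect to the point index, computed by central
#' differences `(x[i+1] - x[i-1]) / 2` with one-sided differences at the two
#' borders so the output length equals the input length. The second
#' derivative is the first-derivative operator applied twice.
#'
#' @param x Numeric vector, or matrix with one spectrum per row.
#' @param order 1 or 2.
#' @return Same shape as `x`.
#' @examples
#' spectral_derivative(c(0, 1, 4, 9), 1)  # 1 2 4 5
#' @export
spectral_derivative <- function(x, order = 1L) {
  if (!order %in% c(1L, 2L)) {
    stop_spectratune("`order` must be 1 or 2.", "spectratune_domain_error")
  }
  if (is.matrix(x)) {
    min_len <- if (order == 1L) 2L else 3L
    if (ncol(x) < min_len) {
      stop_spectratune(sprintf("Need at least %d points for order %d.",
                               min_len, order),
                       "spectratune_domain_error")
    }
    d <- t(apply(x, 1L, deriv1))
    if (order == 2L) d <- t(apply(d, 1L, deriv1))
    dimnames(d) <- dimnames(x)
    return(d)
  }
  min_len <- if (order == 1L) 2L else 3L
  if (length(x) < min_len) {
    stop_spectratune(sprintf("Need at least %d points for order %d.",
                             min_len, order),
                     "spectratune_domain_error")
  }
  d <- deriv1(x)
  if (order == 2L) d <- deriv1(d)
  d
}

deriv1 <- function(x) {
  p <- length(x)
  c(x[2] - x[1],
    if (p > 2) (x[3:p] - x[1:(p - 2)]) / 2,
    x[p] - x[p - 1])
}

#' Standard normal variate transform
#'
#' Centres each spectrum and scales it to unit population (1/n) standard
#' deviation, removing multiplicative scatter effects.
#'
#' @param x Numeric vector, or matrix with one spectrum per row.
#' @param tol Spectra with population sd below `tol` are rejected as
#'   degenerate.
#' @return Same shape as `x`; every spectrum has mean 0 and population sd 1.
#' @examples
#' snv(c(1, 2, 3))
#' @export
snv <- function(x, tol = 1e-12) {
  snv_vec <- function(v) {
    s <- sd_pop(v)
    if (!is.finite(s) || s < tol) {
      stop_spectratune("Cannot SNV-transform a (near-)constant spectrum.",
                       "spectratune_degenerate_spectrum")
    }
    (v - mean(v)) / s
  }
  if (is.matrix(x)) {
    out <- t(apply(x, 1L, snv_vec))
    dimnames(out) <- dimnames(x)
    out
  } else {
    snv_vec(x)
  }
}

#' Preprocessing channel states
#'
#' The five candidate input channels, in their canonical order: reflectance
#' (R), absorbance (ABS), absorbance + first derivative (ABS+D1), absorbance
#' + second derivative (ABS+D2), absorbance + standard normal variate
#' (ABS+SNV). Each is a binary ON/OFF state; at least one must be ON to
#' model anything.
#'
#' @param reflectance,absorbance,abs_d1,abs_d2,abs_snv Logical flags.
#' @return A named logical vector of class `channel_states`.
#' @export
channel_states <- function(reflectance = TRUE, absorbance = FALSE,
                           abs_d1 = FALSE, abs_d2 = FALSE, abs_snv = FALSE) {
  st <- c("R" = isTRUE(reflectance), "ABS" = isTRUE(absorbance),
          "ABS+D1" = isTRUE(abs_d1), "ABS+D2" = isTRUE(abs_d2),
          "ABS+SNV" = isTRUE(abs_snv))
  structure(st, class = "channel_states")
}

channel_names_all <- function() c("R", "ABS", "ABS+D1", "ABS+D2", "ABS+SNV")

#' Assemble the multi-channel network input
#'
#' Computes every ON channel for each spectrum and stacks them into an
#' `n_samples x n_points x n_channels` array in the canonical channel order.
#' Derivative and SNV channels are computed on absorbance. Channels are
#' returned unscaled; fit a [channel_scaler()] on training data and apply it
#' with [scale_channels()] before training so no validation information
#' leaks into the scaling.
#'
#' @param ds A [spectra_dataset()].
#' @param states A [channel_states()] with at least one channel ON.
#' @return A `channel_stack`: list with `data` (3-d array) and
#'   `channel_names`.
#' @export
assemble_channels <- function(ds, states) {
  if (!inherits(states, "channel_states")) states <- do.call(channel_states, as.list(states))
  if (!any(states)) {
    stop_spectratune("At least one preprocessing channel must be ON.",
                     "spectratune_invalid_config")
  }
  R <- ds$reflectance
  A <- if (any(states[-1])) to_absorbance(R) else NULL
  chans <- list()
  if (states[["R"]]) chans[["R"]] <- R
  if (states[["ABS"]]) chans[["ABS"]] <- A
  if (states[["ABS+D1"]]) chans[["ABS+D1"]] <- spectral_derivative(A, 1L)
  if (states[["ABS+D2"]]) chans[["ABS+D2"]] <- spectral_derivative(A, 2L)
  if (states[["ABS+SNV"]]) chans[["ABS+SNV"]] <- snv(A)
  arr <- array(unlist(chans, use.names = FALSE),
               dim = c(nrow(R), ncol(R), length(chans)))
  structure(list(data = arr, channel_names = names(chans)),
            class = "channel_stack")
}

#' @export
print.channel_stack <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<channel_stack> %d samples x %d points x %d channels (%s)\n",
              d[1], d[2], d[3], paste(x$channel_names, collapse = ", ")))
  invisible(x)
}

#' Fit a per-channel standardiser
#'
#' One mean and one standard deviation per channel, pooled over all samples
#' and wavelengths of the (training) stack.
#'
#' @param stack A `channel_stack` from [assemble_channels()].
#' @return A `channel_scaler` with per-channel `mean` and `sd`.
#' @export
channel_scaler <- function(stack) {
  nc <- dim(stack$data)[3]
  m <- s <- numeric(nc)
  for (c in seq_len(nc)) {
    v <- stack$data[, , c]
    m[c] <- mean(v)
    s[c] <- stats::sd(as.vector(v))
    if (!is.finite(s[c]) || s[c] < 1e-12) s[c] <- 1
  }
  structure(list(mean = m, sd = s, channel_names = stack$channel_names),
            class = "channel_scaler")
}

#' Apply a per-channel standardiser
#'
#' @param stack A `channel_stack`.
#' @param scaler A [channel_scaler()] fitted on training data.
#' @return A standardised `channel_stack`.
#' @export
scale_channels <- function(stack, scaler) {
  if (!identical(stack$channel_names, scaler$channel_names)) {
    stop_spectratune("Scaler channels do not match the stack.",
                     "spectratune_invalid_config")
  }
  out <- stack
  for (c in seq_along(scaler$mean)) {
    out$data[, , c] <- (stack$data[, , c] - scaler$mean[c]) / scaler$sd[c]
  }
  out
}
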