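#' Output width of a 1D convolution or pooling stage
#'
#' Standard border semantics: `"Same"` pads symmetrically with zeros so the
#' output width is `ceiling(input_w / stride)`; `"Valid"` uses no padding,
#' giving `floor((input_w - kernel) / stride) + 1`.
#'
#' @param input_w Input width (>= 1).
#' @param kernel Kernel (or pool) size (>= 1).
#' @param stride Stride (>= 1).
#' @param padding `"Same"` or `"Valid"`.
#' @return Integer output width (>= 1); a `Valid` kernel wider than the
#'   input raises an infeasible-architecture error.
#' @examples
#' conv_output_width(211, 5, 4, "Same")   # 53
#' conv_output_width(10, 2, 2, "Valid")   # 5
#' @export
conv_output_width <- function(input_w, kernel, stride, padding) {
  if (!is_count(input_w) || !is_count(kernel) || !is_count(stride)) {
    stop_spectratune("Width, kernel and stride must be positive integers.",
                     "spectratune_infeasible")
  }
  padding <- match.arg(padding, c("Same", "Valid"))
  if (padding == "Same") {
    as.integer(ceiling(input_w / stride))
  } else {
    if (kernel > input_w) {
      stop_spectratune(
        sprintf("Valid padding with kernel %d on width-%d input is infeasible.",
                kernel, input_w),
        "spectratune_infeasible")
    }
    as.integer((input_w - kernel) %/% stride + 1L)
  }
}

layer_spec <- function(layer_type, params, output_width, output_channels) {
  list(layer_type = layer_type, params = params,
       output_width = as.integer(output_width),
       output_channels = as.integer(output_channels))
}

#' Build an architecture specification from a configuration
#'
#' Deterministically unrolls a configuration into an ordered layer list with
#' exact shape arithmetic and a trainable-parameter count — no weights, no
#' training. Each conv-block contributes conv, then batch norm (if ON),
#' activation, pooling (if ON) and dropout (if ON); a flatten layer joins
#' the conv stage to the FC-blocks (dense, batch norm if ON, activation,
#' dropout if ON); the output block is a single linear dense unit.
#'
#' @param config A configuration passing [validate_config()] for a space
#'   like [default_cnn_space()].
#' @param input_width Number of spectral points fed to the network.
#' @param input_channels Number of preprocessing channels; defaults to the
#'   number of ON channel flags in `config`.
#' @return An `architecture` object: `layers`, `input_width`,
#'   `input_channels`, `n_parameters`.
#' @examples
#' cfg <- lucas_reference_config()
#' arch <- build_architecture(cfg, input_width = 211)
#' arch$n_parameters
#' @export
build_architecture <- function(config, input_width,
                               input_channels = NULL) {
  if (is.null(input_channels)) {
    input_channels <- sum(config_channel_states(config))
  }
  if (!is_count(input_width) || !is_count(input_channels)) {
    stop_spectratune("Input width and channel count must be positive integers.",
                     "spectratune_infeasible")
  }
  layers <- list()
  w <- as.integer(input_width)
  ch <- as.integer(input_channels)
  add <- function(l) layers[[length(layers) + 1L]] <<- l

  for (i in seq_len(config$n_conv_blocks)) {
    g <- function(field) config[[sprintf("conv%d_%s", i, field)]]
    w_out <- conv_output_width(w, g("kernel"), g("stride"), g("padding"))
    add(layer_spec("convolutional",
                   list(kernel = g("kernel"), filters = g("filters"),
                        stride = g("stride"), padding = g("padding")),
                   w_out, g("filters")))
    w <- w_out; ch <- g("filters")
    if (identical(g("batch_norm"), "ON")) {
      add(layer_spec("batch_norm", list(), w, ch))
    }
    add(layer_spec("activation", list(activation = g("activation")), w, ch))
    if (identical(g("pooling"), "ON")) {
      w_out <- conv_output_width(w, g("pool_size"), g("pool_stride"),
                                 g("pool_padding"))
      add(layer_spec("pooling",
                     list(pool_type = g("pool_type"), pool_size = g("pool_size"),
                          stride = g("pool_stride"), padding = g("pool_padding")),
                     w_out, ch))
      w <- w_out
    }
    if (identical(g("dropout"), "ON")) {
      add(layer_spec("dropout", list(rate = config$conv_dropout_rate), w, ch))
    }
  }

  add(layer_spec("flatten", list(), w * ch, 1L))
  w <- w * ch; ch <- 1L

  n_fc <- config$n_fc_blocks %||% 0L
  for (j in seq_len(n_fc)) {
    g <- function(field) config[[sprintf("fc%d_%s", j, field)]]
    add(layer_spec("dense", list(units = g("nodes")), g("nodes"), 1L))
    w <- g("nodes")
    if (identical(g("batch_norm"), "ON")) {
      add(layer_spec("batch_norm", list(), w, 1L))
    }
    add(layer_spec("activation", list(activation = g("activation")), w, 1L))
    if (identical(g("dropout"), "ON")) {
      add(layer_spec("dropout", list(rate = config$fc_dropout_rate), w, 1L))
    }
  }
  add(layer_spec("dense", list(units = 1L, activation = "Linear"), 1L, 1L))

  arch <- structure(
    list(layers = layers, input_width = as.integer(input_width),
         input_channels = as.integer(input_channels), n_parameters = 0L),
    class = "architecture"
  )
  arch$n_parameters <- count_parameters(arch)
  arch
}

#' Count trainable parameters of an architecture
#'
#' Convolution: `(kernel * in_channels + 1) * filters`; dense:
#' `(in_features + 1) * units`; batch norm: `2 * channels` (scale and
#' shift; running statistics are not trainable and not counted).
#'
#' @param arch An `architecture` from [build_architecture()].
#' @return Integer parameter count.
#' @export
count_parameters <- function(arch) {
  w <- arch$input_width
  ch <- arch$input_channels
  total <- 0
  for (l in arch$layers) {
    total <- total + switch(l$layer_type,
      convolutional = (l$params$kernel * ch + 1) * l$params$filters,
      dense = (w * ch + 1) * l$params$units,
      batch_norm = 2 * (if (ch > 1) ch else w),
      0
    )
    w <- l$output_width
    ch <- l$output_channels
  }
  as.integer(total)
}

#' @export
print.architecture <- function(x, ...) {
  cat(sprintf("<architecture> input (%d x %d), %d layers, %s parameters\n",
              x$input_width, x$input_channels, length(x$layers),
              format(x$n_parameters, big.mark = ",")))
  print(as_tibble(x), n = Inf)
  invisible(x)
}

#' Architecture summary table
#'
#' One row per layer in the style of published CNN architecture tables:
#' layer type, kernel size, filters, padding type, stride, output width and
#' activation.
#'
#' @param x An `architecture`.
#' @param ... Unused.
#' @return A tibble with one row per layer.
#' @method as_tibble architecture
#' @export
as_tibble.architecture <- function(x, ...) {
  purrr::map_dfr(x$layers, function(l) {
    p <- l$params
    tibble::tibble(
      layer_type = l$layer_type,
      kernel_size = p$kernel %||% p$pool_size %||% NA_integer_,
      filters = p$filters %||% p$units %||% NA_integer_,
      padding = p$padding %||% NA_character_,
      stride = p$stride %||% NA_integer_,
      output_width = l$output_width,
      output_channels = l$output_channels,
      activation = p$activation %||% NA_character_,
      dropout_rate = p$rate %||% NA_real_
    )
  })
}

#' Reference optimal configuration for LUCAS-scale SOC modelling
#'
#' The known-good configuration used throughout the examples and tests: four
#' input channels (reflectance, absorbance, first and second absorbance
#' derivatives; SNV off), a single conv-block (55 filters, kernel 5, stride
#' 4, Same padding, SELU, batch norm / pooling / dropout all off), two
#' FC-blocks (251 nodes with ELU and 219 nodes with Swish, both with batch
#' norm and dropout on), dropout rate 0.22, Adam, batch size 1105 and a
#' 1448-epoch budget. On a 211-point, 4-channel input it yields a conv
#' output width of 53 and a flatten width of 2915.
#'
#' @return A named configuration list.
#' @export
lucas_reference_config <- function() {
  list(
    channel_R = "ON", channel_ABS = "ON", channel_ABS_D1 = "ON",
    channel_ABS_D2 = "ON", channel_ABS_SNV = "OFF",
    n_conv_blocks = 1L, n_fc_blocks = 2L,
    conv1_filters = 55L, conv1_kernel = 5L, conv1_stride = 4L,
    conv1_padding = "Same", conv1_batch_norm = "OFF",
    conv1_activation = "SELU", conv1_pooling = "OFF", conv1_dropout = "OFF",
    fc1_nodes = 251L, fc1_batch_norm = "ON", fc1_activation = "ELU",
    fc1_dropout = "ON",
    fc2_nodes = 219L, fc2_batch_norm = "ON", fc2_activation = "Swish",
    fc2_dropout = "ON",
    conv_dropout_rate = 0.25, fc_dropout_rate = 0.22,
    optimiser = "Adam", batch_size = 1105L, epochs = 1448L
  )
}
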