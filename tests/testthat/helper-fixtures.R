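# Shared fixtures, all generated in code.

# a 211-point grid directly (coarse instrument), cheap for training tests
coarse_grid <- function() wavelength_grid(400, 2500, 10)

tiny_dataset <- function(n = 40, seed = 1, noise_sd = 0.002, ...) {
  generate_spectra(
    synthetic_config(n_samples = n, noise_sd = noise_sd, seed = seed, ...),
    grid = coarse_grid()
  )
}

# minimal feasible configuration: one small conv block, one small FC block
tiny_config <- function(...) {
  cfg <- list(
    channel_R = "ON", channel_ABS = "OFF", channel_ABS_D1 = "OFF",
    channel_ABS_D2 = "OFF", channel_ABS_SNV = "OFF",
    n_conv_blocks = 1L, n_fc_blocks = 1L,
    conv1_filters = 4L, conv1_kernel = 3L, conv1_stride = 4L,
    conv1_padding = "Same", conv1_batch_norm = "OFF",
    conv1_activation = "ReLU", conv1_pooling = "OFF", conv1_dropout = "OFF",
    fc1_nodes = 8L, fc1_batch_norm = "OFF", fc1_activation = "ReLU",
    fc1_dropout = "OFF",
    conv_dropout_rate = 0.1, fc_dropout_rate = 0.1,
    optimiser = "Adam", batch_size = 16L, epochs = 100L
  )
  utils::modifyList(cfg, list(...))
}

# one-dimensional continuous space on [0, 1]
space_1d <- function(name = "x") search_space(list(hp_continuous(name, 0, 1)))

# build a history from explicit (config, value) pairs
history_from_values <- function(space, configs, values,
                                origin = "random") {
  h <- spectratune:::new_history(space)
  for (i in seq_along(configs)) {
    obj <- spectratune:::new_objective_value(values[i], values[i], "ok")
    h <- spectratune:::add_trial(h, configs[[i]], obj, 0, origin)
  }
  h
}

# uniform-random history over a space with an arbitrary objective function
random_history <- function(space, n, objective, seed = 1) {
  set.seed(seed)
  configs <- replicate(n, sample_config(space), simplify = FALSE)
  values <- vapply(configs, objective, 0)
  history_from_values(space, configs, values)
}
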