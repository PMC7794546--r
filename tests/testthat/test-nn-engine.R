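# analytic gradients are checked against central finite differences on a
# network exercising every layer type
test_that("backpropagated gradients match numerical differentiation", {
  cfg <- tiny_config(
    conv1_filters = 3L, conv1_kernel = 3L, conv1_stride = 2L,
    conv1_batch_norm = "ON", conv1_activation = "Swish",
    conv1_pooling = "ON", conv1_pool_type = "Max", conv1_pool_size = 2L,
    conv1_pool_stride = 2L, conv1_pool_padding = "Same",
    fc1_nodes = 4L, fc1_batch_norm = "ON", fc1_activation = "ELU"
  )
  check_grads <- function(cfg, tol = 1e-4) {
    arch <- build_architecture(cfg, input_width = 12, input_channels = 2)
    net <- spectratune:::net_init(arch, seed = 42)
    set.seed(9)
    X <- array(rnorm(5 * 12 * 2), dim = c(5, 12, 2))
    y <- rnorm(5)
    loss <- function(net) {
      p <- as.vector(spectratune:::net_forward(net, X, training = TRUE)$out)
      mean((p - y)^2)
    }
    fw <- spectratune:::net_forward(net, X, training = TRUE, keep_caches = TRUE)
    p <- as.vector(fw$out)
    grads <- spectratune:::net_backward(
      net, matrix(2 * (p - y) / length(y), ncol = 1), fw$caches)
    eps <- 1e-5
    set.seed(2)
    for (i in seq_along(net$layers)) {
      for (f in c("W", "b", "gamma", "beta")) {
        if (is.null(net$layers[[i]][[f]])) next
        par <- net$layers[[i]][[f]]
        for (j in sample(seq_along(par), min(4, length(par)))) {
          up <- net; up$layers[[i]][[f]][j] <- par[j] + eps
          dn <- net; dn$layers[[i]][[f]][j] <- par[j] - eps
          num <- (loss(up) - loss(dn)) / (2 * eps)
          g <- grads[[i]][[f]][j]
          expect_lt(abs(num - g) / max(1e-6, abs(num) + abs(g)), tol)
        }
      }
    }
  }
  check_grads(cfg)
  # and the Valid-padding / average-pooling / other-activation path
  check_grads(utils::modifyList(cfg, list(
    conv1_padding = "Valid", conv1_pool_type = "Average",
    conv1_pool_padding = "Valid", conv1_activation = "SELU",
    fc1_activation = "LeakyReLU")))
})

test_that("activation functions match their closed forms", {
  acts <- spectratune:::ACTIVATIONS
  x <- c(-2, -0.5, 0, 0.5, 2)
  expect_equal(acts$ReLU$f(x), pmax(x, 0))
  expect_equal(acts$LeakyReLU$f(-1), -0.01)
  expect_equal(acts$ELU$f(-1), exp(-1) - 1)
  expect_equal(acts$SELU$f(1), 1.0507009873554805)
  expect_equal(acts$Swish$f(2), 2 * plogis(2))
})

test_that("training is deterministic given the seed", {
  ds <- tiny_dataset(n = 30, seed = 20)
  stack <- assemble_channels(ds, channel_states())
  arch <- build_architecture(tiny_config(), input_width = 211,
                             input_channels = 1)
  fit <- function() {
    train_model(arch, stack$data, ds$target, optimiser = "Adam",
                batch_size = 10, max_epochs = 5, seed = 77)
  }
  m1 <- fit(); m2 <- fit()
  expect_identical(predict(m1, stack), predict(m2, stack))
})

test_that("a constant target is learnable to near-zero RMSE", {
  ds <- tiny_dataset(n = 30, seed = 21)
  ds$target <- rep(10, 30)
  stack <- assemble_channels(ds, channel_states())
  scaled <- scale_channels(stack, channel_scaler(stack))
  arch <- build_architecture(tiny_config(), input_width = 211,
                             input_channels = 1)
  m <- train_model(arch, scaled$data, ds$target, optimiser = "Adam",
                   batch_size = 30, max_epochs = 100,
                   settings = training_settings(learning_rate = 0.01),
                   seed = 5)
  expect_equal(m$status, "ok")
  # the z-scaled constant is the zero function; the net must drive its
  # output weights there
  expect_lt(rmse(ds$target, predict(m, scaled)), 0.1)
})

test_that("each optimiser reduces training loss on a learnable signal", {
  ds <- tiny_dataset(n = 40, seed = 22, noise_sd = 0)
  stack <- assemble_channels(ds, channel_states(TRUE, TRUE))
  scaled <- scale_channels(stack, channel_scaler(stack))
  arch <- build_architecture(
    tiny_config(conv1_filters = 8L, fc1_nodes = 32L,
                conv1_activation = "ELU", fc1_activation = "ELU"),
    input_width = 211, input_channels = 2)
  base <- rmse(ds$target, rep(mean(ds$target), 40))
  for (opt in c("Adam", "RMSProp", "Adagrad")) {
    m <- train_model(arch, scaled$data, ds$target, optimiser = opt,
                     batch_size = 8, max_epochs = 150, seed = 3)
    expect_equal(m$status, "ok")
    expect_lt(rmse(ds$target, predict(m, scaled)), 0.6 * base)
  }
})

test_that("early stopping halts on a stalled monitor and restores best weights", {
  ds <- tiny_dataset(n = 40, seed = 23)
  stack <- assemble_channels(ds, channel_states())
  scaled <- scale_channels(stack, channel_scaler(stack))
  arch <- build_architecture(tiny_config(), input_width = 211,
                             input_channels = 1)
  m <- train_model(arch, scaled$data[1:30, , , drop = FALSE], ds$target[1:30],
                   monitor_x = scaled$data[31:40, , , drop = FALSE],
                   monitor_y = ds$target[31:40],
                   optimiser = "Adam", batch_size = 30, max_epochs = 200,
                   settings = training_settings(patience = 3), seed = 1)
  expect_lt(m$epochs_run, 200)
  expect_equal(length(m$monitor_rmse), m$epochs_run)
  expect_equal(min(m$monitor_rmse), m$monitor_rmse[m$best_epoch])
})

test_that("batch sizes are clamped and inputs validated", {
  ds <- tiny_dataset(n = 12, seed = 24)
  stack <- assemble_channels(ds, channel_states())
  arch <- build_architecture(tiny_config(), input_width = 211,
                             input_channels = 1)
  m <- train_model(arch, stack$data, ds$target, batch_size = 500,
                   max_epochs = 2, seed = 1)
  expect_equal(m$batch_size, 12L)
  expect_error(train_model(arch, stack$data, ds$target[1:5], max_epochs = 2),
               class = "spectratune_invalid_config")
  expect_error(train_model(arch, stack$data, ds$target, max_epochs = 0),
               class = "spectratune_invalid_config")
})
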