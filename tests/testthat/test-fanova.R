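# ten-dimensional continuous space used across the importance tests
space_10d <- function() {
  search_space(lapply(1:10, function(i) hp_continuous(paste0("x", i), 0, 1)))
}

test_that("encoding keeps only independent hyperparameters", {
  sp <- default_cnn_space(n_samples = 64)
  h <- random_search(sp, surrogate_objective("quadratic"), n_trials = 50,
                     seed = 9)
  enc <- encode_history(h)
  expect_equal(nrow(enc$design), 50L)
  # conditionals (pool geometry, later blocks) are out
  expect_false(any(grepl("pool_size|pool_type|conv2_|fc2_", names(enc$design))))
  # unconditional hyperparameters are in
  expect_true(all(c("optimiser", "batch_size", "epochs", "channel_R",
                    "conv1_filters", "fc_dropout_rate") %in% names(enc$design)))
  expect_false(any(vapply(enc$design, anyNA, TRUE)))

  expect_error(encode_history(h, min_trials = 100),
               class = "spectratune_invalid_history")
})

test_that("never-varied hyperparameters are flagged as constant", {
  sp <- search_space(list(hp_continuous("x", 0, 1),
                          hp_categorical("fixed", "only")))
  h <- random_history(sp, 40, function(cfg) cfg$x, seed = 2)
  enc <- encode_history(h, min_trials = 30)
  expect_true(enc$columns$constant[enc$columns$name == "fixed"])
  expect_false(enc$columns$constant[enc$columns$name == "x"])
})

test_that("a hand-built stump marginalises by exact cell volumes", {
  # stump on x1 at 0.5, leaves 1 (left) and 3 (right), over [0,1]^2
  tree <- list(
    nodes = list(
      list(leaf = TRUE, value = 1),
      list(leaf = TRUE, value = 3),
      list(leaf = FALSE, var = 1L, type = "numeric", split = 0.5,
           left = 1L, right = 2L)
    ),
    root = 3L
  )
  columns <- tibble::tibble(
    name = c("x1", "x2"), kind = "continuous", group = "other",
    low = 0, high = 1, categories = list(NULL, NULL), constant = FALSE
  )
  m1 <- spectratune:::single_tree_marginal(tree, columns, 1L)
  expect_equal(m1$breaks, c(0, 0.5, 1))
  expect_equal(m1$values, c(1, 3))
  expect_equal(m1$mean, 2)
  expect_equal(m1$variance, 1)
  m2 <- spectratune:::single_tree_marginal(tree, columns, 2L)
  expect_equal(unique(m2$values), 2)
  expect_equal(m2$variance, 0)
  expect_equal(spectratune:::tree_total_variance(tree, columns), 1)
})

test_that("fitted-tree marginals match brute-force grid integration", {
  # data on the odd lattice (2j-1)/100: any midpoint of two observed values
  # is a multiple of 1/100, so every split threshold falls on a boundary of
  # the 100-bin quadrature grid and midpoint integration is exact
  set.seed(15)
  lattice <- seq(1 / 100, 1, by = 2 / 100)
  n <- 60
  df <- data.frame(x1 = sample(lattice, n, TRUE),
                   x2 = sample(lattice, n, TRUE))
  y <- sin(6 * df$x1) + 0.5 * df$x2 + rnorm(n, 0, 0.05)
  tree <- spectratune:::fit_tree(df, y, kinds = c("numeric", "numeric"),
                                 mtry = 2, min_leaf = 5)
  columns <- tibble::tibble(
    name = c("x1", "x2"), kind = "continuous", group = "other",
    low = 0, high = 1, categories = list(NULL, NULL), constant = FALSE
  )
  mids <- seq(1 / 200, 1 - 1 / 200, by = 1 / 100)
  grid <- expand.grid(x1 = mids, x2 = mids)
  pred <- spectratune:::predict_tree(tree, grid)
  pred_mat <- matrix(pred, nrow = length(mids))   # rows x1, cols x2
  total_var_grid <- mean(pred^2) - mean(pred)^2

  for (dim_j in 1:2) {
    marg <- spectratune:::single_tree_marginal(tree, columns, dim_j)
    grid_marg <- if (dim_j == 1) rowMeans(pred_mat) else colMeans(pred_mat)
    var_grid <- mean(grid_marg^2) - mean(grid_marg)^2
    expect_equal(marg$variance, var_grid, tolerance = 1e-6)
    # the marginal function itself matches, point by point
    step_vals <- marg$values[findInterval(mids, marg$breaks,
                                          rightmost.closed = TRUE)]
    expect_equal(step_vals, unname(grid_marg), tolerance = 1e-6)
  }
  expect_equal(spectratune:::tree_total_variance(tree, columns),
               total_var_grid, tolerance = 1e-6)
})

test_that("importance recovers a single active dimension", {
  sp <- space_10d()
  h <- random_history(sp, 400,
                      function(cfg) 3 * (cfg$x1 - 0.3)^2 + 5 * sin(6 * cfg$x1),
                      seed = 16)
  rep <- fanova(encode_history(h), n_trees = 32, seed = 1)
  tb <- tidy(rep)
  expect_gt(tb$fraction[tb$hyperparameter == "x1"], 0.8)
  expect_lt(max(tb$fraction[tb$hyperparameter != "x1"]), 0.05)
  expect_gt(rep$oob_r2, 0.8)
  # fractions plus the higher-order remainder account for all variance
  expect_equal(sum(tb$fraction) + rep$higher_order, 1, tolerance = 1e-6)
  expect_true(all(tb$fraction >= 0))
  expect_gte(rep$higher_order, 0)
})

test_that("two symmetric effects receive matching importance", {
  sp <- search_space(list(hp_continuous("x1", 0, 1),
                          hp_continuous("x2", 0, 1),
                          hp_continuous("x3", 0, 1)))
  h <- random_history(sp, 400, function(cfg) cfg$x1 + cfg$x2, seed = 17)
  tb <- tidy(fanova(encode_history(h), n_trees = 32, seed = 2))
  f1 <- tb$fraction[tb$hyperparameter == "x1"]
  f2 <- tb$fraction[tb$hyperparameter == "x2"]
  expect_lt(abs(f1 - f2), 0.1)
  expect_lt(tb$fraction[tb$hyperparameter == "x3"], 0.05)
})

test_that("categorical effects are picked up through subset splits", {
  sp <- search_space(list(hp_categorical("opt", c("A", "B", "C")),
                          hp_continuous("x", 0, 1)))
  h <- random_history(sp, 300,
                      function(cfg) c(A = 0, B = 2, C = 4)[[cfg$opt]],
                      seed = 18)
  tb <- tidy(fanova(encode_history(h), n_trees = 32, seed = 3))
  expect_gt(tb$fraction[tb$hyperparameter == "opt"], 0.8)
})

test_that("a constant objective yields a degenerate all-zero report", {
  sp <- space_10d()
  h <- random_history(sp, 60, function(cfg) 7, seed = 19)
  rep <- fanova(encode_history(h), n_trees = 8, seed = 4)
  expect_true(rep$degenerate)
  expect_true(all(rep$importance$fraction == 0))
})

test_that("importance is invariant to affine objective rescaling", {
  sp <- space_10d()
  f <- function(cfg) (cfg$x1 - 0.5)^2 + 0.3 * cfg$x2
  h1 <- random_history(sp, 200, f, seed = 20)
  # power-of-two scaling is exact in floating point, so the fitted trees
  # and variance fractions must agree to machine precision
  h2 <- random_history(sp, 200, function(cfg) 128 * f(cfg), seed = 20)
  r1 <- fanova(encode_history(h1), n_trees = 16, seed = 5)
  r2 <- fanova(encode_history(h2), n_trees = 16, seed = 5)
  expect_equal(r1$importance$fraction, r2$importance$fraction,
               tolerance = 1e-12)
})

test_that("trial order does not change the report", {
  sp <- space_10d()
  h <- random_history(sp, 150, function(cfg) sin(5 * cfg$x1) + cfg$x2,
                      seed = 21)
  perm <- sample(seq_along(h$trials))
  hp <- h
  hp$trials <- h$trials[perm]
  for (i in seq_along(hp$trials)) hp$trials[[i]]$index <- i
  r1 <- fanova(encode_history(h), n_trees = 16, seed = 6)
  r2 <- fanova(encode_history(hp), n_trees = 16, seed = 6)
  expect_equal(r1$importance, r2$importance)
})

test_that("reports export to CSV and plot", {
  sp <- space_10d()
  h <- random_history(sp, 60, function(cfg) cfg$x1, seed = 22)
  rep <- fanova(encode_history(h), n_trees = 8, seed = 7)
  path <- withr::local_tempfile(fileext = ".csv")
  write_importance(rep, path)
  back <- utils::read.csv(path)
  expect_named(back, c("hyperparameter", "group", "fraction"))
  expect_s3_class(autoplot(rep), "ggplot")
  expect_equal(nrow(glance(rep)), 1L)
})
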