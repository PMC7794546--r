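test_that("random search records complete, reproducible histories", {
  sp <- default_cnn_space(n_samples = 64)
  f <- surrogate_objective("quadratic")
  h <- random_search(sp, f, n_trials = 5, seed = 3)
  tb <- tibble::as_tibble(h)
  expect_equal(nrow(tb), 5L)
  expect_true(all(tb$origin == "random"))
  expect_true(all(tb$status == "ok"))
  expect_true(all(diff(tb$running_best) <= 0))

  h2 <- random_search(sp, f, n_trials = 5, seed = 3)
  expect_identical(lapply(h$trials, `[[`, "config"),
                   lapply(h2$trials, `[[`, "config"))

  hc <- random_search(sp, function(cfg) 4.2, n_trials = 4, seed = 1)
  expect_equal(best_trial(hc)$objective$mean_rmse, 4.2)

  # exceptions become failed trials and the search continues
  flaky <- local({
    i <- 0
    function(cfg) { i <<- i + 1; if (i == 2) stop("boom") else i }
  })
  hf <- random_search(sp, flaky, n_trials = 4, seed = 2, penalty = 99)
  tbf <- tibble::as_tibble(hf)
  expect_equal(tbf$status, c("ok", "failed", "ok", "ok"))
  expect_equal(tbf$objective[2], 99)
})

test_that("histories split at the gamma-quantile with index tie-breaks", {
  sp <- space_1d()
  cfgs <- lapply(seq(0.05, 0.95, length.out = 10), function(v) list(x = v))
  h <- history_from_values(sp, cfgs, values = 10:1)
  parts <- split_history(h, gamma = 0.2)
  expect_length(parts$good, 2L)
  expect_length(parts$bad, 8L)
  expect_equal(vapply(parts$good, function(tr) tr$objective$mean_rmse, 0),
               c(1, 2))

  ties <- history_from_values(sp, cfgs, values = rep(5, 10))
  pt <- split_history(ties, gamma = 0.2)
  expect_equal(vapply(pt$good, `[[`, 0L, "index"), 1:2)

  two <- history_from_values(sp, cfgs[1:2], values = c(2, 1))
  expect_length(split_history(two, gamma = 0.25)$good, 1L)
})

test_that("categorical densities smooth counts with the prior weight", {
  sp <- search_space(list(hp_categorical("opt", c("A", "B"))))
  good <- lapply(c("A", "A", "A"), function(v) list(index = 1, config = list(opt = v)))
  bad <- lapply(c("B", "B"), function(v) list(index = 1, config = list(opt = v)))
  dens <- density_estimators(good, bad, sp, tpe_params(prior_weight = 1))
  l <- dens$opt$l
  expect_equal(spectratune:::density_pdf(l, "A"), 4 / 5)
  expect_equal(spectratune:::density_pdf(l, "B"), 1 / 5)
})

test_that("numeric good-densities peak at their single observation", {
  sp <- space_1d()
  good <- list(list(index = 1, config = list(x = 0.5)))
  bad <- list(list(index = 2, config = list(x = 0.9)))
  dens <- density_estimators(good, bad, sp, tpe_params())
  grid <- seq(0, 1, by = 0.01)
  pdf <- spectratune:::density_pdf(dens$x$l, grid)
  expect_equal(grid[which.max(pdf)], 0.5)
})

test_that("good and bad densities coincide on an uninformative history", {
  sp <- space_1d()
  set.seed(6)
  cfgs <- lapply(runif(500), function(v) list(x = v))
  h <- history_from_values(sp, cfgs, values = runif(500))
  parts <- split_history(h, 0.25)
  dens <- density_estimators(parts$good, parts$bad, sp, tpe_params())
  # Kolmogorov-Smirnov distance between the two estimated distributions
  grid <- seq(0.0005, 0.9995, by = 0.001)
  F_l <- cumsum(spectratune:::density_pdf(dens$x$l, grid)) * 0.001
  F_g <- cumsum(spectratune:::density_pdf(dens$x$g, grid)) * 0.001
  expect_lt(max(abs(F_l - F_g)), 0.1)
  expect_lt(max(abs(F_l - grid)), 0.1)  # both close to uniform
})

test_that("a huge prior weight collapses the Parzen model to the uniform prior", {
  sp <- space_1d()
  good <- lapply(rep(0.9, 20), function(v) list(index = 1, config = list(x = v)))
  bad <- lapply(rep(0.1, 20), function(v) list(index = 1, config = list(x = v)))
  dens <- density_estimators(good, bad, sp, tpe_params(prior_weight = 1e6))
  grid <- seq(0.05, 0.95, by = 0.05)
  expect_true(all(abs(spectratune:::density_pdf(dens$x$l, grid) - 1) < 0.01))
  expect_true(all(abs(spectratune:::density_pdf(dens$x$g, grid) - 1) < 0.01))
})

test_that("suggestions on finite spaces equal the brute-force l/g argmax", {
  set.seed(11)
  params <- tpe_params(n_startup = 5, gamma = 0.25, prior_weight = 1)
  for (rep in 1:10) {
    k <- sample(2:5, 1)
    cats <- LETTERS[seq_len(k)]
    sp <- search_space(list(hp_categorical("c", cats)))
    n <- sample(10:30, 1)
    cfgs <- lapply(sample(cats, n, replace = TRUE), function(v) list(c = v))
    h <- history_from_values(sp, cfgs, values = runif(n))

    # independent oracle: smoothed count ratio over all categories
    parts <- split_history(h, params$gamma)
    count <- function(trials, v) {
      sum(vapply(trials, function(tr) identical(tr$config$c, v), TRUE))
    }
    ratio <- vapply(cats, function(v) {
      l <- (count(parts$good, v) + 1) / (length(parts$good) + k)
      g <- (count(parts$bad, v) + 1) / (length(parts$bad) + k)
      l / g
    }, 0)
    sugg <- tpe_suggest(sp, h, params)$c
    expect_equal(ratio[[sugg]], max(ratio), tolerance = 1e-12)
  }
})

test_that("pre-startup suggestions fall back to uniform sampling", {
  sp <- default_cnn_space(n_samples = 100)
  h <- spectratune:::new_history(sp)
  set.seed(14)
  for (i in 1:20) {
    cfg <- tpe_suggest(sp, h, tpe_params(n_startup = 20))
    expect_length(validate_config(sp, cfg), 0L)
  }
})

test_that("TPE concentrates suggestions near a 1-D optimum", {
  sp <- space_1d()
  h <- random_history(sp, 100, function(cfg) (cfg$x - 0.3)^2, seed = 21)
  params <- tpe_params(n_startup = 20)
  set.seed(22)
  sugg <- replicate(50, tpe_suggest(sp, h, params)$x)
  expect_lt(abs(mean(sugg) - 0.3), abs(mean(sugg) - 0.5))
  expect_lt(mean(abs(sugg - 0.3)), 0.2)
})

test_that("every TPE-proposed configuration respects the conditional tree", {
  sp <- default_cnn_space(n_samples = 64)
  f <- surrogate_objective("quadratic")
  h <- tpe_optimize(sp, f, n_trials = 30, seed = 4,
                    params = tpe_params(n_startup = 10))
  tb <- tibble::as_tibble(h)
  expect_equal(nrow(tb), 30L)
  expect_equal(tb$origin, c(rep("startup", 10), rep("tpe", 20)))
  expect_true(all(diff(tb$running_best) <= 0))
  for (tr in h$trials) {
    expect_length(validate_config(sp, tr$config), 0L)
  }
})

test_that("a budget equal to the startup count is pure random sampling", {
  sp <- default_cnn_space(n_samples = 64)
  h <- tpe_optimize(sp, surrogate_objective("quadratic"), n_trials = 8,
                    seed = 5, params = tpe_params(n_startup = 8))
  expect_true(all(tibble::as_tibble(h)$origin == "startup"))
  expect_error(
    tpe_optimize(sp, surrogate_objective("quadratic"), n_trials = 5,
                 seed = 1, params = tpe_params(n_startup = 10)),
    class = "spectratune_invalid_config")
})

test_that("interrupted searches resume to the full budget", {
  sp <- default_cnn_space(n_samples = 64)
  f <- surrogate_objective("quadratic")
  part <- tpe_optimize(sp, f, n_trials = 12, seed = 6,
                       params = tpe_params(n_startup = 8))
  full <- tpe_optimize(sp, f, n_trials = 25, seed = 6,
                       params = tpe_params(n_startup = 8),
                       resume_from = part)
  expect_length(full$trials, 25L)
  expect_identical(full$trials[[3]]$config, part$trials[[3]]$config)
})

test_that("histories round-trip through JSON lines", {
  sp <- default_cnn_space(n_samples = 64)
  h <- tpe_optimize(sp, surrogate_objective("quadratic"), n_trials = 12,
                    seed = 7, params = tpe_params(n_startup = 8))
  path <- withr::local_tempfile(fileext = ".jsonl")
  write_history(h, path)
  back <- read_history(path)
  expect_equal(tibble::as_tibble(back), tibble::as_tibble(h),
               tolerance = 1e-12)
  expect_equal(back$trials[[5]]$config, h$trials[[5]]$config)
  expect_equal(back$best_index, h$best_index)

  conv <- withr::local_tempfile(fileext = ".csv")
  write_convergence(h, conv)
  cc <- utils::read.csv(conv)
  expect_equal(nrow(cc), 12L)
  expect_named(cc, c("index", "objective", "running_best", "origin"))
})

test_that("random and TPE histories share one schema", {
  sp <- default_cnn_space(n_samples = 64)
  f <- surrogate_objective("quadratic")
  ht <- tpe_optimize(sp, f, n_trials = 10, seed = 8,
                     params = tpe_params(n_startup = 8))
  hr <- random_search(sp, f, n_trials = 10, seed = 8)
  expect_identical(names(tibble::as_tibble(ht)), names(tibble::as_tibble(hr)))
  expect_identical(names(glance(ht)), names(glance(hr)))
})
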