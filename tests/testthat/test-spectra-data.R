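test_that("wavelength grids carry consistent point counts", {
  g <- wavelength_grid()
  expect_equal(g$n_points, 4201L)
  expect_equal(length(wavelengths(g)), 4201L)
  expect_equal(wavelengths(g)[2] - wavelengths(g)[1], 0.5)
  expect_equal(coarse_grid()$n_points, 211L)
  expect_error(wavelength_grid(500, 400), class = "spectratune_invalid_grid")
  expect_error(wavelength_grid(step_nm = 0), class = "spectratune_invalid_grid")
})

test_that("generator is bit-identical under a fixed seed", {
  cfg <- synthetic_config(n_samples = 15, seed = 99)
  a <- generate_spectra(cfg, coarse_grid())
  b <- generate_spectra(cfg, coarse_grid())
  expect_identical(a$reflectance, b$reflectance)
  expect_identical(a$target, b$target)
})

test_that("no-signal configuration returns the bare baseline", {
  cfg <- synthetic_config(n_samples = 12, n_peaks = 0, noise_sd = 0,
                          baseline_sd = 0, seed = 4)
  ds <- generate_spectra(cfg, coarse_grid())
  # all spectra identical and untouched by the target
  expect_true(all(apply(ds$reflectance, 2, function(col) diff(range(col)) == 0)))
})

test_that("with one linear-depth band the target is recoverable exactly", {
  cfg <- synthetic_config(n_samples = 60, n_peaks = 1, noise_sd = 0,
                          baseline_sd = 0, depth_link = "linear", seed = 8)
  ds <- generate_spectra(cfg, coarse_grid())
  # the band profile is proportional to any between-sample difference;
  # at the deepest-band wavelength, reflectance is an exact linear
  # function of the target, so the band depth there correlates perfectly
  profile <- ds$reflectance[which.min(ds$target), ] -
    ds$reflectance[which.max(ds$target), ]
  w_star <- which.max(profile)
  expect_equal(stats::cor(ds$target, 1 - ds$reflectance[, w_star]), 1,
               tolerance = 1e-10)
})

test_that("default synthetic target is right-skewed", {
  ds <- generate_spectra(synthetic_config(n_samples = 1000, seed = 2),
                         coarse_grid())
  expect_gt(spectratune:::sample_skewness(ds$target), 0)
})

test_that("invalid generator configurations are rejected", {
  expect_error(synthetic_config(n_samples = 0),
               class = "spectratune_invalid_config")
  expect_error(synthetic_config(n_samples = -5),
               class = "spectratune_invalid_config")
  expect_error(synthetic_config(noise_sd = -1),
               class = "spectratune_invalid_config")
  expect_error(generate_spectra(synthetic_config(n_samples = 10),
                                wavelength_grid(400, 430, 1)),
               class = "spectratune_invalid_config")
})

test_that("strided downsampling keeps every factor-th point", {
  ds <- generate_spectra(synthetic_config(n_samples = 10, seed = 1))
  thin <- downsample_spectra(ds, 20)
  expect_equal(thin$grid$n_points, 211L)
  expect_identical(thin$reflectance[, 1], ds$reflectance[, 1])
  expect_identical(thin$reflectance[, 211], ds$reflectance[, 4201])
  expect_identical(downsample_spectra(ds, 1), ds)

  g100 <- wavelength_grid(400, 499, 1)
  ds100 <- spectra_dataset(matrix(0.5, 3, 100), c(1, 2, 3), g100)
  expect_equal(downsample_spectra(ds100, 7)$grid$n_points, 15L)
  expect_error(downsample_spectra(ds, 0), class = "spectratune_invalid_config")
})

test_that("downsampling composes multiplicatively", {
  ds <- tiny_dataset(n = 10, seed = 3)
  ab <- downsample_spectra(downsample_spectra(ds, 2), 3)
  once <- downsample_spectra(ds, 6)
  expect_identical(ab$reflectance, once$reflectance)
  expect_identical(ab$grid, once$grid)
})

test_that("spectra tables round-trip through CSV", {
  ds <- tiny_dataset(n = 10, seed = 5)
  path <- withr::local_tempfile(fileext = ".csv")
  write_spectra_csv(ds, path)
  back <- read_spectra_csv(path)
  expect_equal(back$reflectance, ds$reflectance, tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_equal(back$target, ds$target, tolerance = 1e-10)
  expect_equal(back$grid$n_points, ds$grid$n_points)
})

test_that("rows with non-finite values are dropped with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("400,410,420,target",
               "0.5,0.6,0.7,12",
               "0.4,NaN,0.6,30",
               "0.3,0.4,0.5,7"), path)
  expect_warning(ds <- read_spectra_csv(path), "1 row")
  expect_equal(nrow(ds$reflectance), 2L)
})

test_that("malformed spectra tables fail loudly", {
  path <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("400,410,420,soc", "0.5,0.6,0.7,12"), path)
  expect_error(read_spectra_csv(path, target_col = "target"),
               class = "spectratune_parse_error")
  empty <- withr::local_tempfile(fileext = ".csv")
  writeLines(character(0), empty)
  expect_error(read_spectra_csv(empty), class = "spectratune_parse_error")
})

test_that("dataset invariants are enforced", {
  g <- wavelength_grid(400, 402, 1)
  expect_error(spectra_dataset(matrix(c(0, 0.5, 0.5), 1), 1, g),
               class = "spectratune_invalid_data")
  expect_error(spectra_dataset(matrix(0.5, 1, 3), -1, g),
               class = "spectratune_invalid_data")
  expect_error(spectra_dataset(matrix(0.5, 2, 3), c(1, 2, 3), g),
               class = "spectratune_invalid_data")
})

test_that("a spectra dataset tidies to one row per sample", {
  ds <- tiny_dataset(n = 10, seed = 2)
  tb <- tibble::as_tibble(ds)
  expect_equal(nrow(tb), 10L)
  expect_equal(ncol(tb), 2L + 211L)
  expect_named(tb[1:2], c("sample_id", "target"))
})
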