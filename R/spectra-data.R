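#' Wavelength grid
#'
#' A regularly spaced wavelength axis. The default matches a full-range
#' vis-NIR laboratory instrument: 400 to 2500 nm at 0.5 nm resolution,
#' giving 4201 points.
#'
#' @param start_nm First wavelength in nanometres.
#' @param end_nm Last wavelength in nanometres.
#' @param step_nm Spacing between consecutive wavelengths (> 0).
#' @return An object of class `wavelength_grid` with fields `start_nm`,
#'   `end_nm`, `step_nm` and `n_points`.
#' @examples
#' wavelength_grid()            # 4201-point vis-NIR grid
#' wavelength_grid(400, 700, 1) # visible range only
#' @export
wavelength_grid <- function(start_nm = 400, end_nm = 2500, step_nm = 0.5) {
  if (!is_number(start_nm) || !is_number(end_nm) || !is_number(step_nm) ||
      step_nm <= 0 || end_nm <= start_nm) {
    stop_spectratune("`wavelength_grid()` needs end_nm > start_nm and step_nm > 0.",
                     "spectratune_invalid_grid")
  }
  n_points <- as.integer(round((end_nm - start_nm) / step_nm)) + 1L
  structure(
    list(start_nm = start_nm, end_nm = end_nm, step_nm = step_nm,
         n_points = n_points),
    class = "wavelength_grid"
  )
}

#' @export
print.wavelength_grid <- function(x, ...) {
  cat(sprintf("<wavelength_grid> %g-%g nm, step %g nm (%d points)\n",
              x$start_nm, x$end_nm, x$step_nm, x$n_points))
  invisible(x)
}

#' Wavelengths of a grid
#'
#' @param grid A [wavelength_grid()].
#' @return Numeric vector of wavelengths in nm, length `grid$n_points`.
#' @export
wavelengths <- function(grid) {
  grid$start_nm + grid$step_nm * (seq_len(grid$n_points) - 1)
}

#' Spectra dataset
#'
#' Bundle a reflectance matrix (samples x wavelengths, values strictly in
#' (0, 1] so absorbance is finite), a non-negative numeric target (the soil
#' organic carbon role, g/kg) and the wavelength grid.
#'
#' @param reflectance Numeric matrix, `n_samples x grid$n_points`, all values
#'   in (0, 1].
#' @param target Numeric vector of length `n_samples`, non-negative.
#' @param grid A [wavelength_grid()] whose `n_points` matches `ncol(reflectance)`.
#' @param sample_ids Optional character ids; defaults to `"s1"`, `"s2"`, ...
#' @return An object of class `spectra_dataset`.
#' @seealso [generate_spectra()], [downsample_spectra()], [read_spectra_csv()]
#' @export
spectra_dataset <- function(reflectance, target, grid,
                            sample_ids = NULL) {
  reflectance <- as.matrix(reflectance)
  storage.mode(reflectance) <- "double"
  if (!inherits(grid, "wavelength_grid")) {
    stop_spectratune("`grid` must be a wavelength_grid.", "spectratune_invalid_data")
  }
  if (ncol(reflectance) != grid$n_points) {
    stop_spectratune(
      sprintf("reflectance has %d columns but the grid has %d points.",
              ncol(reflectance), grid$n_points),
      "spectratune_invalid_data")
  }
  if (anyNA(reflectance) || any(!is.finite(reflectance)) ||
      any(reflectance <= 0) || any(reflectance > 1)) {
    stop_spectratune("reflectance values must be finite and in (0, 1].",
                     "spectratune_invalid_data")
  }
  target <- as.numeric(target)
  if (length(target) != nrow(reflectance)) {
    stop_spectratune("`target` length must equal the number of spectra.",
                     "spectratune_invalid_data")
  }
  if (anyNA(target) || any(!is.finite(target)) || any(target < 0)) {
    stop_spectratune("`target` must be finite and non-negative.",
                     "spectratune_invalid_data")
  }
  n <- nrow(reflectance)
  sample_ids <- sample_ids %||% paste0("s", seq_len(n))
  sample_ids <- as.character(sample_ids)
  if (length(sample_ids) != n || anyDuplicated(sample_ids)) {
    stop_spectratune("`sample_ids` must be unique and match the sample count.",
                     "spectratune_invalid_data")
  }
  dimnames(reflectance) <- list(sample_ids, format_wavelength(wavelengths(grid)))
  structure(
    list(grid = grid, reflectance = reflectance, target = target,
         sample_ids = sample_ids),
    class = "spectra_dataset"
  )
}

format_wavelength <- function(w) {
  # drop trailing zeros so "500" and "500.5" both round-trip through CSV
  sub("\\.?0+$", "", format(w, trim = TRUE, scientific = FALSE, nsmall = 4))
}

#' @export
print.spectra_dataset <- function(x, ...) {
  cat(sprintf("<spectra_dataset> %d spectra x %d wavelengths (%g-%g nm)\n",
              nrow(x$reflectance), x$grid$n_points, x$grid$start_nm,
              x$grid$end_nm))
  cat(sprintf("  target: median %.3g, range [%.3g, %.3g]\n",
              stats::median(x$target), min(x$target), max(x$target)))
  invisible(x)
}

#' @export
dim.spectra_dataset <- function(x) dim(x$reflectance)

#' Coerce a spectra dataset to a tibble
#'
#' One row per sample: `sample_id`, `target`, then one column per wavelength
#' (named by the wavelength in nm).
#'
#' @param x A `spectra_dataset`.
#' @param ... Unused.
#' @return A tibble with `n_samples` rows.
#' @method as_tibble spectra_dataset
#' @export
as_tibble.spectra_dataset <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(sample_id = x$sample_ids, target = x$target),
    tibble::as_tibble(x$reflectance)
  )
}

#' Configuration for the synthetic vis-NIR spectra generator
#'
#' Describes a simulated soil spectral library: broad overlapping Gaussian
#' absorption features superimposed on a smooth sloping baseline, with a
#' right-skewed positive target (the soil-organic-carbon role) that controls
#' the depth of the absorption bands.
#'
#' The target is lognormal with median `exp(target_meanlog)` (default
#' 20 g/kg) and log-sd `target_sdlog` (default 0.8), a realistic shape for a
#' continental-scale soil library containing both mineral and organic soils.
#'
#' @param n_samples Number of spectra (>= 10).
#' @param n_peaks Number of Gaussian absorption bands (>= 0).
#' @param noise_sd Standard deviation of i.i.d. reflectance noise (>= 0).
#' @param target_meanlog,target_sdlog Lognormal parameters of the target.
#' @param baseline_sd Standard deviation of the per-sample baseline offset;
#'   set 0 for identical baselines.
#' @param depth_link `"saturating"` (band depth scales with
#'   `t / (t + 50)`, so very carbon-rich samples do not drive reflectance
#'   negative) or `"linear"` (depth directly proportional to the target;
#'   useful for exactness checks).
#' @param seed Integer seed; the generator is fully reproducible.
#' @return A `synthetic_config` list.
#' @export
synthetic_config <- function(n_samples = 500, n_peaks = 8, noise_sd = 0.002,
                             target_meanlog = log(20), target_sdlog = 0.8,
                             baseline_sd = 0.02,
                             depth_link = c("saturating", "linear"),
                             seed = 1L) {
  if (!is_count(n_samples, min = 1L) || n_samples < 10) {
    stop_spectratune("`n_samples` must be an integer >= 10.",
                     "spectratune_invalid_config")
  }
  if (!is_count(n_peaks, min = 0L)) {
    stop_spectratune("`n_peaks` must be a non-negative integer.",
                     "spectratune_invalid_config")
  }
  if (!is_number(noise_sd) || noise_sd < 0) {
    stop_spectratune("`noise_sd` must be >= 0.", "spectratune_invalid_config")
  }
  if (!is_number(baseline_sd) || baseline_sd < 0) {
    stop_spectratune("`baseline_sd` must be >= 0.", "spectratune_invalid_config")
  }
  depth_link <- match.arg(depth_link)
  structure(
    list(n_samples = as.integer(n_samples), n_peaks = as.integer(n_peaks),
         noise_sd = noise_sd, target_meanlog = target_meanlog,
         target_sdlog = target_sdlog, baseline_sd = baseline_sd,
         depth_link = depth_link, seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' Generate synthetic vis-NIR-like spectra with a known target
#'
#' Each spectrum is a smooth, gently rising baseline minus a sum of broad
#' Gaussian absorption bands plus i.i.d. noise, clipped to (1e-6, 1]. Band
#' depths are deterministic functions of the sample's target draw, so the
#' target is recoverable from the spectra and every downstream modelling
#' stage can be validated without external data.
#'
#' @param config A [synthetic_config()].
#' @param grid A [wavelength_grid()] with at least 50 points.
#' @return A [spectra_dataset()].
#' @examples
#' ds <- generate_spectra(synthetic_config(n_samples = 50, seed = 7))
#' dim(ds)
#' @export
generate_spectra <- function(config = synthetic_config(),
                             grid = wavelength_grid()) {
  if (!inherits(config, "synthetic_config")) {
    stop_spectratune("`config` must come from synthetic_config().",
                     "spectratune_invalid_config")
  }
  if (grid$n_points < 50) {
    stop_spectratune("`grid` must have at least 50 points.",
                     "spectratune_invalid_config")
  }
  w <- wavelengths(grid)
  n <- config$n_samples
  p <- grid$n_points

  old_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_state)) assign(".Random.seed", old_state, envir = globalenv())
  }, add = TRUE)
  set.seed(config$seed)

  target <- rlnorm(n, meanlog = config$target_meanlog,
                   sdlog = config$target_sdlog)

  # smooth baseline rising towards the NIR, as for most mineral soils
  wn <- (w - grid$start_nm) / (grid$end_nm - grid$start_nm)
  baseline <- 0.40 + 0.30 * wn - 0.05 * sin(2 * pi * wn)
  offsets <- if (config$baseline_sd > 0) rnorm(n, 0, config$baseline_sd) else numeric(n)

  R <- matrix(rep(baseline, each = n), nrow = n) + offsets

  if (config$n_peaks > 0) {
    centers <- runif(config$n_peaks, grid$start_nm, grid$end_nm)
    widths <- runif(config$n_peaks, 0.02, 0.10) * (grid$end_nm - grid$start_nm)
    base_depth <- runif(config$n_peaks, 0.2, 1.0)
    base_depth <- base_depth / sum(base_depth)      # total depth budget ~0.25
    depth_scale <- switch(config$depth_link,
      saturating = 0.25 * target / (target + 50),
      linear = 0.25 * target / max(target)
    )
    for (j in seq_len(config$n_peaks)) {
      band <- exp(-(w - centers[j])^2 / (2 * widths[j]^2))
      R <- R - (depth_scale * base_depth[j]) %o% band
    }
  }
  if (config$noise_sd > 0) {
    R <- R + matrix(rnorm(n * p, 0, config$noise_sd), nrow = n)
  }
  R <- pmin(pmax(R, 1e-6), 1)
  spectra_dataset(R, target, grid)
}

#' Downsample spectra by strided point selection
#'
#' Keeps every `factor`-th wavelength starting from the first, the usual way
#' high-resolution spectra are thinned to curb multicollinearity and
#' training cost (a 4201-point grid thinned 1:20 keeps 211 points).
#'
#' @param ds A [spectra_dataset()].
#' @param factor Positive integer stride; `1` is the identity.
#' @return A [spectra_dataset()] on the thinned grid.
#' @examples
#' ds <- generate_spectra(synthetic_config(n_samples = 20, seed = 1))
#' downsample_spectra(ds, 20)$grid$n_points  # 211
#' @export
downsample_spectra <- function(ds, factor) {
  if (!is_count(factor)) {
    stop_spectratune("`factor` must be a positive integer.",
                     "spectratune_invalid_config")
  }
  factor <- as.integer(factor)
  if (factor == 1L) return(ds)
  keep <- seq(1L, ds$grid$n_points, by = factor)
  w <- wavelengths(ds$grid)[keep]
  new_grid <- wavelength_grid(start_nm = w[1], end_nm = w[length(w)],
                              step_nm = ds$grid$step_nm * factor)
  spectra_dataset(ds$reflectance[, keep, drop = FALSE], ds$target, new_grid,
                  sample_ids = ds$sample_ids)
}

#' Read a spectra table from delimited text
#'
#' Expects one row per sample with a header of wavelengths (in nm) plus one
#' named target column; an optional `sample_id` column is honoured. Rows
#' containing non-finite values are dropped with a warning reporting the
#' count.
#'
#' @param path Path to a CSV/TSV file.
#' @param target_col Name of the target column (default `"target"`).
#' @param sep Field separator; `","` for CSV (default), `"\t"` for TSV.
#' @return A [spectra_dataset()].
#' @export
read_spectra_csv <- function(path, target_col = "target", sep = ",") {
  df <- tryCatch(
    utils::read.table(path, header = TRUE, sep = sep, check.names = FALSE,
                      stringsAsFactors = FALSE),
    error = function(e) {
      stop_spectratune(sprintf("Could not parse '%s': %s", path,
                               conditionMessage(e)),
                       "spectratune_parse_error")
    }
  )
  if (nrow(df) == 0L || ncol(df) == 0L) {
    stop_spectratune(sprintf("'%s' contains no data rows.", path),
                     "spectratune_parse_error")
  }
  if (!target_col %in% names(df)) {
    stop_spectratune(sprintf("Target column '%s' not found in '%s'.",
                             target_col, path),
                     "spectratune_parse_error")
  }
  ids <- NULL
  if ("sample_id" %in% names(df)) {
    ids <- as.character(df[["sample_id"]])
    df[["sample_id"]] <- NULL
  }
  target <- df[[target_col]]
  df[[target_col]] <- NULL
  wl <- suppressWarnings(as.numeric(names(df)))
  if (anyNA(wl)) {
    stop_spectratune("All non-target columns must be named by numeric wavelengths (nm).",
                     "spectratune_parse_error")
  }
  R <- as.matrix(df)
  if (!is.numeric(R) || !is.numeric(target)) {
    stop_spectratune("Spectra and target cells must all be numeric.",
                     "spectratune_parse_error")
  }
  ok <- is.finite(target) & apply(R, 1L, function(r) all(is.finite(r)))
  if (!all(ok)) {
    rlang::warn(sprintf("Dropped %d row(s) with non-finite values.", sum(!ok)))
    R <- R[ok, , drop = FALSE]
    target <- target[ok]
    ids <- ids[ok]
  }
  if (nrow(R) == 0L) {
    stop_spectratune("No complete rows left after dropping non-finite values.",
                     "spectratune_parse_error")
  }
  step <- if (length(wl) > 1) wl[2] - wl[1] else 1
  grid <- wavelength_grid(start_nm = wl[1], end_nm = wl[length(wl)],
                          step_nm = step)
  spectra_dataset(R, target, grid, sample_ids = ids)
}

#' Write a spectra dataset to delimited text
#'
#' Inverse of [read_spectra_csv()]: `sample_id`, one column per wavelength,
#' then the target column.
#'
#' @param ds A [spectra_dataset()].
#' @param path Output path.
#' @param target_col Name for the target column.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_spectra_csv <- function(ds, path, target_col = "target", sep = ",") {
  df <- data.frame(sample_id = ds$sample_ids, ds$reflectance,
                   check.names = FALSE)
  df[[target_col]] <- ds$target
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Plot a handful of spectra
#'
#' @param ds A [spectra_dataset()].
#' @param n_show Number of spectra to draw (sampled deterministically from
#'   the dataset order).
#' @return A ggplot object.
#' @export
plot_spectra <- function(ds, n_show = 20) {
  idx <- unique(round(seq(1, nrow(ds$reflectance), length.out = n_show)))
  df <- as_tibble.spectra_dataset(ds)[idx, ] |>
    tidyr::pivot_longer(-c("sample_id", "target"),
                        names_to = "wavelength", values_to = "reflectance") |>
    dplyr::mutate(wavelength = as.numeric(.data$wavelength))
  ggplot2::ggplot(df, ggplot2::aes(.data$wavelength, .data$reflectance,
                                   group = .data$sample_id,
                                   colour = .data$target)) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::labs(x = "Wavelength (nm)", y = "Reflectance",
                  colour = "Target (g/kg)") +
    ggplot2::theme_minimal()
}
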