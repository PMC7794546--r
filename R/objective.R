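#' k-fold split
#'
#' Random permutation of `1:n` partitioned into `k` folds whose sizes
#' differ by at most one (the larger folds come first). Deterministic given
#' `seed`.
#'
#' @param n Number of samples (>= k).
#' @param k Number of folds (>= 2).
#' @param seed Integer seed.
#' @return A `fold_split`: `k`, `assignments` (fold index per sample),
#'   `seed`.
#' @examples
#' table(kfold_split(17607, 10, seed = 1)$assignments)
#' @export
kfold_split <- function(n, k = 10L, seed = 1L) {
  if (!is_count(n) || !is_count(k, min = 2L) || n < k) {
    stop_spectratune("Need n >= k >= 2.", "spectratune_invalid_config")
  }
  old_state <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_state)) assign(".Random.seed", old_state, envir = globalenv())
  }, add = TRUE)
  set.seed(seed)
  sizes <- rep(n %/% k, k)
  extra <- n %% k
  if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
  assignments <- integer(n)
  assignments[sample.int(n)] <- rep.int(seq_len(k), times = sizes)
  structure(list(k = as.integer(k), assignments = assignments,
                 seed = as.integer(seed)),
            class = "fold_split")
}

#' Root mean squared error
#'
#' @param y Observed values.
#' @param yhat Predicted values, same length.
#' @return `sqrt(mean((y - yhat)^2))`.
#' @export
rmse <- function(y, yhat) {
  if (length(y) != length(yhat) || length(y) < 1L) {
    stop_spectratune("`y` and `yhat` must have equal positive length.",
                     "spectratune_invalid_config")
  }
  sqrt(mean((y - yhat)^2))
}

new_objective_value <- function(mean_rmse, fold_rmses, status) {
  structure(list(mean_rmse = mean_rmse, fold_rmses = fold_rmses,
                 status = status),
            class = "objective_value")
}

#' @export
print.objective_value <- function(x, ...) {
  cat(sprintf("<objective_value> mean RMSE %.4g (%s; %d folds)\n",
              x$mean_rmse, x$status, length(x$fold_rmses)))
  invisible(x)
}

# value assigned to infeasible/failed trials: strictly worse than the
# trivial mean predictor, but finite so the optimiser gets a signal
penalty_objective <- function(target) 2 * stats::sd(target)

#' Cross-validated training objective
#'
#' The quantity the hyperparameter search minimises: for each of `k` folds,
#' assemble the configuration's preprocessing channels (standardisation
#' statistics fitted on the training side only), build the architecture,
#' train with the configuration's optimiser, batch size and epoch budget
#' under early stopping, predict the held-out fold and score RMSE; the
#' objective is the mean of the k fold RMSEs. Infeasible architectures and
#' training failures do not abort the search: they return a finite penalty
#' objective (twice the target's standard deviation) with status
#' `"infeasible"` or `"failed"`.
#'
#' @param config A configuration passing [validate_config()].
#' @param ds A [spectra_dataset()].
#' @param k Number of folds (default 10).
#' @param settings A [training_settings()].
#' @param seed Integer seed controlling the fold split and training.
#' @return An `objective_value`: `mean_rmse`, `fold_rmses`, `status`.
#' @export
evaluate_config <- function(config, ds, k = 10L,
                            settings = training_settings(), seed = 1L) {
  n <- nrow(ds$reflectance)
  split <- kfold_split(n, k, seed = seed)
  states <- config_channel_states(config)
  penalty <- penalty_objective(ds$target)
  max_epochs <- min(config$epochs,
                    settings$max_epochs %||% config$epochs)

  fold_rmses <- numeric(k)
  for (i in seq_len(k)) {
    valid_idx <- which(split$assignments == i)
    train_idx <- setdiff(seq_len(n), valid_idx)

    res <- tryCatch({
      stack_all <- assemble_channels(ds, states)
      scaler <- channel_scaler(
        structure(list(data = stack_all$data[train_idx, , , drop = FALSE],
                       channel_names = stack_all$channel_names),
                  class = "channel_stack"))
      scaled <- scale_channels(stack_all, scaler)

      arch <- build_architecture(config, input_width = ds$grid$n_points,
                                 input_channels = sum(states))

      # carve the early-stopping monitor out of the training side only
      n_tr <- length(train_idx)
      n_mon <- max(1L, floor(settings$monitor_fraction * n_tr))
      set.seed(seed + 1000L * i)
      mon_pos <- sample.int(n_tr, n_mon)
      mon_idx <- train_idx[mon_pos]
      fit_idx <- train_idx[-mon_pos]

      model <- train_model(
        arch,
        x = scaled$data[fit_idx, , , drop = FALSE],
        y = ds$target[fit_idx],
        monitor_x = scaled$data[mon_idx, , , drop = FALSE],
        monitor_y = ds$target[mon_idx],
        optimiser = config$optimiser,
        batch_size = min(config$batch_size, length(fit_idx)),
        max_epochs = max_epochs,
        settings = settings,
        seed = seed + i
      )
      if (model$status != "ok") {
        list(rmse = penalty, status = "failed")
      } else {
        pred <- predict(model, scaled$data[valid_idx, , , drop = FALSE])
        list(rmse = rmse(ds$target[valid_idx], pred), status = "ok")
      }
    },
    spectratune_infeasible = function(e) list(rmse = penalty, status = "infeasible"),
    error = function(e) list(rmse = penalty, status = "failed"))

    if (res$status != "ok") {
      return(new_objective_value(penalty, rep(penalty, k), res$status))
    }
    fold_rmses[i] <- res$rmse
  }
  new_objective_value(mean(fold_rmses), fold_rmses, "ok")
}
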