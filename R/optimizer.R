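# ------------------------------------------------------------------
# Search histories, random search and the TPE Bayesian optimiser.
# ------------------------------------------------------------------

new_history <- function(space) {
  structure(list(trials = list(), space = space, best_index = NA_integer_),
            class = "tune_history")
}

add_trial <- function(history, config, objective, elapsed, origin) {
  idx <- length(history$trials) + 1L
  history$trials[[idx]] <- list(index = idx, config = config,
                                objective = objective, elapsed = elapsed,
                                origin = origin)
  if (is.na(history$best_index) ||
      objective$mean_rmse <
        history$trials[[history$best_index]]$objective$mean_rmse) {
    history$best_index <- idx
  }
  history
}

#' Best trial of a history
#'
#' @param history A `tune_history`.
#' @return The trial (list with `index`, `config`, `objective`, `origin`)
#'   with the smallest mean objective.
#' @export
best_trial <- function(history) {
  if (is.na(history$best_index)) {
    stop_spectratune("History has no completed trials.",
                     "spectratune_invalid_history")
  }
  history$trials[[history$best_index]]
}

#' @export
print.tune_history <- function(x, ...) {
  n <- length(x$trials)
  cat(sprintf("<tune_history> %d trials", n))
  if (n > 0) {
    cat(sprintf(", best objective %.4g (trial %d)",
                best_trial(x)$objective$mean_rmse, x$best_index))
  }
  cat("\n")
  invisible(x)
}

#' Tidy a search history
#'
#' One row per trial: index, origin, status, mean objective, running best
#' and elapsed seconds.
#'
#' @param x A `tune_history`.
#' @param ... Unused.
#' @return A tibble with `length(x$trials)` rows.
#' @method as_tibble tune_history
#' @export
as_tibble.tune_history <- function(x, ...) {
  tb <- purrr::map_dfr(x$trials, function(tr) {
    tibble::tibble(index = tr$index, origin = tr$origin,
                   status = tr$objective$status,
                   objective = tr$objective$mean_rmse,
                   elapsed = tr$elapsed)
  })
  if (nrow(tb) > 0) tb$running_best <- cummin(tb$objective)
  tb
}

#' @rdname as_tibble.tune_history
#' @method tidy tune_history
#' @export
tidy.tune_history <- function(x, ...) as_tibble.tune_history(x, ...)

#' Summarise a search history in one row
#'
#' @param x A `tune_history`.
#' @param ... Unused.
#' @return A one-row tibble: number of trials, completed/failed counts,
#'   best objective and its trial index.
#' @method glance tune_history
#' @export
glance.tune_history <- function(x, ...) {
  tb <- as_tibble.tune_history(x)
  tibble::tibble(
    n_trials = nrow(tb),
    n_ok = sum(tb$status == "ok"),
    n_penalised = sum(tb$status != "ok"),
    best_objective = if (nrow(tb)) min(tb$objective) else NA_real_,
    best_index = x$best_index
  )
}

#' Convergence plot of a search history
#'
#' Per-trial objective values and the running best, the standard view for
#' comparing optimisers at equal trial budgets.
#'
#' @param object A `tune_history`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot tune_history
#' @export
autoplot.tune_history <- function(object, ...) {
  tb <- as_tibble.tune_history(object)
  ggplot2::ggplot(tb, ggplot2::aes(.data$index, .data$objective)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$origin), alpha = 0.6) +
    ggplot2::geom_step(ggplot2::aes(y = .data$running_best)) +
    ggplot2::labs(x = "Trial", y = "Objective (mean CV RMSE)",
                  colour = "Origin") +
    ggplot2::theme_minimal()
}

# normalise the user's objective function: may return a bare number or an
# objective_value; exceptions become failed trials with the penalty value
run_objective <- function(objective_fn, config, penalty) {
  t0 <- proc.time()[["elapsed"]]
  obj <- tryCatch(objective_fn(config), error = function(e) e)
  elapsed <- proc.time()[["elapsed"]] - t0
  if (inherits(obj, "error")) {
    obj <- new_objective_value(penalty, penalty, "failed")
  } else if (!inherits(obj, "objective_value")) {
    obj <- new_objective_value(as.numeric(obj), as.numeric(obj), "ok")
  }
  list(objective = obj, elapsed = elapsed)
}

#' Random search
#'
#' Evaluates `n_trials` independent uniform draws from the space — the
#' baseline against which the Bayesian optimiser is compared.
#'
#' @param space A [search_space()].
#' @param objective_fn Function `config -> number` or `config ->
#'   objective_value`. Exceptions are recorded as failed trials and the
#'   search continues.
#' @param n_trials Number of trials (>= 1).
#' @param seed Integer seed.
#' @param penalty Objective value recorded for failed trials.
#' @return A `tune_history`.
#' @export
random_search <- function(space, objective_fn, n_trials, seed = 1L,
                          penalty = Inf) {
  if (!is_count(n_trials)) {
    stop_spectratune("`n_trials` must be a positive integer.",
                     "spectratune_invalid_config")
  }
  set.seed(seed)
  history <- new_history(space)
  for (t in seq_len(n_trials)) {
    config <- sample_config(space)
    res <- run_objective(objective_fn, config, penalty)
    history <- add_trial(history, config, res$objective, res$elapsed, "random")
  }
  history
}

#' TPE settings
#'
#' @param n_startup Uniformly sampled trials before the Parzen model is
#'   used (>= 1).
#' @param gamma Quantile splitting the history into good and bad trials
#'   (0 < gamma < 1).
#' @param n_candidates Candidates drawn from the good-density per
#'   suggestion.
#' @param prior_weight Weight of the uniform prior blended into every
#'   density.
#' @param bandwidth_floor Minimum kernel bandwidth as a fraction of the
#'   domain width.
#' @param enumeration_limit On fully categorical spaces with at most this
#'   many configurations, candidates are the complete enumeration, making
#'   the suggestion the exact argmax of the smoothed density ratio.
#' @return A `tpe_params` list.
#' @export
tpe_params <- function(n_startup = 20L, gamma = 0.25, n_candidates = 24L,
                       prior_weight = 1.0, bandwidth_floor = 0.01,
                       enumeration_limit = 512L) {
  if (!is_count(n_startup) || !is_count(n_candidates)) {
    stop_spectratune("`n_startup` and `n_candidates` must be positive integers.",
                     "spectratune_invalid_config")
  }
  if (!is_number(gamma) || gamma <= 0 || gamma >= 1) {
    stop_spectratune("`gamma` must be in (0, 1).", "spectratune_invalid_config")
  }
  structure(list(n_startup = as.integer(n_startup), gamma = gamma,
                 n_candidates = as.integer(n_candidates),
                 prior_weight = prior_weight,
                 bandwidth_floor = bandwidth_floor,
                 enumeration_limit = as.integer(enumeration_limit)),
            class = "tpe_params")
}

#' Split a history into good and bad trials
#'
#' The best `ceiling(gamma * n)` completed trials (at least one) form the
#' good set; the rest are bad. Ties are broken by trial index, so earlier
#' trials win.
#'
#' @param history A `tune_history` with >= 2 trials.
#' @param gamma Quantile in (0, 1).
#' @return List with `good` and `bad` lists of trials.
#' @export
split_history <- function(history, gamma = 0.25) {
  trials <- history$trials
  if (length(trials) < 2L) {
    stop_spectratune("Need at least 2 completed trials to split.",
                     "spectratune_invalid_history")
  }
  obj <- vapply(trials, function(tr) tr$objective$mean_rmse, 0)
  ord <- order(obj, vapply(trials, `[[`, 0L, "index"))
  n_good <- max(1L, min(length(trials) - 1L, ceiling(gamma * length(trials))))
  list(good = trials[ord[seq_len(n_good)]],
       bad = trials[ord[-seq_len(n_good)]])
}

# ---- Parzen densities over one hyperparameter --------------------

# numeric: Gaussian-kernel mixture at the observed values, truncated to the
# domain, blended with a uniform prior; categorical/flag: Laplace-smoothed
# category frequencies
build_density <- function(def, values, params) {
  if (def$kind %in% c("categorical", "flag")) {
    cats <- def$domain
    counts <- table(factor(unlist(values), levels = cats))
    probs <- (as.numeric(counts) + params$prior_weight) /
      (sum(counts) + length(cats) * params$prior_weight)
    return(list(kind = "categorical", cats = cats, probs = probs))
  }
  lo <- def$domain[["low"]]; hi <- def$domain[["high"]]
  obs <- as.numeric(unlist(values))
  width <- max(hi - lo, .Machine$double.eps)
  # adaptive per-observation bandwidths: distance to the neighbouring
  # observation (domain edges included), so the mixture sharpens where
  # observations cluster; floored to avoid degenerate spikes
  bw <- if (length(obs)) {
    ord <- order(obs)
    srt <- c(lo, obs[ord], hi)
    gaps <- pmax(srt[seq_along(obs) + 1] - srt[seq_along(obs)],
                 srt[seq_along(obs) + 2] - srt[seq_along(obs) + 1])
    out <- numeric(length(obs))
    out[ord] <- gaps
    pmin(pmax(out, params$bandwidth_floor * width), width)
  } else numeric(0)
  # component masses inside the domain, for truncation
  mass <- if (length(obs)) pnorm(hi, obs, bw) - pnorm(lo, obs, bw) else numeric(0)
  mass[mass < 1e-12] <- 1e-12
  list(kind = "numeric", lo = lo, hi = hi, obs = obs, bw = bw, mass = mass,
       integer = def$kind == "integer", prior_weight = params$prior_weight)
}

density_pdf <- function(dens, x) {
  if (dens$kind == "categorical") {
    return(dens$probs[match(x, dens$cats)])
  }
  n <- length(dens$obs)
  pw <- dens$prior_weight
  prior <- if (dens$integer) 1 / (dens$hi - dens$lo + 1) else 1 / (dens$hi - dens$lo)
  kern <- if (n > 0) {
    sapply(x, function(xi) sum(dnorm(xi, dens$obs, dens$bw) / dens$mass))
  } else rep(0, length(x))
  (kern + pw * prior) / (n + pw)
}

density_sample <- function(dens, n = 1L) {
  if (dens$kind == "categorical") {
    return(sample(dens$cats, n, replace = TRUE, prob = dens$probs))
  }
  nobs <- length(dens$obs)
  pw <- dens$prior_weight
  comp <- sample.int(nobs + 1L, n, replace = TRUE,
                     prob = c(rep(1, nobs), pw))
  out <- numeric(n)
  for (i in seq_len(n)) {
    if (comp[i] > nobs) {
      out[i] <- runif(1, dens$lo, dens$hi)
    } else {
      m <- dens$obs[comp[i]]
      h <- dens$bw[comp[i]]
      # inverse-CDF draw from the truncated Gaussian component
      u <- runif(1, pnorm(dens$lo, m, h), pnorm(dens$hi, m, h))
      out[i] <- qnorm(u, m, h)
    }
  }
  out <- pmin(pmax(out, dens$lo), dens$hi)
  if (dens$integer) out <- round(out)
  out
}

#' Per-hyperparameter good/bad Parzen estimators
#'
#' Builds, for every hyperparameter, the density of its values among good
#' trials (`l`) and among bad trials (`g`). Conditional hyperparameters are
#' estimated only from trials where they were active; a hyperparameter
#' never observed on one side falls back to the uniform prior there.
#'
#' @param good,bad Lists of trials from [split_history()].
#' @param space The [search_space()].
#' @param params A [tpe_params()].
#' @return Named list: per hyperparameter, `list(l = , g = )` density
#'   objects.
#' @export
density_estimators <- function(good, bad, space, params = tpe_params()) {
  out <- list()
  for (def in space$defs) {
    vals_of <- function(trials) {
      v <- lapply(trials, function(tr) tr$config[[def$name]])
      v[!vapply(v, is.null, TRUE)]
    }
    out[[def$name]] <- list(
      l = build_density(def, vals_of(good), params),
      g = build_density(def, vals_of(bad), params)
    )
  }
  out
}

# draw one candidate configuration from the good densities, respecting the
# conditional tree (parents first, children only when active)
sample_from_densities <- function(space, dens) {
  config <- list()
  for (def in space$defs) {
    if (def_is_active(def, config)) {
      v <- density_sample(dens[[def$name]]$l, 1L)
      if (def$kind %in% c("integer", "continuous")) v <- as.numeric(v)
      config[[def$name]] <- if (def$kind == "integer") as.integer(v) else v
    }
  }
  config
}

# log l(config) - log g(config), summed over the assigned hyperparameters
score_candidate <- function(config, dens) {
  s <- 0
  for (nm in names(config)) {
    d <- dens[[nm]]
    if (is.null(d)) next
    s <- s + log(density_pdf(d$l, config[[nm]])) -
      log(density_pdf(d$g, config[[nm]]))
  }
  s
}

# all configurations of a fully categorical/flag space (small spaces only)
enumerate_space <- function(space, limit) {
  kinds <- vapply(space$defs, `[[`, "", "kind")
  if (!all(kinds %in% c("categorical", "flag"))) return(NULL)
  sizes <- vapply(space$defs, function(d) length(d$domain), 0L)
  if (prod(sizes) > limit) return(NULL)
  configs <- list(list())
  for (def in space$defs) {
    nxt <- list()
    for (cfg in configs) {
      if (def_is_active(def, cfg)) {
        for (v in def$domain) {
          cfg2 <- cfg
          cfg2[[def$name]] <- v
          nxt[[length(nxt) + 1L]] <- cfg2
        }
      } else {
        nxt[[length(nxt) + 1L]] <- cfg
      }
    }
    configs <- nxt
  }
  configs[vapply(configs,
                 function(cfg) length(validate_config(space, cfg)) == 0L,
                 TRUE)]
}

#' Suggest the next configuration by TPE
#'
#' With fewer completed trials than `params$n_startup` the suggestion is a
#' uniform draw. Otherwise the history is split at the gamma-quantile,
#' per-hyperparameter Parzen estimators `l` (good) and `g` (bad) are built,
#' candidates are drawn from `l` (the complete enumeration on small finite
#' spaces), and the candidate maximising the summed log-density ratio
#' `sum(log l - log g)` over its active hyperparameters — the expected-
#' improvement ranking — is returned.
#'
#' @param space A [search_space()].
#' @param history A `tune_history`.
#' @param params A [tpe_params()].
#' @return A configuration passing [validate_config()].
#' @export
tpe_suggest <- function(space, history, params = tpe_params()) {
  if (length(history$trials) < params$n_startup) {
    return(sample_config(space))
  }
  obj <- vapply(history$trials, function(tr) tr$objective$mean_rmse, 0)
  if (diff(range(obj)) < 1e-12) {
    # a flat history (e.g. nothing but penalty values yet) carries no
    # ranking signal; keep exploring uniformly instead of modelling noise
    return(sample_config(space))
  }
  parts <- split_history(history, params$gamma)
  dens <- density_estimators(parts$good, parts$bad, space, params)
  candidates <- enumerate_space(space, params$enumeration_limit)
  if (is.null(candidates)) {
    candidates <- vector("list", params$n_candidates)
    for (i in seq_len(params$n_candidates)) {
      cand <- sample_from_densities(space, dens)
      tries <- 0L
      while (length(validate_config(space, cand)) > 0L && tries < 50L) {
        cand <- sample_from_densities(space, dens)
        tries <- tries + 1L
      }
      if (length(validate_config(space, cand)) > 0L) cand <- sample_config(space)
      candidates[[i]] <- cand
    }
  }
  scores <- vapply(candidates, score_candidate, 0, dens = dens)
  candidates[[which.max(scores)]]
}

#' TPE Bayesian optimisation
#'
#' Runs `n_trials` evaluations: the first `params$n_startup` uniformly at
#' random, the rest suggested by [tpe_suggest()]. The search is
#' checkpointable: pass `checkpoint_path` to append one JSON line per trial
#' and `resume_from` (a `tune_history`) to continue an interrupted run up
#' to the same total budget.
#'
#' @inheritParams random_search
#' @param params A [tpe_params()].
#' @param resume_from Optional existing `tune_history` over the same space.
#' @param checkpoint_path Optional JSONL path appended after every trial.
#' @return A `tune_history` with `n_trials` trials.
#' @export
tpe_optimize <- function(space, objective_fn, n_trials, seed = 1L,
                         params = tpe_params(), penalty = Inf,
                         resume_from = NULL, checkpoint_path = NULL) {
  if (!is_count(n_trials) || n_trials < params$n_startup) {
    stop_spectratune("`n_trials` must be >= `params$n_startup`.",
                     "spectratune_invalid_config")
  }
  history <- resume_from %||% new_history(space)
  set.seed(seed + length(history$trials))
  while (length(history$trials) < n_trials) {
    config <- if (length(history$trials) < params$n_startup) {
      sample_config(space)
    } else {
      tpe_suggest(space, history, params)
    }
    origin <- if (length(history$trials) < params$n_startup) "startup" else "tpe"
    res <- run_objective(objective_fn, config, penalty)
    history <- add_trial(history, config, res$objective, res$elapsed, origin)
    if (!is.null(checkpoint_path)) {
      append_history_line(history$trials[[length(history$trials)]],
                          checkpoint_path)
    }
  }
  history
}

# ---- history persistence -----------------------------------------

trial_to_json <- function(trial) {
  jsonlite::toJSON(
    list(index = trial$index, origin = trial$origin,
         status = trial$objective$status,
         mean_rmse = trial$objective$mean_rmse,
         fold_rmses = as.numeric(trial$objective$fold_rmses),
         elapsed = trial$elapsed, config = trial$config),
    auto_unbox = TRUE, digits = NA)
}

append_history_line <- function(trial, path) {
  cat(trial_to_json(trial), "\n", sep = "", file = path, append = TRUE)
}

#' Write / read a search history as JSON lines
#'
#' One trial per line: index, origin, status, mean and per-fold objectives,
#' elapsed seconds and the full configuration. The space is stored
#' alongside in `<path>.space.json` so histories round-trip.
#'
#' @param history A `tune_history`.
#' @param path Output `.jsonl` path.
#' @return `write_history()` returns `path` invisibly; `read_history()` a
#'   `tune_history`.
#' @export
write_history <- function(history, path) {
  lines <- vapply(history$trials, trial_to_json, "")
  writeLines(lines, path)
  write_search_space(history$space, paste0(path, ".space.json"))
  invisible(path)
}

#' @rdname write_history
#' @param space Optional [search_space()]; by default read from
#'   `<path>.space.json`.
#' @export
read_history <- function(path, space = NULL) {
  space <- space %||% read_search_space(paste0(path, ".space.json"))
  history <- new_history(space)
  for (line in readLines(path)) {
    if (!nzchar(trimws(line))) next
    rec <- jsonlite::fromJSON(line, simplifyVector = TRUE)
    cfg <- lapply(rec$config, function(v) if (is.list(v)) unlist(v) else v)
    # restore integer lattice values to integer storage
    for (nm in names(cfg)) {
      def <- space$defs[[nm]]
      if (!is.null(def) && def$kind == "integer") cfg[[nm]] <- as.integer(cfg[[nm]])
    }
    obj <- new_objective_value(rec$mean_rmse, as.numeric(rec$fold_rmses),
                               rec$status)
    history <- add_trial(history, cfg, obj, rec$elapsed, rec$origin)
  }
  history
}

#' Write a convergence trace
#'
#' @param history A `tune_history`.
#' @param path CSV output path with columns `trial`, `objective`,
#'   `running_best`, `origin`.
#' @return `path`, invisibly.
#' @export
write_convergence <- function(history, path) {
  tb <- as_tibble.tune_history(history)
  utils::write.csv(tb[, c("index", "objective", "running_best", "origin")],
                   path, row.names = FALSE)
  invisible(path)
}
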