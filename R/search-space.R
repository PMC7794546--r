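#' Hyperparameter definitions
#'
#' Building blocks of a tree-structured, mixed-type search space. A
#' definition has a unique `name`, a `kind` (`"integer"`, `"continuous"`,
#' `"categorical"` or `"flag"` — a flag being the two-category ON/OFF
#' state), a domain, an optional activation condition (the definition is
#' active only when a parent hyperparameter takes one of the given values)
#' and a presentation `group`.
#'
#' @param name Unique identifier.
#' @param low,high Inclusive bounds for numeric kinds.
#' @param values Category labels for categorical kinds.
#' @param condition `NULL`, or `list(parent = <name>, values = <allowed
#'   parent values>)`.
#' @param group One of `"input_channel"`, `"conv_block"`, `"fc_block"`,
#'   `"other"`.
#' @return A `hp_def` list.
#' @name hp_def
NULL

new_hp_def <- function(name, kind, domain, condition, group) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stop_spectratune("Hyperparameter names must be non-empty strings.",
                     "spectratune_invalid_space")
  }
  if (!is.null(condition) &&
      (!is.list(condition) || is.null(condition$parent) ||
       is.null(condition$values))) {
    stop_spectratune("`condition` must be list(parent=, values=).",
                     "spectratune_invalid_space")
  }
  group <- match.arg(group, c("input_channel", "conv_block", "fc_block", "other"))
  structure(list(name = name, kind = kind, domain = domain,
                 condition = condition, group = group),
            class = "hp_def")
}

#' @rdname hp_def
#' @export
hp_integer <- function(name, low, high, condition = NULL, group = "other") {
  if (!is_count(low, min = -Inf) || !is_count(high, min = -Inf) || low > high) {
    stop_spectratune(sprintf("Integer domain for '%s' needs low <= high.", name),
                     "spectratune_invalid_space")
  }
  new_hp_def(name, "integer", c(low = as.numeric(low), high = as.numeric(high)),
             condition, group)
}

#' @rdname hp_def
#' @export
hp_continuous <- function(name, low, high, condition = NULL, group = "other") {
  if (!is_number(low) || !is_number(high) || low > high) {
    stop_spectratune(sprintf("Continuous domain for '%s' needs low <= high.", name),
                     "spectratune_invalid_space")
  }
  new_hp_def(name, "continuous", c(low = low, high = high), condition, group)
}

#' @rdname hp_def
#' @export
hp_categorical <- function(name, values, condition = NULL, group = "other") {
  values <- as.character(values)
  if (length(values) < 1L || anyDuplicated(values)) {
    stop_spectratune(sprintf("Categories for '%s' must be unique and non-empty.", name),
                     "spectratune_invalid_space")
  }
  new_hp_def(name, "categorical", values, condition, group)
}

#' @rdname hp_def
#' @export
hp_flag <- function(name, condition = NULL, group = "other") {
  new_hp_def(name, "flag", c("ON", "OFF"), condition, group)
}

#' Assemble a search space
#'
#' Validates that names are unique, that every condition references an
#' earlier-defined parent (so the condition graph is a tree evaluated in
#' definition order) and stores the definitions in order.
#'
#' @param defs List of [hp_def] objects.
#' @return A `search_space`.
#' @seealso [default_cnn_space()], [sample_config()], [validate_config()]
#' @export
search_space <- function(defs) {
  nms <- vapply(defs, `[[`, "", "name")
  if (anyDuplicated(nms)) {
    stop_spectratune("Hyperparameter names must be unique.",
                     "spectratune_invalid_space")
  }
  for (i in seq_along(defs)) {
    cond <- defs[[i]]$condition
    if (!is.null(cond)) {
      j <- match(cond$parent, nms)
      if (is.na(j) || j >= i) {
        stop_spectratune(
          sprintf("Condition parent '%s' of '%s' must be defined earlier.",
                  cond$parent, nms[i]),
          "spectratune_invalid_space")
      }
    }
  }
  names(defs) <- nms
  structure(list(defs = defs), class = "search_space")
}

#' @export
print.search_space <- function(x, ...) {
  cat(sprintf("<search_space> %d hyperparameters (%d conditional)\n",
              length(x$defs),
              sum(!vapply(x$defs, function(d) is.null(d$condition), TRUE))))
  print(as_tibble(x), n = 12)
  invisible(x)
}

#' @method as_tibble search_space
#' @export
as_tibble.search_space <- function(x, ...) {
  purrr::map_dfr(x$defs, function(d) {
    tibble::tibble(
      name = d$name, kind = d$kind, group = d$group,
      domain = if (d$kind %in% c("integer", "continuous"))
        sprintf("[%g, %g]", d$domain[["low"]], d$domain[["high"]])
      else paste(d$domain, collapse = ", "),
      parent = if (is.null(d$condition)) NA_character_ else d$condition$parent
    )
  })
}

activation_choices <- function() c("ReLU", "LeakyReLU", "ELU", "SELU", "Swish")

#' Default 1D-CNN hyperparameter space for spectroscopic regression
#'
#' The full tree-structured space: five input-channel state flags; the
#' number of convolutional and fully-connected blocks; per conv-block
#' filters \[4, 64\], kernel \[2, 10\], stride \[2, 10\], padding type,
#' batch-norm state, activation, pooling state with conditional pool
#' type/size/stride/padding, and dropout state; per FC-block nodes
#' \[5, 256\], batch-norm state, activation and dropout state; shared
#' conv-block and FC-block dropout rates \[0, 0.5\]; the optimiser
#' (Adagrad, RMSProp, Adam); batch size \[16, n_samples\]; and the epoch
#' budget \[100, 1500\]. Per-block hyperparameters of blocks beyond the
#' active block count are inactive conditionals.
#'
#' @param n_samples Dataset size; upper bound of the batch-size domain
#'   (>= 16).
#' @param max_conv_blocks,max_fc_blocks Largest allowed block counts.
#' @param pool_size_range,pool_stride_range Integer domains for the
#'   conditional pooling hyperparameters.
#' @return A [search_space()].
#' @examples
#' sp <- default_cnn_space(n_samples = 1000)
#' length(sp$defs)
#' @export
default_cnn_space <- function(n_samples, max_conv_blocks = 4L,
                              max_fc_blocks = 3L,
                              pool_size_range = c(2L, 5L),
                              pool_stride_range = c(1L, 3L)) {
  if (!is_count(n_samples, min = 16L)) {
    stop_spectratune("`n_samples` must be an integer >= 16.",
                     "spectratune_invalid_space")
  }
  acts <- activation_choices()
  defs <- list(
    hp_flag("channel_R", group = "input_channel"),
    hp_flag("channel_ABS", group = "input_channel"),
    hp_flag("channel_ABS_D1", group = "input_channel"),
    hp_flag("channel_ABS_D2", group = "input_channel"),
    hp_flag("channel_ABS_SNV", group = "input_channel"),
    hp_integer("n_conv_blocks", 1L, max_conv_blocks),
    hp_integer("n_fc_blocks", 1L, max_fc_blocks)
  )
  for (i in seq_len(max_conv_blocks)) {
    active <- if (i == 1L) NULL else
      list(parent = "n_conv_blocks", values = seq(i, max_conv_blocks))
    pre <- sprintf("conv%d_", i)
    defs <- c(defs, list(
      hp_integer(paste0(pre, "filters"), 4L, 64L, active, "conv_block"),
      hp_integer(paste0(pre, "kernel"), 2L, 10L, active, "conv_block"),
      hp_integer(paste0(pre, "stride"), 2L, 10L, active, "conv_block"),
      hp_categorical(paste0(pre, "padding"), c("Same", "Valid"), active, "conv_block"),
      hp_flag(paste0(pre, "batch_norm"), active, "conv_block"),
      hp_categorical(paste0(pre, "activation"), acts, active, "conv_block"),
      hp_flag(paste0(pre, "pooling"), active, "conv_block"),
      hp_categorical(paste0(pre, "pool_type"), c("Average", "Max"),
                     list(parent = paste0(pre, "pooling"), values = "ON"),
                     "conv_block"),
      hp_integer(paste0(pre, "pool_size"), pool_size_range[1], pool_size_range[2],
                 list(parent = paste0(pre, "pooling"), values = "ON"), "conv_block"),
      hp_integer(paste0(pre, "pool_stride"), pool_stride_range[1], pool_stride_range[2],
                 list(parent = paste0(pre, "pooling"), values = "ON"), "conv_block"),
      hp_categorical(paste0(pre, "pool_padding"), c("Same", "Valid"),
                     list(parent = paste0(pre, "pooling"), values = "ON"),
                     "conv_block"),
      hp_flag(paste0(pre, "dropout"), active, "conv_block")
    ))
  }
  for (j in seq_len(max_fc_blocks)) {
    active <- if (j == 1L) NULL else
      list(parent = "n_fc_blocks", values = seq(j, max_fc_blocks))
    pre <- sprintf("fc%d_", j)
    defs <- c(defs, list(
      hp_integer(paste0(pre, "nodes"), 5L, 256L, active, "fc_block"),
      hp_flag(paste0(pre, "batch_norm"), active, "fc_block"),
      hp_categorical(paste0(pre, "activation"), acts, active, "fc_block"),
      hp_flag(paste0(pre, "dropout"), active, "fc_block")
    ))
  }
  defs <- c(defs, list(
    hp_continuous("conv_dropout_rate", 0, 0.5),
    hp_continuous("fc_dropout_rate", 0, 0.5),
    hp_categorical("optimiser", c("Adagrad", "RMSProp", "Adam")),
    hp_integer("batch_size", 16L, n_samples),
    hp_integer("epochs", 100L, 1500L)
  ))
  search_space(defs)
}

# is `def` active given the (partial) configuration?
def_is_active <- function(def, config) {
  cond <- def$condition
  if (is.null(cond)) return(TRUE)
  pv <- config[[cond$parent]]
  !is.null(pv) && pv %in% cond$values
}

value_in_domain <- function(def, value) {
  switch(def$kind,
    integer = is_number(value) && value == round(value) &&
      value >= def$domain[["low"]] && value <= def$domain[["high"]],
    continuous = is_number(value) &&
      value >= def$domain[["low"]] && value <= def$domain[["high"]],
    categorical = ,
    flag = is.character(value) && length(value) == 1L && value %in% def$domain
  )
}

#' Validate a configuration against a search space
#'
#' A valid configuration assigns every unconditional hyperparameter, assigns
#' a conditional hyperparameter exactly when its parent condition holds,
#' keeps every value inside its domain, and — when the space has
#' input-channel flags — turns at least one channel ON.
#'
#' @param space A [search_space()].
#' @param config Named list of hyperparameter values.
#' @return Character vector of human-readable violations; empty when valid.
#' @export
validate_config <- function(space, config) {
  violations <- character()
  for (def in space$defs) {
    active <- def_is_active(def, config)
    present <- !is.null(config[[def$name]])
    if (active && !present) {
      violations <- c(violations,
                      sprintf("'%s' is active but unassigned", def$name))
    } else if (!active && present) {
      violations <- c(violations,
                      sprintf("'%s' is assigned but its condition does not hold",
                              def$name))
    } else if (present && !value_in_domain(def, config[[def$name]])) {
      violations <- c(violations,
                      sprintf("'%s' = %s is outside its domain", def$name,
                              format(config[[def$name]])))
    }
  }
  ch <- intersect(names(space$defs),
                  grep("^channel_", names(space$defs), value = TRUE))
  if (length(ch) > 0) {
    on <- vapply(ch, function(nm) identical(config[[nm]], "ON"), TRUE)
    if (!any(on)) {
      violations <- c(violations, "all input-channel states are OFF")
    }
  }
  violations
}

sample_def_uniform <- function(def) {
  switch(def$kind,
    integer = def$domain[["low"]] +
      sample.int(def$domain[["high"]] - def$domain[["low"]] + 1L, 1L) - 1L,
    continuous = runif(1L, def$domain[["low"]], def$domain[["high"]]),
    categorical = ,
    flag = sample_one(def$domain)
  )
}

#' Sample a configuration uniformly
#'
#' Draws every unconditional hyperparameter uniformly over its domain
#' (integers on the lattice, categoricals over the categories) and every
#' conditional hyperparameter only when its parent condition holds. The rare
#' draw that fails [validate_config()] (all channel flags OFF) is rejected
#' and redrawn, so the result is uniform on the valid region.
#'
#' @param space A [search_space()].
#' @return A named list (`spectra_config`) passing [validate_config()].
#' @export
sample_config <- function(space) {
  for (attempt in 1:100) {
    config <- list()
    for (def in space$defs) {
      if (def_is_active(def, config)) {
        config[[def$name]] <- sample_def_uniform(def)
      }
    }
    if (length(validate_config(space, config)) == 0L) return(config)
  }
  stop_spectratune("Could not draw a valid configuration in 100 attempts.",
                   "spectratune_invalid_space")
}

#' Serialise / parse a search space
#'
#' Search spaces round-trip through YAML or JSON (chosen by file
#' extension): one record per hyperparameter with name, kind, domain,
#' condition and group.
#'
#' @param space A [search_space()].
#' @param path File path ending in `.yaml`/`.yml` or `.json`.
#' @return `write_search_space()` returns `path` invisibly;
#'   `read_search_space()` returns a [search_space()].
#' @export
write_search_space <- function(space, path) {
  recs <- lapply(unname(space$defs), function(d) {
    r <- list(name = d$name, kind = d$kind, group = d$group)
    if (d$kind %in% c("integer", "continuous")) {
      r$low <- unname(d$domain[["low"]]); r$high <- unname(d$domain[["high"]])
    } else {
      r$values <- as.list(d$domain)
    }
    if (!is.null(d$condition)) {
      r$condition <- list(parent = d$condition$parent,
                          values = as.list(d$condition$values))
    }
    r
  })
  if (grepl("\\.ya?ml$", path)) {
    yaml::write_yaml(recs, path)
  } else {
    jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

#' @rdname write_search_space
#' @export
read_search_space <- function(path) {
  recs <- if (grepl("\\.ya?ml$", path)) yaml::read_yaml(path)
          else jsonlite::read_json(path)
  defs <- lapply(recs, function(r) {
    cond <- if (!is.null(r$condition)) {
      list(parent = r$condition$parent,
           values = unlist(r$condition$values, use.names = FALSE))
    }
    switch(r$kind,
      integer = hp_integer(r$name, r$low, r$high, cond, r$group),
      continuous = hp_continuous(r$name, r$low, r$high, cond, r$group),
      categorical = hp_categorical(r$name,
                                   unlist(r$values, use.names = FALSE),
                                   cond, r$group),
      flag = hp_flag(r$name, cond, r$group),
      stop_spectratune(sprintf("Unknown hyperparameter kind '%s'.", r$kind),
                       "spectratune_invalid_space")
    )
  })
  search_space(defs)
}

#' Read / write a single configuration as JSON
#'
#' @param config Named list of hyperparameter values.
#' @param path JSON file path.
#' @return `write_config()` returns `path` invisibly; `read_config()` the
#'   named list.
#' @export
write_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  cfg <- jsonlite::read_json(path)
  lapply(cfg, function(v) if (is.list(v)) unlist(v, use.names = FALSE) else v)
}

# channel_states implied by a configuration's channel flags
config_channel_states <- function(config) {
  channel_states(
    reflectance = identical(config$channel_R, "ON"),
    absorbance = identical(config$channel_ABS, "ON"),
    abs_d1 = identical(config$channel_ABS_D1, "ON"),
    abs_d2 = identical(config$channel_ABS_D2, "ON"),
    abs_snv = identical(config$channel_ABS_SNV, "ON")
  )
}
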