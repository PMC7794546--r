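# ------------------------------------------------------------------
# Functional-ANOVA hyperparameter importance.
#
# A regression-tree ensemble is fitted to (configuration -> objective) and,
# for every tree and hyperparameter, the tree's exact marginal predictor is
# obtained by integrating its piecewise-constant function over all other
# dimensions with cell-volume weights (no Monte Carlo). First-order
# importance is the variance of that marginal divided by the tree's total
# variance, averaged over trees. The forest is hand-rolled because the
# integration needs the full partition geometry of every tree.
# ------------------------------------------------------------------

#' Encode a history for importance analysis
#'
#' Keeps only independent (unconditional) hyperparameters — they exist in
#' every trial, so the design matrix has no missing cells — and the mean
#' objective of every trial, penalised trials included (optionally
#' excluded). Hyperparameters that never varied are flagged in the column
#' metadata.
#'
#' @param history A `tune_history`.
#' @param min_trials Minimum number of trials required (default 30).
#' @param include_penalised Keep infeasible/failed trials (default `TRUE`;
#'   their penalty objective marks bad regions).
#' @return An `encoded_history`: `design` (data.frame), `response`,
#'   `columns` (tibble of name/kind/group/domain info, `constant` flag).
#' @export
encode_history <- function(history, min_trials = 30L,
                           include_penalised = TRUE) {
  trials <- history$trials
  if (!include_penalised) {
    trials <- purrr::keep(trials, function(tr) tr$objective$status == "ok")
  }
  if (length(trials) < min_trials) {
    stop_spectratune(
      sprintf("Need at least %d completed trials, have %d.",
              min_trials, length(trials)),
      "spectratune_invalid_history")
  }
  defs <- purrr::keep(history$space$defs,
                      function(d) is.null(d$condition))
  design <- as.data.frame(
    lapply(defs, function(d) {
      v <- vapply(trials, function(tr) {
        val <- tr$config[[d$name]]
        if (d$kind %in% c("categorical", "flag")) as.character(val)
        else as.character(as.numeric(val))
      }, "")
      if (d$kind %in% c("categorical", "flag")) v else as.numeric(v)
    }),
    optional = TRUE, stringsAsFactors = FALSE
  )
  names(design) <- names(defs)
  response <- vapply(trials, function(tr) tr$objective$mean_rmse, 0)
  columns <- purrr::map_dfr(defs, function(d) {
    tibble::tibble(
      name = d$name, kind = d$kind, group = d$group,
      low = if (d$kind %in% c("integer", "continuous")) d$domain[["low"]] else NA_real_,
      high = if (d$kind %in% c("integer", "continuous")) d$domain[["high"]] else NA_real_,
      categories = list(if (d$kind %in% c("categorical", "flag")) d$domain else NULL),
      constant = length(unique(design[[d$name]])) <= 1L
    )
  })
  structure(list(design = design, response = response, columns = columns),
            class = "encoded_history")
}

# ---- regression trees with recorded split geometry ---------------

# nodes are stored in a flat list; each node is either
#   list(leaf = TRUE, value = )
# or
#   list(leaf = FALSE, var = <column index>, type = "numeric"|"categorical",
#        split = <threshold> | <character vector of left categories>,
#        left = <node index>, right = <node index>)
fit_tree <- function(design, y, kinds, mtry, min_leaf) {
  nodes <- list()
  new_node <- function(node) {
    nodes[[length(nodes) + 1L]] <<- node
    length(nodes)
  }

  best_split <- function(idx) {
    feats <- sample.int(ncol(design), min(mtry, ncol(design)))
    best <- NULL
    base_sse <- sum((y[idx] - mean(y[idx]))^2)
    for (j in feats) {
      xj <- design[[j]][idx]
      if (kinds[j] == "numeric") {
        ord <- order(xj)
        xs <- xj[ord]; ys <- y[idx][ord]
        distinct <- which(diff(xs) > 0)
        if (length(distinct) == 0L) next
        csum <- cumsum(ys); tot <- csum[length(ys)]
        nl <- distinct
        sse_red <- csum[nl]^2 / nl + (tot - csum[nl])^2 / (length(ys) - nl)
        ok <- nl >= min_leaf & (length(ys) - nl) >= min_leaf
        if (!any(ok)) next
        k <- distinct[ok][which.max(sse_red[ok])]
        gain <- max(sse_red[ok]) - tot^2 / length(ys)
        if (is.null(best) || gain > best$gain) {
          best <- list(gain = gain, var = j, type = "numeric",
                       split = (xs[k] + xs[k + 1]) / 2)
        }
      } else {
        # order categories by mean response; scan splits along that order
        means <- tapply(y[idx], xj, mean)
        if (length(means) < 2L) next
        cats_ord <- names(sort(means))
        grp <- match(xj, cats_ord)
        ord <- order(grp)
        ys <- y[idx][ord]; gs <- grp[ord]
        distinct <- which(diff(gs) > 0)
        if (length(distinct) == 0L) next
        csum <- cumsum(ys); tot <- csum[length(ys)]
        nl <- distinct
        sse_red <- csum[nl]^2 / nl + (tot - csum[nl])^2 / (length(ys) - nl)
        ok <- nl >= min_leaf & (length(ys) - nl) >= min_leaf
        if (!any(ok)) next
        k <- which(ok)[which.max(sse_red[ok])]
        gain <- max(sse_red[ok]) - tot^2 / length(ys)
        left_cats <- cats_ord[seq_len(gs[distinct[k] + 1L] - 1L)]
        if (is.null(best) || gain > best$gain) {
          best <- list(gain = gain, var = j, type = "categorical",
                       split = left_cats)
        }
      }
    }
    best
  }

  grow <- function(idx) {
    if (length(idx) < 2L * min_leaf || length(unique(y[idx])) == 1L) {
      return(new_node(list(leaf = TRUE, value = mean(y[idx]))))
    }
    sp <- best_split(idx)
    node_sse <- sum((y[idx] - mean(y[idx]))^2)
    # gain threshold relative to the node SSE, so fits are invariant to
    # rescaling of the objective
    if (is.null(sp) || sp$gain <= 1e-10 * node_sse) {
      return(new_node(list(leaf = TRUE, value = mean(y[idx]))))
    }
    xj <- design[[sp$var]][idx]
    go_left <- if (sp$type == "numeric") xj <= sp$split else xj %in% sp$split
    left <- grow(idx[go_left])
    right <- grow(idx[!go_left])
    new_node(list(leaf = FALSE, var = sp$var, type = sp$type,
                  split = sp$split, left = left, right = right))
  }

  root <- grow(seq_along(y))
  list(nodes = nodes, root = root)
}

predict_tree <- function(tree, design) {
  vapply(seq_len(nrow(design)), function(i) {
    nd <- tree$nodes[[tree$root]]
    while (!nd$leaf) {
      xv <- design[[nd$var]][i]
      go_left <- if (nd$type == "numeric") xv <= nd$split else xv %in% nd$split
      nd <- tree$nodes[[if (go_left) nd$left else nd$right]]
    }
    nd$value
  }, 0)
}

# collect the partition cells of a tree: per leaf, value plus per-dimension
# bounds (numeric: c(lo, hi)) or category subsets
tree_cells <- function(tree, columns) {
  d <- nrow(columns)
  init <- lapply(seq_len(d), function(j) {
    if (columns$kind[j] %in% c("categorical", "flag")) columns$categories[[j]]
    else domain_bounds(columns, j)
  })
  cells <- list()
  recurse <- function(node_idx, cell) {
    nd <- tree$nodes[[node_idx]]
    if (nd$leaf) {
      cells[[length(cells) + 1L]] <<- list(value = nd$value, dims = cell)
      return(invisible())
    }
    j <- nd$var
    if (nd$type == "numeric") {
      lc <- cell; rc <- cell
      lc[[j]] <- c(cell[[j]][1], min(cell[[j]][2], nd$split))
      rc[[j]] <- c(max(cell[[j]][1], nd$split), cell[[j]][2])
      recurse(nd$left, lc)
      recurse(nd$right, rc)
    } else {
      lc <- cell; rc <- cell
      lc[[j]] <- intersect(cell[[j]], nd$split)
      rc[[j]] <- setdiff(cell[[j]], nd$split)
      recurse(nd$left, lc)
      recurse(nd$right, rc)
    }
  }
  recurse(tree$root, init)
  cells
}

# uniform-measure width of the full domain of column j (numeric span, with
# integers treated on a continuous lattice span +1)
domain_bounds <- function(columns, j) {
  lo <- columns$low[j]; hi <- columns$high[j]
  if (columns$kind[j] == "integer") c(lo - 0.5, hi + 0.5) else c(lo, hi)
}

cell_dim_fraction <- function(cell_dim, columns, j) {
  if (columns$kind[j] %in% c("categorical", "flag")) {
    length(cell_dim) / length(columns$categories[[j]])
  } else {
    b <- domain_bounds(columns, j)
    (cell_dim[2] - cell_dim[1]) / (b[2] - b[1])
  }
}

#' Exact marginal of a single tree along one dimension
#'
#' Integrates the tree's piecewise-constant prediction over all dimensions
#' except `dimension`, weighting every partition cell by its relative
#' volume under independent uniform inputs. For a numeric dimension the
#' result is a step function (breakpoints and values); for a categorical
#' one, a value per category. Also returns the marginal's mean and
#' variance under the uniform measure.
#'
#' @param tree A fitted tree (internal structure from the fANOVA forest).
#' @param columns Column metadata from [encode_history()].
#' @param dimension Column index or name.
#' @return List with `type`, `breaks`/`categories`, `values`, `mean`,
#'   `variance`.
#' @keywords internal
single_tree_marginal <- function(tree, columns, dimension) {
  j <- if (is.character(dimension)) match(dimension, columns$name) else dimension
  cells <- tree_cells(tree, columns)
  weights <- vapply(cells, function(cl) {
    prod(vapply(seq_len(nrow(columns))[-j], function(k) {
      cell_dim_fraction(cl$dims[[k]], columns, k)
    }, 0))
  }, 0)
  if (columns$kind[j] %in% c("categorical", "flag")) {
    cats <- columns$categories[[j]]
    vals <- vapply(cats, function(cc) {
      inc <- vapply(cells, function(cl) cc %in% cl$dims[[j]], TRUE)
      sum(weights[inc] * vapply(cells[inc], `[[`, 0, "value"))
    }, 0)
    m <- mean(vals)
    v <- mean((vals - m)^2)
    list(type = "categorical", categories = cats, values = vals,
         mean = m, variance = v)
  } else {
    b <- domain_bounds(columns, j)
    brks <- sort(unique(c(b, unlist(lapply(cells, function(cl) cl$dims[[j]])))))
    mids <- (brks[-1] + brks[-length(brks)]) / 2
    vals <- vapply(mids, function(x) {
      inc <- vapply(cells, function(cl) {
        x >= cl$dims[[j]][1] && x <= cl$dims[[j]][2]
      }, TRUE)
      sum(weights[inc] * vapply(cells[inc], `[[`, 0, "value"))
    }, 0)
    lens <- diff(brks) / (b[2] - b[1])
    m <- sum(lens * vals)
    v <- sum(lens * (vals - m)^2)
    list(type = "numeric", breaks = brks, values = vals, mean = m,
         variance = v)
  }
}

# total variance of a tree's prediction under independent uniform inputs
tree_total_variance <- function(tree, columns) {
  cells <- tree_cells(tree, columns)
  fracs <- vapply(cells, function(cl) {
    prod(vapply(seq_len(nrow(columns)), function(k) {
      cell_dim_fraction(cl$dims[[k]], columns, k)
    }, 0))
  }, 0)
  vals <- vapply(cells, `[[`, 0, "value")
  m <- sum(fracs * vals)
  sum(fracs * (vals - m)^2)
}

#' Functional-ANOVA hyperparameter importance
#'
#' Fits a bootstrap ensemble of regression trees to the encoded history and
#' decomposes each tree's prediction variance into per-hyperparameter
#' first-order (main-effect) fractions via exact cell-volume marginal
#' integration; fractions are averaged over trees and the remainder is
#' reported as the higher-order (interaction) fraction. Surrogate fit
#' quality is the out-of-bag R².
#'
#' @param encoded An [encode_history()] result.
#' @param n_trees Number of trees (default 64).
#' @param min_leaf Minimum samples per leaf (default 3).
#' @param mtry Features tried per split; default `ceiling(d / 3)`.
#' @param seed Integer seed for bootstrap and feature subsampling.
#' @return A `fanova_importance`: tibble of per-hyperparameter fractions
#'   plus `higher_order` fraction, `oob_r2` and settings. When every tree
#'   has zero prediction variance all fractions are 0 and `degenerate` is
#'   `TRUE`.
#' @export
fanova <- function(encoded, n_trees = 64L, min_leaf = 3L, mtry = NULL,
                   seed = 1L) {
  design <- encoded$design
  y <- encoded$response
  columns <- encoded$columns
  d <- ncol(design)
  n <- nrow(design)
  mtry <- mtry %||% max(1L, ceiling(d / 3))
  kinds <- ifelse(columns$kind %in% c("categorical", "flag"),
                  "categorical", "numeric")
  # canonical row order, so the report is invariant to trial permutations
  key <- do.call(paste, c(list(format(y, digits = 15)),
                          lapply(design, format), list(sep = "\r")))
  ord <- order(key)
  design <- design[ord, , drop = FALSE]
  y <- y[ord]
  set.seed(seed)

  frac_sum <- numeric(d)
  ho_sum <- 0
  n_used <- 0L
  oob_pred <- numeric(n)
  oob_cnt <- integer(n)

  for (t in seq_len(n_trees)) {
    boot <- sample.int(n, n, replace = TRUE)
    oob <- setdiff(seq_len(n), unique(boot))
    tree <- fit_tree(design[boot, , drop = FALSE], y[boot], kinds,
                     mtry, min_leaf)
    if (length(oob) > 0) {
      oob_pred[oob] <- oob_pred[oob] +
        predict_tree(tree, design[oob, , drop = FALSE])
      oob_cnt[oob] <- oob_cnt[oob] + 1L
    }
    v_tot <- tree_total_variance(tree, columns)
    if (v_tot < 1e-12) next
    fr <- vapply(seq_len(d), function(j) {
      single_tree_marginal(tree, columns, j)$variance / v_tot
    }, 0)
    frac_sum <- frac_sum + fr
    ho_sum <- ho_sum + (1 - sum(fr))
    n_used <- n_used + 1L
  }

  degenerate <- n_used == 0L
  fractions <- if (degenerate) numeric(d) else frac_sum / n_used
  higher_order <- if (degenerate) 0 else ho_sum / n_used

  seen <- oob_cnt > 0
  oob_r2 <- if (sum(seen) > 1 && stats::var(y[seen]) > 0) {
    1 - mean((y[seen] - oob_pred[seen] / oob_cnt[seen])^2) / stats::var(y[seen])
  } else NA_real_

  structure(
    list(
      importance = tibble::tibble(
        hyperparameter = columns$name,
        group = columns$group,
        fraction = fractions
      ) |> dplyr::arrange(dplyr::desc(.data$fraction)),
      higher_order = higher_order,
      oob_r2 = oob_r2,
      degenerate = degenerate,
      settings = list(n_trees = n_trees, min_leaf = min_leaf, mtry = mtry,
                      seed = seed)
    ),
    class = "fanova_importance"
  )
}

#' @export
print.fanova_importance <- function(x, ...) {
  cat(sprintf("<fanova_importance> %d hyperparameters, higher-order %.3f, OOB R2 %.3f\n",
              nrow(x$importance), x$higher_order,
              if (is.na(x$oob_r2)) NA else x$oob_r2))
  print(x$importance, n = 10)
  invisible(x)
}

#' Tidy a fANOVA importance report
#'
#' @param x A `fanova_importance`.
#' @param ... Unused.
#' @return Tibble with `hyperparameter`, `group`, `fraction`.
#' @method tidy fanova_importance
#' @export
tidy.fanova_importance <- function(x, ...) x$importance

#' One-row summary of a fANOVA report
#'
#' @param x A `fanova_importance`.
#' @param ... Unused.
#' @return Tibble with the higher-order fraction, OOB R² and top
#'   hyperparameter.
#' @method glance fanova_importance
#' @export
glance.fanova_importance <- function(x, ...) {
  tibble::tibble(
    n_hyperparameters = nrow(x$importance),
    higher_order = x$higher_order,
    oob_r2 = x$oob_r2,
    top_hyperparameter = x$importance$hyperparameter[1],
    degenerate = x$degenerate
  )
}

#' Importance bar chart
#'
#' Per-hyperparameter first-order variance fractions, coloured by group
#' (training-related, input channels, conv-block, FC-block).
#'
#' @param object A `fanova_importance`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fanova_importance
#' @export
autoplot.fanova_importance <- function(object, ...) {
  tb <- object$importance
  tb$hyperparameter <- stats::reorder(tb$hyperparameter, tb$fraction)
  ggplot2::ggplot(tb, ggplot2::aes(.data$fraction, .data$hyperparameter,
                                   fill = .data$group)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "First-order variance fraction", y = NULL,
                  fill = "Group") +
    ggplot2::theme_minimal()
}

#' Write an importance report to CSV
#'
#' @param report A `fanova_importance`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_importance <- function(report, path) {
  utils::write.csv(report$importance, path, row.names = FALSE)
  invisible(path)
}
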