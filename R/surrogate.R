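#' Deterministic surrogate objectives for fast optimiser studies
#'
#' A surrogate objective maps a configuration to a number without training
#' any network, so optimiser behaviour (TPE vs random search, importance
#' analysis) can be studied in seconds. `"quadratic"` is a smooth
#' RMSE-like landscape (units: g/kg, minimum near 5) whose optimum mirrors
#' a known-good spectroscopic CNN: late-epoch budgets, moderate batch
#' sizes, a single conv-block, Adam, derivative channels ON. `"sphere"` is
#' a neutral bowl over the numeric hyperparameters, centred mid-domain.
#'
#' Like the real cross-validated objective, `"quadratic"` first runs the
#' exact architecture shape arithmetic on a 211-point input: configurations
#' whose layer widths collapse below one point are infeasible and receive a
#' flat penalty value (30 g/kg, strictly worse than any feasible value), so
#' optimisers face the same feasibility structure they meet when training
#' real networks.
#'
#' @param name `"quadratic"` or `"sphere"`.
#' @param input_width Input width used for the feasibility check.
#' @param penalty Value returned for infeasible architectures.
#' @return A function `config -> numeric`.
#' @examples
#' f <- surrogate_objective("quadratic")
#' f(lucas_reference_config())
#' @export
surrogate_objective <- function(name = c("quadratic", "sphere"),
                                input_width = 211L, penalty = 30) {
  name <- match.arg(name)
  z <- function(v, lo, hi) (v - lo) / (hi - lo)
  cat_pen <- function(value, costs) costs[[value]] %||% 1

  if (name == "sphere") {
    return(function(config) {
      val <- 5
      for (nm in names(config)) {
        v <- config[[nm]]
        if (is.numeric(v)) val <- val + (v / max(abs(v), 1) - 0.5)^2
      }
      val
    })
  }

  function(config) {
    feasible <- tryCatch({
      build_architecture(config, input_width = input_width)
      TRUE
    }, spectratune_infeasible = function(e) FALSE)
    if (!feasible) return(penalty)
    val <- 5
    val <- val + 6 * (z(config$epochs, 100, 1500) - 0.9)^2
    val <- val + 0.6 * (log(config$batch_size) - log(256))^2 / log(10)^2 * 4
    val <- val + 0.8 * (config$n_conv_blocks - 1)
    val <- val + 0.4 * abs(config$n_fc_blocks - 2)
    val <- val + cat_pen(config$optimiser,
                         list(Adam = 0, RMSProp = 0.5, Adagrad = 1))
    val <- val + (if (identical(config$channel_R, "ON")) 0 else 0.4)
    val <- val + (if (identical(config$channel_ABS, "ON")) 0 else 0.3)
    val <- val + (if (identical(config$channel_ABS_D1, "ON")) 0 else 0.8)
    val <- val + (if (identical(config$channel_ABS_D2, "ON")) 0 else 0.2)
    val <- val + (if (identical(config$channel_ABS_SNV, "OFF")) 0 else 0.2)
    if (!is.null(config$conv1_filters)) {
      val <- val + 3 * (z(config$conv1_filters, 4, 64) - 0.85)^2
      val <- val + 2 * (z(config$conv1_kernel, 2, 10) - 0.4)^2
      val <- val + 1.5 * (z(config$conv1_stride, 2, 10) - 0.25)^2
      val <- val + (if (identical(config$conv1_padding, "Same")) 0 else 0.3)
      val <- val + (if (identical(config$conv1_pooling, "OFF")) 0 else 0.3)
    }
    if (!is.null(config$fc1_nodes)) {
      val <- val + 1.5 * (z(config$fc1_nodes, 5, 256) - 0.95)^2
    }
    val <- val + 1.2 * (config$fc_dropout_rate - 0.22)^2
    val
  }
}
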