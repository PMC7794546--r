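#' @importFrom rlang abort warn inform %||% .data
#' @importFrom tibble as_tibble tibble
#' @importFrom generics tidy glance
#' @export
generics::tidy
#' @export
generics::glance
#' @export
tibble::as_tibble
#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
#' @importFrom stats rnorm runif rlnorm sd var dnorm pnorm qnorm
#' @importFrom utils head tail
NULL

# error with a package-specific condition class so callers can catch it
stop_spectratune <- function(msg, class) {
  rlang::abort(msg, class = c(class, "spectratune_error"))
}

is_count <- function(x, min = 1L) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x) && x >= min
}

is_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}

# population (1/n) standard deviation
sd_pop <- function(x) {
  sqrt(mean((x - mean(x))^2))
}

sample_skewness <- function(x) {
  m <- mean(x)
  s <- sd_pop(x)
  mean((x - m)^3) / s^3
}

# sample one element from a vector without the length-1 surprise of sample()
sample_one <- function(x) {
  x[[sample.int(length(x), 1L)]]
}
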