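#' Regression accuracy metrics
#'
#' The three metrics used throughout the workflow. `r_squared()` is the
#' coefficient of determination
#' \deqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2,}
#' the proportion of total response variability explained by the model; it
#' can be negative for models worse than predicting the mean. `rmse()` is
#' \eqn{\sqrt{\sum e^2 / n}} and `mae()` is \eqn{\sum |e| / n}.
#'
#' @param actual Observed response values.
#' @param predicted Model predictions, same length.
#' @return A single numeric value.
#' @examples
#' r_squared(c(1, 2, 3), c(1, 2, 4))  # 0.5
#' rmse(c(0, 0), c(3, 4))             # sqrt(12.5)
#' mae(c(0, 0), c(3, 4))              # 3.5
#' @export
r_squared <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 2L)
  tss <- sum((actual - mean(actual))^2)
  if (tss <= 0) stop("R^2 undefined: response has zero variance", call. = FALSE)
  1 - sum((actual - predicted)^2) / tss
}

#' @rdname r_squared
#' @export
rmse <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 1L)
  sqrt(mean((actual - predicted)^2))
}

#' @rdname r_squared
#' @export
mae <- function(actual, predicted) {
  stopifnot(length(actual) == length(predicted), length(actual) >= 1L)
  mean(abs(actual - predicted))
}
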