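#' Multi-label binary cross-entropy loss
#'
#' The training objective for multi-hot disease labels: with sigmoid outputs
#' \eqn{\hat y_i} and labels \eqn{y_i} over C classes,
#' \deqn{L(\hat y, y) = -\frac{1}{C} \sum_{i=1}^{C} y_i \log \hat y_i +
#'   (1 - y_i) \log(1 - \hat y_i),}
#' averaged over the batch. Probabilities are clamped to
#' `[eps, 1 - eps]` before the logarithms so the loss is always finite.
#'
#' @param predictions Numeric matrix (N x C) of sigmoid probabilities in
#'   `[0, 1]` (a vector is treated as one row).
#' @param labels Binary matrix (N x C) of multi-hot labels, same shape.
#' @param eps Clamping constant (default `1e-7`).
#' @return A single non-negative number.
#' @examples
#' multi_label_loss(c(0.5, 0.5, 0.5, 0.5), c(1, 0, 0, 0))  # log(2)
#' @export
multi_label_loss <- function(predictions, labels, eps = 1e-7) {
  if (is.null(dim(predictions))) predictions <- matrix(predictions, nrow = 1)
  if (is.null(dim(labels))) labels <- matrix(labels, nrow = 1)
  if (!identical(dim(predictions), dim(labels))) {
    stop("predictions and labels must have the same shape", call. = FALSE)
  }
  if (any(predictions < 0 | predictions > 1)) {
    stop("predictions must lie in [0, 1]", call. = FALSE)
  }
  if (!all(labels %in% c(0, 1))) stop("labels must be binary", call. = FALSE)
  p <- pmin(pmax(predictions, eps), 1 - eps)
  per_image <- -rowMeans(labels * log(p) + (1 - labels) * log(1 - p))
  mean(per_image)
}
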