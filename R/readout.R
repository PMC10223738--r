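#' Detection-task readout normalization
#'
#' `A'_i = A_i / (A_0 + A_1 + b_0 + b_1)`. The bias factors `b_0`, `b_1`
#' keep the normalization well defined on windows that are almost entirely
#' dark (large lung regions with no structure), where both detector
#' readouts can be near zero.
#'
#' @param readout Nonnegative detector readouts `(A_0, A_1)` from
#'   [read_detectors()].
#' @param b0,b1 Nonnegative bias scalars.
#' @return Numeric vector `A'` of class `normalized_readout` with
#'   `scheme = "detection"`.
#' @export
normalize_detection <- function(readout, b0 = 0, b1 = 0) {
  A <- as.numeric(readout)
  if (any(A < 0) || b0 < 0 || b1 < 0) stop("readouts and biases must be >= 0")
  S <- sum(A) + b0 + b1
  if (S <= 0)
    stop("degenerate input: all readouts and biases are zero")
  structure(A / S, class = "normalized_readout", scheme = "detection",
            b0 = b0, b1 = b1)
}

#' Classification-task readout normalization
#'
#' `A'_i = alpha * A_i / max(A_0, A_1)`: the winning detector maps exactly
#' to `alpha`, the target scale of the mean-square-error loss.
#'
#' @param readout Nonnegative detector readouts.
#' @param alpha Positive target scale (default 1).
#' @return Numeric vector `A'` of class `normalized_readout` with
#'   `scheme = "classification"`.
#' @export
normalize_classification <- function(readout, alpha = 1) {
  A <- as.numeric(readout)
  if (alpha <= 0) stop("alpha must be > 0")
  M <- max(A)
  if (M <= 0) stop("degenerate input: max readout is zero")
  structure(alpha * A / M, class = "normalized_readout",
            scheme = "classification", alpha = alpha)
}

#' Softmax cross-entropy loss on normalized readouts
#'
#' `L = -sum_i y_i * log(softmax(A')_i)` for a one-hot label `y`.
#' With a symmetric readout (`A'_0 = A'_1`) the loss is `log(2)` for either
#' label.
#'
#' @param normalized Numeric vector of normalized readouts.
#' @param label One-hot numeric vector of the same length.
#' @return Nonnegative scalar loss.
#' @export
loss_softmax_ce <- function(normalized, label) {
  A <- as.numeric(normalized)
  .check_one_hot(label, length(A))
  z <- A - max(A)                       # stable log-sum-exp
  logp <- z - log(sum(exp(z)))
  -sum(label * logp)
}

#' Mean-square-error loss against an alpha-scaled one-hot target
#'
#' `L = sum_i (A'_i - alpha * y_i)^2`; zero exactly when the normalized
#' readout equals the scaled one-hot target.
#'
#' @inheritParams loss_softmax_ce
#' @param alpha Target scale (must match the normalization's alpha).
#' @return Nonnegative scalar loss.
#' @export
loss_mse <- function(normalized, label, alpha = 1) {
  A <- as.numeric(normalized)
  .check_one_hot(label, length(A))
  sum((A - alpha * label)^2)
}

.check_one_hot <- function(label, len) {
  if (length(label) != len || any(!label %in% c(0, 1)) || sum(label) != 1)
    stop("label must be one-hot over ", len, " classes")
  invisible(TRUE)
}

#' Per-class existence scores from a normalized readout
#'
#' `score_i = A'_i / (A'_0 + A'_1)`: nonnegative and summing to one, the
#' second component is interpreted as the probability that the window
#' contains a nodule.
#'
#' @param normalized Numeric vector of normalized readouts (nonnegative,
#'   not all zero).
#' @return Numeric score vector summing to 1.
#' @export
nodule_score <- function(normalized) {
  A <- as.numeric(normalized)
  s <- sum(A)
  if (s <= 0) stop("degenerate input: scores undefined when readouts sum to 0")
  A / s
}
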