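#' Numerically stabilized natural logarithm
#'
#' All logarithms of probabilities in the engine go through `lnstab()`, which
#' computes `log(x + eps)` with `eps = 1e-16` so that structural zeros in
#' likelihoods, transitions or preferences stay finite (floored near
#' `log(1e-16)`, about -36.8 nats) instead of producing `-Inf`.
#'
#' @param x Non-negative numeric vector, matrix or array.
#' @param eps Stabilization constant added before taking the log.
#' @return Object of the same shape as `x` with stabilized logs.
#' @export
#' @examples
#' lnstab(c(0, 0.5, 1))
lnstab <- function(x, eps = 1e-16) {
  log(x + eps)
}

#' Softmax (exp-normalization) of a vector of logits
#'
#' Returns the categorical distribution proportional to `exp(logits)`. The
#' computation subtracts the maximum logit first, so the result is invariant to
#' adding a constant to all logits and safe for large magnitudes.
#'
#' @param logits Finite numeric vector; length one or more.
#' @return Numeric probability vector summing to one.
#' @export
#' @examples
#' softmax(c(0, 0, 0))
#' softmax(log(1:3))
softmax <- function(logits) {
  if (length(logits) == 0L) {
    stop("`logits` must have length >= 1", call. = FALSE)
  }
  if (!is.numeric(logits) || anyNA(logits)) {
    stop("`logits` must be numeric and non-missing", call. = FALSE)
  }
  z <- exp(logits - max(logits))
  z / sum(z)
}

#' Log-sum-exp of a numeric vector
#' @noRd
logsumexp <- function(x) {
  m <- max(x)
  m + log(sum(exp(x - m)))
}

#' Validate a categorical probability vector
#'
#' Checks the invariants used throughout the engine: non-negative entries that
#' sum to one within `tol`.
#'
#' @param p Numeric vector.
#' @param tol Absolute tolerance on the sum.
#' @param what Label used in error messages.
#' @return `p`, invisibly, if valid; otherwise an error.
#' @export
check_categorical <- function(p, tol = 1e-10, what = "probability vector") {
  if (length(p) < 1L || !is.numeric(p)) {
    stop(sprintf("%s must be a numeric vector of length >= 1", what), call. = FALSE)
  }
  if (any(p < -tol)) {
    stop(sprintf("%s has negative entries", what), call. = FALSE)
  }
  if (abs(sum(p) - 1) > tol) {
    stop(sprintf("%s does not sum to 1 (sum = %.12g)", what, sum(p)), call. = FALSE)
  }
  invisible(p)
}

#' Normalize columns of a matrix (or a bare vector) to sum to one
#' @noRd
norm_cols <- function(m) {
  if (is.null(dim(m))) {
    return(m / sum(m))
  }
  sweep(m, 2L, colSums(m), "/")
}

#' Shannon entropy (nats) of a probability vector
#' @noRd
entropy_cat <- function(p) {
  -sum(p * lnstab(p))
}
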