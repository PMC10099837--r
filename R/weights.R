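#' Inverse-frequency class weights for imbalanced data
#'
#' Computes per-class weights from class counts as
#' \deqn{w_c = \frac{N}{K \cdot n_c}}
#' where `N` is the total sample count and `K` the number of classes — the
#' standard inverse-frequency weighting used with a categorical
#' cross-entropy loss.  Balanced counts give unit weights, and the weights
#' conserve total mass: \eqn{\sum_c n_c w_c = N}.
#'
#' @param counts Named numeric vector of per-class counts; every count must
#'   be positive.
#' @return A named numeric vector of weights (class `snprex_class_weights`).
#' @examples
#' compute_class_weights(c(POSITIVE = 623, NEGATIVE = 86, NEUTRAL = 77))
#' @export
compute_class_weights <- function(counts) {
  counts <- setNames(as.numeric(counts), names(counts))  # accepts table()
  if (is.null(names(counts)) && length(counts) > 0) {
    names(counts) <- paste0("class", seq_along(counts))
  }
  if (length(counts) == 0L) abort("`counts` must be non-empty.")
  if (any(is.na(counts)) || any(counts <= 0)) {
    abort("every class count must be a positive number.")
  }
  n <- sum(counts)
  k <- length(counts)
  structure(n / (k * counts), class = "snprex_class_weights")
}

#' @export
print.snprex_class_weights <- function(x, ...) {
  print(round(unclass(x), 4))
  invisible(x)
}
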