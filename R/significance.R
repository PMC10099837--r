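#' Paired significance test between two systems
#'
#' Compares two systems on aligned evaluation units: a paired t-test on
#' per-fold scores, or an exact two-sided binomial sign test on
#' per-instance win/loss counts with ties dropped.  Degenerate situations
#' are flagged rather than silently reported: zero variance of paired
#' differences leaves the t statistic undefined, and an all-tie sign test
#' (e.g. identical inputs) has no informative pairs and p-value 1.
#'
#' @param a,b Equal-length numeric vectors: per-fold scores (`test = "t"`)
#'   or per-instance correctness/score values (`test = "sign"`).
#' @param test `"t"` or `"sign"`.
#' @return A one-row tibble of class `snprex_significance`: `test`,
#'   `statistic`, `p_value`, `n_units`, `unit` (`"fold"` or `"instance"`),
#'   `degenerate`.
#' @examples
#' paired_significance(c(rep(1, 10)), c(rep(0, 10)), test = "sign")
#' @export
paired_significance <- function(a, b, test = c("t", "sign")) {
  test <- match.arg(test)
  stopifnot(length(a) == length(b), length(a) > 0)
  if (test == "t") {
    d <- a - b
    if (isTRUE(all.equal(stats::var(d), 0)) || length(d) < 2L) {
      out <- tibble(test = "paired t-test", statistic = NA_real_,
                    p_value = NA_real_, n_units = length(a), unit = "fold",
                    degenerate = TRUE)
    } else {
      tt <- t.test(a, b, paired = TRUE)
      out <- tibble(test = "paired t-test",
                    statistic = unname(tt$statistic),
                    p_value = tt$p.value, n_units = length(a),
                    unit = "fold", degenerate = FALSE)
    }
  } else {
    wins <- sum(a > b); losses <- sum(a < b)
    m <- wins + losses
    if (m == 0L) {
      out <- tibble(test = "sign test", statistic = NA_real_, p_value = 1,
                    n_units = 0L, unit = "instance", degenerate = TRUE)
    } else {
      bt <- binom.test(wins, m, p = 0.5)
      out <- tibble(test = "sign test", statistic = as.numeric(wins),
                    p_value = bt$p.value, n_units = m, unit = "instance",
                    degenerate = FALSE)
    }
  }
  class(out) <- c("snprex_significance", class(out))
  out
}
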