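#' Multi-class precision, recall and F1
#'
#' Computes per-class precision, recall, F1 and support from the confusion
#' matrix of aligned gold and predicted label vectors, plus macro and
#' support-weighted averages and micro accuracy.  Zero-division cases
#' (empty prediction or support for a class) are reported as 0 and flagged
#' in the per-class table.  The averaging mode actually used for headline
#' reporting is carried in the result and always printed, since macro and
#' weighted averages can differ substantially on imbalanced label sets.
#'
#' @param gold,predicted Equal-length label vectors (character or factor).
#' @param averaging Headline averaging mode: `"macro"` (default) or
#'   `"weighted"`.
#' @return An object of class `snprex_metrics`: use `tidy()` for the
#'   per-class table and `glance()` for the averages.
#' @examples
#' m <- prf_metrics(c("A", "A", "B"), c("A", "B", "B"))
#' tidy(m)
#' glance(m)
#' @export
prf_metrics <- function(gold, predicted, averaging = c("macro", "weighted")) {
  averaging <- match.arg(averaging)
  gold <- as.character(gold); predicted <- as.character(predicted)
  if (length(gold) != length(predicted)) {
    abort("`gold` and `predicted` must have the same length.")
  }
  if (length(gold) == 0L) abort("cannot score empty label vectors.")
  classes <- sort(union(gold, predicted))
  cm <- table(factor(gold, classes), factor(predicted, classes))
  tp <- diag(cm)
  pred_n <- colSums(cm)
  supp <- rowSums(cm)
  precision <- ifelse(pred_n > 0, tp / pred_n, 0)
  recall <- ifelse(supp > 0, tp / supp, 0)
  f1 <- ifelse(precision + recall > 0,
               2 * precision * recall / (precision + recall), 0)
  per_class <- tibble(
    class = classes,
    precision = as.numeric(precision),
    recall = as.numeric(recall),
    f1 = as.numeric(f1),
    support = as.integer(supp),
    zero_division = pred_n == 0 | supp == 0
  )
  w <- supp / sum(supp)
  structure(
    list(
      per_class = per_class,
      confusion = cm,
      averaging = averaging,
      macro = c(precision = mean(precision), recall = mean(recall),
                f1 = mean(f1)),
      weighted = c(precision = sum(w * precision), recall = sum(w * recall),
                   f1 = sum(w * f1)),
      accuracy = sum(tp) / length(gold)
    ),
    class = "snprex_metrics"
  )
}

#' @export
print.snprex_metrics <- function(x, ...) {
  cat("<snprex_metrics>", x$averaging, "averaging\n")
  print(x$per_class)
  avg <- if (x$averaging == "macro") x$macro else x$weighted
  cat(sprintf("%s P/R/F1: %.3f / %.3f / %.3f   accuracy: %.3f\n",
              x$averaging, avg["precision"], avg["recall"], avg["f1"],
              x$accuracy))
  invisible(x)
}

#' @export
tidy.snprex_metrics <- function(x, ...) x$per_class

#' @export
glance.snprex_metrics <- function(x, ...) {
  tibble(
    averaging = x$averaging,
    precision = unname(if (x$averaging == "macro") x$macro["precision"]
                       else x$weighted["precision"]),
    recall = unname(if (x$averaging == "macro") x$macro["recall"]
                    else x$weighted["recall"]),
    f1 = unname(if (x$averaging == "macro") x$macro["f1"]
                else x$weighted["f1"]),
    macro_precision = unname(x$macro["precision"]),
    macro_recall = unname(x$macro["recall"]),
    macro_f1 = unname(x$macro["f1"]),
    weighted_precision = unname(x$weighted["precision"]),
    weighted_recall = unname(x$weighted["recall"]),
    weighted_f1 = unname(x$weighted["f1"]),
    accuracy = x$accuracy
  )
}

#' Cohen's kappa chance-corrected agreement
#'
#' \eqn{\kappa = (p_o - p_e)/(1 - p_e)} with expected agreement from the
#' product of marginal label distributions — the usual inter-annotator
#' agreement statistic.  When the expected agreement is 1 (both sequences
#' constant and identical) kappa is undefined and returned as `NA` with a
#' warning.
#'
#' @param labels_a,labels_b Equal-length label vectors.
#' @return A single numeric kappa value.
#' @export
cohen_kappa <- function(labels_a, labels_b) {
  labels_a <- as.character(labels_a); labels_b <- as.character(labels_b)
  if (length(labels_a) != length(labels_b)) {
    abort("label sequences must have the same length.")
  }
  n <- length(labels_a)
  if (n == 0L) abort("cannot compute agreement on empty sequences.")
  classes <- union(labels_a, labels_b)
  p_o <- mean(labels_a == labels_b)
  pa <- table(factor(labels_a, classes)) / n
  pb <- table(factor(labels_b, classes)) / n
  p_e <- sum(as.numeric(pa) * as.numeric(pb))
  if (p_e >= 1) {
    warn("expected agreement is 1; kappa is undefined.")
    return(NA_real_)
  }
  (p_o - p_e) / (1 - p_e)
}

#' Rank-based ROC AUC
#'
#' The probability that a randomly chosen positive instance receives a
#' higher score than a randomly chosen negative one, with ties counting
#' one half — the Mann-Whitney formulation of the area under the ROC
#' curve.  Invariant under any strictly monotone transform of the scores.
#'
#' @param scores Numeric scores, larger meaning more positive.
#' @param gold Binary gold labels: logical, 0/1, or a two-level factor /
#'   character vector whose second sorted level is treated as positive
#'   unless `positive` is given.
#' @param positive Optional positive-class label.
#' @return A single numeric AUC in \[0, 1\].
#' @export
roc_auc <- function(scores, gold, positive = NULL) {
  stopifnot(length(scores) == length(gold))
  if (is.logical(gold)) {
    pos <- gold
  } else if (is.numeric(gold)) {
    pos <- gold == max(gold)
  } else {
    gold <- as.character(gold)
    lv <- sort(unique(gold))
    positive <- positive %||% lv[length(lv)]
    pos <- gold == positive
  }
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) {
    abort("AUC requires both a positive and a negative instance.")
  }
  r <- rank(scores)  # average ranks give ties weight 1/2
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}
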