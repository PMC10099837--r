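#' Plot per-class metrics
#'
#' Bar chart of precision, recall and F1 per class for a
#' [prf_metrics()] result.
#'
#' @param object A `snprex_metrics` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snprex_metrics <- function(object, ...) {
  long <- tidyr::pivot_longer(object$per_class,
                              c("precision", "recall", "f1"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$class, y = .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Per-class metrics (%s averaging headline)",
                                  object$averaging)) +
    ggplot2::theme_minimal()
}

#' Plot label and certainty distributions of a corpus
#'
#' @param object A `snprex_corpus_stats` object from [corpus_statistics()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.snprex_corpus_stats <- function(object, ...) {
  d <- tibble(
    group = c(rep("association label", 3), rep("certainty grade", 3)),
    level = c("positive", "negative", "neutral", "weak", "moderate", "strong"),
    n = c(object$n_positive, object$n_negative, object$n_neutral,
          object$n_weak, object$n_moderate, object$n_strong)
  )
  ggplot2::ggplot(d, ggplot2::aes(x = .data$level, y = .data$n)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~group, scales = "free_x") +
    ggplot2::labs(x = NULL, y = "candidates") +
    ggplot2::theme_minimal()
}

#' ROC curve for a binary scorer
#'
#' Plots the empirical ROC curve (true positive rate against false
#' positive rate over all score thresholds) and annotates the rank-based
#' AUC from [roc_auc()].
#'
#' @inheritParams roc_auc
#' @return A ggplot object.
#' @export
plot_roc <- function(scores, gold, positive = NULL) {
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
  ord <- order(scores, decreasing = TRUE)
  tpr <- c(0, cumsum(pos[ord]) / sum(pos))
  fpr <- c(0, cumsum(!pos[ord]) / sum(!pos))
  auc <- roc_auc(scores, pos)
  ggplot2::ggplot(tibble(fpr = fpr, tpr = tpr),
                  ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step() +
    ggplot2::geom_abline(linetype = "dashed", colour = "grey60") +
    ggplot2::labs(x = "False positive rate", y = "True positive rate",
                  title = sprintf("ROC curve (AUC = %.3f)", auc)) +
    ggplot2::theme_minimal()
}
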