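#' Seeded (stratified) k-fold assignment
#'
#' Partitions `n` instances into `k` folds.  Stratified assignment shuffles
#' each class and deals its members round-robin across folds, so per-fold
#' class counts differ by at most one instance from exact proportionality;
#' it requires every class to have at least `k` members.  The assignment is
#' a pure function of `(n, k, labels, seed)`.
#'
#' @param n Number of instances (or a data frame, whose row count is used).
#' @param k Number of folds (>= 2).
#' @param stratify Logical; stratify by `labels`?
#' @param labels Label vector of length `n` (required when stratifying).
#' @param seed Integer seed.
#' @return An integer vector of fold ids in `1:k`, length `n`.
#' @export
kfold_split <- function(n, k, stratify = FALSE, labels = NULL, seed = 1L) {
  if (is.data.frame(n)) n <- nrow(n)
  n <- as.integer(n); k <- as.integer(k)
  if (k < 2L) abort("`k` must be at least 2.")
  if (n < k) abort("cannot make more folds than instances.")
  set.seed(seed)
  if (!stratify) {
    return(sample(rep_len(seq_len(k), n)))
  }
  if (is.null(labels) || length(labels) != n) {
    abort("stratified folding requires `labels` of length n.")
  }
  labels <- as.character(labels)
  counts <- table(labels)
  if (min(counts) < k) {
    abort(sprintf(
      "stratification infeasible: class '%s' has %d < k = %d instances.",
      names(which.min(counts)), min(counts), k))
  }
  fold <- integer(n)
  offset <- 0L
  for (cl in sort(unique(labels))) {
    idx <- sample(which(labels == cl))
    # rotate the starting fold between classes so remainders spread out
    fold[idx] <- ((seq_along(idx) - 1L + offset) %% k) + 1L
    offset <- offset + length(idx)
  }
  fold
}

#' Aggregate candidate predictions to abstract level
#'
#' Collapses sentence-level candidate labels to one label per (document,
#' SNP surface, phenotype surface) group: under `"any-positive"` a group
#' containing any `POSITIVE` is positive, then any `NEGATIVE` negative,
#' else `NEUTRAL`; under `"majority"` the modal label wins, with ties
#' resolved to `NEGATIVE`.
#'
#' @param predictions Tibble with columns `doc_id`, `label`, and grouping
#'   columns `snp` and `phenotype` (entity surface forms or ids).
#' @param policy `"any-positive"` or `"majority"`.
#' @return A tibble with one row per group: `doc_id`, `snp`, `phenotype`,
#'   `label`.
#' @export
aggregate_to_abstract <- function(predictions,
                                  policy = c("any-positive", "majority")) {
  policy <- match.arg(policy)
  stopifnot(all(c("doc_id", "snp", "phenotype", "label") %in%
                  names(predictions)))
  vote <- function(labs) {
    if (policy == "any-positive") {
      if (any(labs == "POSITIVE")) return("POSITIVE")
      if (any(labs == "NEGATIVE")) return("NEGATIVE")
      return("NEUTRAL")
    }
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    if (length(winners) > 1L) "NEGATIVE" else winners
  }
  summarise(group_by(as_tibble(predictions), .data$doc_id, .data$snp,
                     .data$phenotype),
            label = vote(.data$label), .groups = "drop")
}
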