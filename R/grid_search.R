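#' Exhaustive grid search with seeded stratified cross-validation
#'
#' Evaluates every point of a hyperparameter grid for one baseline family
#' by stratified k-fold cross-validation (see [kfold_split()]) and returns
#' the best point together with the full score table.  Ties are broken in
#' favour of the first-listed grid point, and folds are fixed by the seed
#' before the sweep, so the search is fully deterministic.
#'
#' The canonical logistic-regression grid of this pipeline crosses seven
#' regularization strengths `C = 10^k, k = -3..3` with penalty `l1`/`l2`
#' and a recorded `solver` axis (28 points); the solver axis is inert under
#' the single glmnet backend but preserved so grids transcribe one-to-one.
#'
#' @param data Feature + label data frame (as for [train_baseline()]).
#' @param label Label column name.
#' @param family Baseline family passed to [train_baseline()].
#' @param grid Named list of parameter value vectors; the grid is their
#'   full cross product and must be non-empty.
#' @param k Fold count (>= 2).
#' @param scoring `"macro_f1"`, `"weighted_f1"` or `"accuracy"`.
#' @param weights Optional class weights applied at every fit.
#' @param seed Integer seed controlling fold assignment and fits.
#' @return A list of class `snprex_grid` with elements `best_params` (named
#'   list), `best_score`, and `results` (one row per grid point with its
#'   mean cross-validated score).
#' @export
grid_search <- function(data, label = "label", family = "logreg",
                        grid = list(C = 10^(-3:3), penalty = c("l1", "l2"),
                                    solver = c("liblinear", "newton-cg")),
                        k = 5L, scoring = c("macro_f1", "weighted_f1",
                                            "accuracy"),
                        weights = NULL, seed = 1L) {
  scoring <- match.arg(scoring)
  if (length(grid) == 0L || any(lengths(grid) == 0L)) {
    abort("`grid` must be a non-empty named list of value vectors.")
  }
  if (k < 2L) abort("fold count must be at least 2.")
  data <- as.data.frame(data)
  y <- as.character(data[[label]])
  folds <- kfold_split(length(y), k = k, stratify = TRUE, labels = y,
                       seed = seed)
  points <- expand.grid(grid, stringsAsFactors = FALSE,
                        KEEP.OUT.ATTRS = FALSE)

  score_point <- function(params) {
    fold_scores <- map_dbl(seq_len(k), function(f) {
      tr <- data[folds != f, , drop = FALSE]
      te <- data[folds == f, , drop = FALSE]
      m <- train_baseline(tr, label = label, family = family,
                         weights = weights, seed = seed, params = params)
      pred <- predict(m, te[, setdiff(names(te), label), drop = FALSE])
      rep <- prf_metrics(te[[label]], pred)
      switch(scoring,
             macro_f1 = glance(rep)$macro_f1,
             weighted_f1 = glance(rep)$weighted_f1,
             accuracy = glance(rep)$accuracy)
    })
    mean(fold_scores)
  }

  scores <- map_dbl(seq_len(nrow(points)), function(i) {
    score_point(as.list(points[i, , drop = FALSE]))
  })
  best <- which.max(scores)  # first maximum: first-listed point wins ties
  structure(
    list(
      best_params = as.list(points[best, , drop = FALSE]),
      best_score = scores[best],
      results = bind_cols(as_tibble(points), tibble(score = scores)),
      scoring = scoring, k = k, seed = seed, family = family
    ),
    class = "snprex_grid"
  )
}

#' @export
print.snprex_grid <- function(x, ...) {
  cat("<snprex_grid>", nrow(x$results), "points,", x$k, "folds,",
      x$scoring, "\n")
  cat("  best:", paste(names(x$best_params),
                       vapply(x$best_params, format, ""), sep = "=",
                       collapse = ", "),
      sprintf("(score %.4f)", x$best_score), "\n")
  invisible(x)
}

#' @export
tidy.snprex_grid <- function(x, ...) x$results

#' @export
glance.snprex_grid <- function(x, ...) {
  tibble(n_points = nrow(x$results), k = x$k, scoring = x$scoring,
         best_score = x$best_score, seed = x$seed, family = x$family)
}
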