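#' Certainty feature extraction for positive associations (MBS features)
#'
#' Builds the modality-based feature vector used to grade how certain a
#' positively reported association is: one indicator per modality marker in
#' the lexicon, the marker count, whether the sentence reports a p-value,
#' the smallest reported p-value and whether it bounds significance below
#' `config$alpha`, and clause-connector indicators (any connector /
#' concessive connector).  Marker sources follow `mode`: gold annotation or
#' the heuristic lexicon matcher.  A certainty grade is only defined for
#' positive candidates, so non-positive input is an error.
#'
#' @param corpus An [snp_corpus()].
#' @param candidates Candidate tibble; defaults to the corpus's POSITIVE
#'   gold candidates.  A `label` or `gold_label` column, when present, must
#'   be `"POSITIVE"` throughout.
#' @param config A [snprex_config()].
#' @param mode `"heuristic"` or `"gold"` marker source.
#' @return A tibble: candidate keys, `marker_*` indicator columns (one per
#'   lexicon entry), `n_markers`, `has_pvalue`, `min_pvalue` (`NA` when
#'   absent), `pvalue_significant`, `has_connector`, `has_concessive`.
#' @export
mbs_features <- function(corpus, candidates = NULL, config = snprex_config(),
                         mode = c("heuristic", "gold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "snp_corpus"))
  if (is.null(candidates)) {
    candidates <- filter(corpus$candidates, .data$gold_label == "POSITIVE")
  }
  labcol <- intersect(c("label", "gold_label"), names(candidates))
  if (length(labcol) && any(candidates[[labcol[1]]] != "POSITIVE")) {
    abort("certainty features are only defined for POSITIVE candidates.")
  }
  markers <- detect_modality_markers(corpus, config, mode)
  pvals <- extract_pvalues(corpus, config)
  conns <- detect_clause_connectors(corpus, config)
  lex <- config$modality_markers
  mk_cols <- paste0("marker_", gsub("[^a-z0-9]+", "_", lex))

  rows <- map(seq_len(nrow(candidates)), function(i) {
    cd <- candidates[i, ]
    mm <- filter(markers, .data$doc_id == cd$doc_id, .data$sent_id == cd$sent_id)
    pv <- filter(pvals, .data$doc_id == cd$doc_id, .data$sent_id == cd$sent_id)
    cc <- filter(conns, .data$doc_id == cd$doc_id, .data$sent_id == cd$sent_id)
    ind <- setNames(as.list(lex %in% tolower(mm$text)), mk_cols)
    has_p <- nrow(pv) > 0L
    min_p <- if (has_p) min(pv$value) else NA_real_
    sig <- has_p && any(pvalue_is_significant(pv$comparator, pv$value,
                                              config$alpha))
    bind_cols(
      select(cd, "doc_id", "sent_id", "snp_id", "phenotype_id"),
      as_tibble(ind),
      tibble(
        n_markers = nrow(mm), has_pvalue = has_p, min_pvalue = min_p,
        pvalue_significant = sig,
        has_connector = nrow(cc) > 0L,
        has_concessive = nrow(cc) > 0L && any(cc$is_concessive)
      )
    )
  })
  if (length(rows) == 0L) {
    return(bind_cols(
      empty_candidates()[0, 1:4],
      as_tibble(setNames(rep(list(logical()), length(mk_cols)), mk_cols)),
      tibble(n_markers = integer(), has_pvalue = logical(),
             min_pvalue = double(), pvalue_significant = logical(),
             has_connector = logical(), has_concessive = logical())
    ))
  }
  list_rbind(rows)
}

mbs_feature_matrix <- function(features) {
  cols <- setdiff(names(features),
                  c("doc_id", "sent_id", "snp_id", "phenotype_id"))
  x <- features[, cols, drop = FALSE]
  # encode min_pvalue as -log10 evidence with an explicit absence indicator
  x$neg_log10_p <- ifelse(x$has_pvalue & !is.na(x$min_pvalue),
                          -log10(pmax(x$min_pvalue, 1e-300)), 0)
  x$min_pvalue <- NULL
  m <- as.matrix(as.data.frame(lapply(x, as.numeric)))
  rownames(m) <- NULL
  m
}

#' Train the certainty classifier
#'
#' Fits a margin classifier (support vector machine with a linear kernel by
#' default) on certainty feature vectors, with optional per-class weights
#' for the imbalanced grade distribution.  The returned model records its
#' feature schema, hyperparameters and training seed; prediction refuses a
#' feature table whose schema does not match.
#'
#' @param features Feature tibble from [mbs_features()].
#' @param labels Character vector of grades (`WEAK`/`MODERATE`/`STRONG`),
#'   one per feature row; at least two distinct grades are required.
#' @param weights Optional named class-weight vector, e.g. from
#'   [compute_class_weights()].
#' @param kernel SVM kernel (default `"linear"`).
#' @param cost SVM cost parameter.
#' @param seed Integer seed recorded and applied during fitting.
#' @return An object of class `snprex_certainty_model`.
#' @export
train_certainty_model <- function(features, labels, weights = NULL,
                                  kernel = "linear", cost = 1, seed = 1L) {
  if (nrow(features) == 0L) abort("cannot train on an empty feature set.")
  labels <- as.character(labels)
  stopifnot(length(labels) == nrow(features))
  if (length(unique(labels)) < 2L) {
    abort("training requires at least two distinct certainty grades.")
  }
  x <- mbs_feature_matrix(features)
  y <- factor(labels)
  set.seed(seed)
  fit <- e1071::svm(x = x, y = y, kernel = kernel, cost = cost,
                    class.weights = weights, scale = FALSE)
  structure(
    list(fit = fit, schema = colnames(x),
         classes = levels(y),
         majority = names(which.max(table(y))),
         hyperparameters = list(kernel = kernel, cost = cost,
                                weights = weights),
         seed = seed, n_train = nrow(x)),
    class = "snprex_certainty_model"
  )
}

#' Predict certainty grades
#'
#' @param model A trained [train_certainty_model()] object.
#' @param features Feature tibble from [mbs_features()] with the same
#'   schema the model was trained on.
#' @return Character vector of predicted grades.  Feature rows with no
#'   signal at all (no marker, no p-value, no connector) fall back to the
#'   training majority class, with a message.
#' @export
predict_certainty <- function(model, features) {
  stopifnot(inherits(model, "snprex_certainty_model"))
  x <- mbs_feature_matrix(features)
  if (!identical(colnames(x), model$schema)) {
    abort("feature schema does not match the trained model's schema.")
  }
  out <- as.character(predict(model$fit, x))
  blank <- rowSums(abs(x)) == 0
  if (any(blank)) {
    inform(sprintf(
      "%d feature vector(s) carried no signal; falling back to majority class '%s'.",
      sum(blank), model$majority))
    out[blank] <- model$majority
  }
  out
}

#' @export
print.snprex_certainty_model <- function(x, ...) {
  cat("<snprex_certainty_model>", x$hyperparameters$kernel, "SVM,",
      x$n_train, "training vectors, classes:",
      paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

#' @export
glance.snprex_certainty_model <- function(x, ...) {
  tibble(model_family = "svm", kernel = x$hyperparameters$kernel,
         cost = x$hyperparameters$cost, n_train = x$n_train,
         n_classes = length(x$classes), seed = x$seed)
}

#' @export
tidy.snprex_certainty_model <- function(x, ...) {
  tibble(class = x$classes, n_support_vectors = as.integer(x$fit$nSV))
}
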