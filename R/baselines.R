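#' Train a shallow baseline classifier
#'
#' Fits one of the standard model families over a numeric feature table,
#' with optional class weighting (from [compute_class_weights()]) applied
#' wherever the family supports it, and all randomness seeded so that the
#' same data, seed and parameters reproduce the fit bit for bit.
#'
#' Families and their backends: `"logreg"` (multinomial elastic net,
#' glmnet), `"random_forest"` (ranger), `"decision_tree"` (rpart),
#' `"gradient_boosting"` (xgboost), `"naive_bayes"` (e1071, Gaussian; no
#' weight support), `"knn"` (class, distance-based, weights not
#' applicable), `"svm"` (e1071 margin classifier).
#'
#' @param data A data frame/tibble whose columns are numeric features plus
#'   one label column.
#' @param label Name of the label column (default `"label"`).
#' @param family One of `"logreg"`, `"random_forest"`, `"decision_tree"`,
#'   `"gradient_boosting"`, `"naive_bayes"`, `"knn"`, `"svm"`.
#' @param weights Optional named class weights.
#' @param seed Integer seed.
#' @param params Named list of family-specific hyperparameters, e.g.
#'   `list(C = 1, penalty = "l2")` for `"logreg"`, `list(k = 5)` for
#'   `"knn"`, `list(cost = 1, kernel = "linear")` for `"svm"`,
#'   `list(nrounds = 50, max_depth = 3)` for `"gradient_boosting"`.
#' @return An object of class `snprex_model` with a [predict()] method
#'   (`type = "class"` or `"prob"`).
#' @export
train_baseline <- function(data, label = "label",
                           family = c("logreg", "random_forest",
                                      "decision_tree", "gradient_boosting",
                                      "naive_bayes", "knn", "svm"),
                           weights = NULL, seed = 1L, params = list()) {
  family <- match.arg(family)
  data <- as.data.frame(data)
  if (!label %in% names(data)) abort(sprintf("no column '%s' in data.", label))
  y <- factor(data[[label]])
  if (nlevels(y) < 2L) abort("training requires at least two classes.")
  x <- as.matrix(data[, setdiff(names(data), label), drop = FALSE])
  storage.mode(x) <- "double"
  if (!is.null(weights)) {
    weights <- unclass(weights)
    missing_cls <- setdiff(levels(y), names(weights))
    if (length(missing_cls)) {
      abort(sprintf("weights missing for class(es): %s",
                    paste(missing_cls, collapse = ", ")))
    }
  }
  case_w <- if (is.null(weights)) rep(1, length(y)) else weights[as.character(y)]
  set.seed(seed)

  fit <- switch(family,
    logreg = {
      alpha <- if (identical(params$penalty, "l1")) 1 else 0
      lambda <- 1 / (params$C %||% 1) / length(y)
      glmnet::glmnet(x, y, family = "multinomial", alpha = alpha,
                     lambda = lambda, weights = case_w)
    },
    random_forest = ranger::ranger(
      x = as.data.frame(x), y = y,
      num.trees = params$num_trees %||% 200,
      case.weights = case_w, probability = TRUE,
      seed = seed, num.threads = 1
    ),
    decision_tree = {
      df <- data.frame(.y = y, x, check.names = FALSE)
      rpart::rpart(.y ~ ., data = df, weights = case_w,
                   method = "class",
                   control = rpart::rpart.control(
                     minsplit = params$minsplit %||% 5, cp = params$cp %||% 0.001))
    },
    gradient_boosting = {
      dtrain <- xgboost::xgb.DMatrix(x, label = as.integer(y) - 1L,
                                     weight = case_w)
      xgboost::xgb.train(
        params = list(objective = "multi:softprob",
                      num_class = nlevels(y),
                      max_depth = params$max_depth %||% 3,
                      eta = params$eta %||% 0.3,
                      nthread = 1, seed = seed),
        data = dtrain, nrounds = params$nrounds %||% 50, verbose = 0)
    },
    naive_bayes = e1071::naiveBayes(x = as.data.frame(x), y = y),
    knn = list(x = x, y = y, k = params$k %||% 5),  # lazy learner
    svm = e1071::svm(x = x, y = y,
                     kernel = params$kernel %||% "linear",
                     cost = params$cost %||% 1,
                     class.weights = weights, probability = TRUE,
                     scale = FALSE)
  )
  structure(
    list(family = family, fit = fit, classes = levels(y),
         feature_names = colnames(x), seed = seed, params = params,
         weights = weights, n_train = nrow(x)),
    class = "snprex_model"
  )
}

#' Predict from a baseline model
#'
#' @param object An `snprex_model`.
#' @param newdata Data frame or matrix of features with the training
#'   columns.
#' @param type `"class"` for labels, `"prob"` for a class-probability
#'   matrix (families without calibrated probabilities return 0/1 votes).
#' @param ... Unused.
#' @export
predict.snprex_model <- function(object, newdata, type = c("class", "prob"),
                                 ...) {
  type <- match.arg(type)
  newdata <- as.data.frame(newdata)
  miss <- setdiff(object$feature_names, names(newdata))
  if (length(miss)) {
    abort(sprintf("newdata lacks feature column(s): %s",
                  paste(head(miss, 3), collapse = ", ")))
  }
  x <- as.matrix(newdata[, object$feature_names, drop = FALSE])
  storage.mode(x) <- "double"
  cls <- object$classes
  prob <- switch(object$family,
    logreg = {
      p <- predict(object$fit, x, type = "response")
      matrix(p, nrow = nrow(x),
             dimnames = list(NULL, dimnames(p)[[2]]))[, cls, drop = FALSE]
    },
    random_forest = predict(object$fit, as.data.frame(x))$predictions[, cls, drop = FALSE],
    decision_tree = predict(object$fit, as.data.frame(x), type = "prob")[, cls, drop = FALSE],
    gradient_boosting = {
      p <- predict(object$fit, xgboost::xgb.DMatrix(x))
      matrix(p, ncol = length(cls), byrow = TRUE, dimnames = list(NULL, cls))
    },
    naive_bayes = predict(object$fit, as.data.frame(x), type = "raw")[, cls, drop = FALSE],
    knn = {
      set.seed(object$seed)  # class::knn breaks distance ties at random
      pred <- class::knn(object$fit$x, x, object$fit$y,
                         k = object$fit$k, prob = TRUE)
      p <- matrix(0, nrow(x), length(cls), dimnames = list(NULL, cls))
      share <- attr(pred, "prob")
      for (i in seq_len(nrow(x))) {
        p[i, as.character(pred[i])] <- share[i]
        rest <- setdiff(cls, as.character(pred[i]))
        if (length(rest)) p[i, rest] <- (1 - share[i]) / length(rest)
      }
      p
    },
    svm = {
      p <- attr(predict(object$fit, x, probability = TRUE), "probabilities")
      p[, cls, drop = FALSE]
    }
  )
  if (type == "prob") return(prob)
  cls[max.col(prob, ties.method = "first")]
}

#' @export
print.snprex_model <- function(x, ...) {
  cat("<snprex_model>", x$family, "|", x$n_train, "training rows |",
      length(x$feature_names), "features | classes:",
      paste(x$classes, collapse = "/"), "\n")
  invisible(x)
}

#' @export
glance.snprex_model <- function(x, ...) {
  tibble(family = x$family, n_train = x$n_train,
         n_features = length(x$feature_names),
         n_classes = length(x$classes), seed = x$seed,
         weighted = !is.null(x$weights))
}

#' @export
tidy.snprex_model <- function(x, ...) {
  if (length(x$params) == 0L) {
    return(tibble(parameter = character(), value = character()))
  }
  tibble(parameter = names(x$params),
         value = map_chr(x$params, ~ paste(format(.x), collapse = ",")))
}
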