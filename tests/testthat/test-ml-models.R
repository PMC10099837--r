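test_that("class weights follow the inverse-frequency formula and conserve mass", {
  expect_equal(unclass(compute_class_weights(c(a = 10, b = 10))),
               c(a = 1, b = 1))

  w <- compute_class_weights(c(POSITIVE = 623, NEGATIVE = 86, NEUTRAL = 77))
  n <- 623 + 86 + 77
  expect_equal(unname(unclass(w)),
               c(n / (3 * 623), n / (3 * 86), n / (3 * 77)))
  expect_equal(round(unname(unclass(w)), 3), c(0.421, 3.047, 3.403))

  w2 <- unclass(compute_class_weights(c(x = 1, y = 999)))
  expect_equal(unname(w2), c(1000 / 2, 1000 / (2 * 999)))

  set.seed(7)
  for (i in 1:50) {
    k <- sample(2:6, 1)
    counts <- sample(1:500, k)
    names(counts) <- paste0("c", 1:k)
    w <- unclass(compute_class_weights(counts))
    expect_equal(sum(counts * w), sum(counts))
  }

  expect_error(compute_class_weights(c(a = 0, b = 5)), "positive")
})

test_that("vectorization is entity-blinded and leak-free", {
  c1 <- pair_corpus("rs429358 was associated with obesity here",
                    c(0L, 8L), c(29L, 36L))
  c2 <- pair_corpus("rs999999 was associated with obesity here",
                    c(0L, 8L), c(29L, 36L))
  v1 <- vectorize_candidates(c1, enumerate_candidates(c1))
  v2 <- vectorize_candidates(c2, enumerate_candidates(c2),
                             vocabulary = attr(v1, "vocabulary"))
  num <- setdiff(names(v1), c("doc_id", "sent_id", "snp_id", "phenotype_id"))
  expect_equal(v1[, num], v2[, num])

  # a vocabulary built on one split contains no other-split-only token
  tr <- pair_corpus("rs1 was associated with obesity", c(0L, 3L), c(24L, 31L))
  te <- pair_corpus("rs1 was correlated with zebrafish", c(0L, 3L), c(24L, 33L))
  vtr <- vectorize_candidates(tr, enumerate_candidates(tr))
  vocab <- attr(vtr, "vocabulary")
  expect_false(any(c("correlated", "zebrafish") %in% vocab))
  vte <- vectorize_candidates(te, enumerate_candidates(te), vocabulary = vocab)
  expect_equal(setdiff(names(vte), names(vtr)), character(0))

  # empty sentence: zero token bag, Boolean block still present
  ec <- pair_corpus("ab cd", c(0L, 2L), c(3L, 5L))
  ve <- vectorize_candidates(ec, enumerate_candidates(ec),
                             vocabulary = c("unseen"))
  expect_equal(sum(ve$tok_unseen), 0)
  expect_true(all(c("both_in_scope", "is_neutral_cand", "has_pvalue") %in%
                    names(ve)))
})

make_separable_data <- function(n = 60, classes = 2, seed = 1) {
  set.seed(seed)
  y <- rep(paste0("k", seq_len(classes)), length.out = n)
  x1 <- as.numeric(factor(y)) * 10 + rnorm(n, sd = 0.1)
  x2 <- rnorm(n)
  data.frame(f1 = x1, f2 = x2, label = y, stringsAsFactors = FALSE)
}

test_that("baseline families fit, are deterministic, and carry weights", {
  d <- make_separable_data(60, 2, seed = 2)
  for (fam in c("logreg", "random_forest", "decision_tree",
                "gradient_boosting", "naive_bayes", "knn", "svm")) {
    m1 <- train_baseline(d, family = fam, seed = 9)
    m2 <- train_baseline(d, family = fam, seed = 9)
    p1 <- predict(m1, d[, 1:2])
    p2 <- predict(m2, d[, 1:2])
    expect_identical(p1, p2)
    if (fam %in% c("decision_tree", "random_forest", "svm", "knn")) {
      expect_equal(mean(p1 == d$label), 1,
                   info = paste("separable accuracy for", fam))
    }
  }
  w <- compute_class_weights(table(d$label))
  mw <- train_baseline(d, family = "svm", weights = w, seed = 9)
  expect_true(mw$family == "svm")
  expect_error(train_baseline(d[d$label == "k1", ], family = "svm"),
               "two classes")
})

test_that("grid search evaluates the full cross product deterministically", {
  d <- make_separable_data(40, 2, seed = 3)
  single <- grid_search(d, family = "svm", grid = list(cost = 1), k = 2,
                        seed = 5)
  expect_equal(nrow(single$results), 1L)
  expect_equal(single$best_params$cost, 1)

  loggrid <- list(C = 10^(-3:3), penalty = c("l1", "l2"),
                  solver = c("liblinear", "newton-cg"))
  gs <- grid_search(d, family = "logreg", grid = loggrid, k = 2, seed = 5)
  expect_equal(nrow(gs$results), 7L * 2L * 2L)
  # returned point scores at least as well as every other point
  expect_true(all(gs$best_score >= gs$results$score))
  # separable data: a tree family reaches fold accuracy 1
  tg <- grid_search(d, family = "decision_tree", grid = list(cp = c(0.01)),
                    k = 2, scoring = "accuracy", seed = 5)
  expect_equal(tg$best_score, 1)
  expect_error(grid_search(d, grid = list(), k = 2), "non-empty")
})

test_that("a weighted bag-of-features baseline learns rule-consistent corpora", {
  g <- generate_corpus(generator_config(n_abstracts = 334, seed = 31))
  cand <- g$corpus$candidates
  n <- nrow(cand)
  expect_gte(n, 1000L)
  set.seed(31)
  idx <- sample(n) <= round(0.7 * n)
  tr_cand <- cand[idx, ]; te_cand <- cand[!idx, ]
  vtr <- vectorize_candidates(g$corpus, tr_cand, mode = "gold")
  vte <- vectorize_candidates(g$corpus, te_cand,
                              vocabulary = attr(vtr, "vocabulary"),
                              mode = "gold")
  feat <- setdiff(names(vtr), c("doc_id", "sent_id", "snp_id", "phenotype_id"))
  train <- data.frame(vtr[, feat], label = tr_cand$gold_label,
                      check.names = FALSE)
  w <- compute_class_weights(table(train$label))
  m <- train_baseline(train, family = "logreg", weights = w, seed = 31,
                      params = list(C = 10))
  pred <- predict(m, vte[, feat])
  f1 <- glance(prf_metrics(te_cand$gold_label, pred))$macro_f1
  expect_gte(f1, 0.8)
})

test_that("the CNN-LSTM architecture spec is declarative and round-trips", {
  spec <- build_cnn_lstm_spec(n_classes = 3)
  out_layer <- spec$layers[[length(spec$layers)]]
  expect_equal(out_layer$units, 3L)
  expect_equal(out_layer$activation, "softmax")
  types <- vapply(spec$layers, `[[`, "", "type")
  expect_equal(types, c("embedding", "conv1d", "max_pooling1d", "conv1d",
                        "max_pooling1d", "lstm", "dense", "dense"))

  expect_error(build_cnn_lstm_spec(n_classes = 1), "2")

  no_stop <- build_cnn_lstm_spec(early_stopping = NULL)
  expect_null(no_stop$early_stopping)

  back <- arch_spec_from_json(arch_spec_to_json(spec))
  expect_equal(back$layers, spec$layers)
  expect_equal(back$n_classes, spec$n_classes)
  expect_equal(back$early_stopping, spec$early_stopping)
})
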