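test_that("precision/recall/F1 reproduce hand-computed confusion matrices", {
  perfect <- prf_metrics(c("A", "B", "C"), c("A", "B", "C"))
  expect_equal(unname(perfect$macro), c(1, 1, 1))
  expect_equal(perfect$accuracy, 1)

  # all-one-class prediction on a balanced two-class set
  gold <- rep(c("P", "N"), each = 5)
  pred <- rep("P", 10)
  m <- prf_metrics(gold, pred)
  tab <- tidy(m)
  expect_equal(tab$recall[tab$class == "P"], 1)
  expect_equal(tab$recall[tab$class == "N"], 0)
  expect_equal(glance(m)$macro_f1, 1 / 3)
  expect_true(tab$zero_division[tab$class == "N"])

  # 3-class confusion [[5,0,0],[1,3,0],[0,0,1]]
  gold <- c(rep("a", 5), rep("b", 4), "c")
  pred <- c(rep("a", 5), "a", rep("b", 3), "c")
  m <- tidy(prf_metrics(gold, pred))
  expect_equal(m$precision, c(5 / 6, 1, 1))
  expect_equal(m$recall, c(1, 3 / 4, 1))
  expect_equal(m$support, c(5L, 4L, 1L))
})

test_that("metrics match the brute-force oracle on random label sets", {
  set.seed(17)
  for (i in 1:60) {
    k <- sample(2:4, 1)
    n <- sample(5:40, 1)
    gold <- sample(letters[1:k], n, replace = TRUE)
    pred <- sample(letters[1:k], n, replace = TRUE)
    m <- prf_metrics(gold, pred)
    o <- oracle_prf(gold, pred)
    expect_equal(tidy(m)$f1, unname(o$f1))
    expect_equal(tidy(m)$precision, unname(o$precision))
    expect_equal(glance(m)$macro_f1, o$macro_f1)
    expect_equal(glance(m)$weighted_f1, o$weighted_f1)
    expect_equal(glance(m)$accuracy, o$accuracy)
    # support-weighted recall is micro accuracy for single-label tasks
    expect_equal(glance(m)$weighted_recall, o$accuracy)
  }
})

test_that("Cohen's kappa matches its definition and properties", {
  x <- c("a", "b", "a", "c", "b", "a")
  expect_equal(cohen_kappa(x, x), 1)
  expect_warning(k <- cohen_kappa(rep("a", 5), rep("a", 5)), "undefined")
  expect_true(is.na(k))

  # chance-level construction: independent marginals, agreement = p_e
  a <- c(rep("x", 2), rep("y", 2))
  b <- c("x", "y", "x", "y")
  expect_equal(cohen_kappa(a, b), 0)

  # 2x2 paired-count table (30,10;10,50) style
  a <- c(rep("p", 40), rep("n", 60))
  b <- c(rep("p", 30), rep("n", 10), rep("p", 10), rep("n", 50))
  po <- (30 + 50) / 100
  pe <- 0.4 * 0.4 + 0.6 * 0.6
  expect_equal(cohen_kappa(a, b), (po - pe) / (1 - pe))

  set.seed(23)
  for (i in 1:40) {
    n <- sample(4:30, 1)
    a <- sample(c("u", "v", "w"), n, replace = TRUE)
    b <- sample(c("u", "v", "w"), n, replace = TRUE)
    if (length(unique(c(a, b))) == 1) next
    expect_equal(cohen_kappa(a, b), oracle_kappa(a, b))
    expect_equal(cohen_kappa(a, b), cohen_kappa(b, a))
  }
})

test_that("rank-based AUC behaves as a pairwise-win probability", {
  expect_equal(roc_auc(c(1, 2, 3, 10, 11), c(FALSE, FALSE, FALSE, TRUE, TRUE)), 1)
  expect_equal(roc_auc(rep(1, 10), rep(c(TRUE, FALSE), 5)), 0.5)
  expect_error(roc_auc(1:3, c(TRUE, TRUE, TRUE)), "negative")

  set.seed(29)
  for (i in 1:40) {
    n <- sample(6:30, 1)
    s <- rnorm(n); pos <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (!any(pos) || all(pos)) next
    expect_equal(roc_auc(s, pos), oracle_auc(s, pos))
    # invariance under strictly monotone transforms
    expect_equal(roc_auc(exp(s), pos), roc_auc(s, pos))
    expect_equal(roc_auc(rank(s), pos), roc_auc(s, pos))
  }

  # random scores concentrate near 0.5
  set.seed(31)
  s <- runif(10000); pos <- rep(c(TRUE, FALSE), 5000)
  expect_lt(abs(roc_auc(s, pos) - 0.5), 0.02)

  # independent cross-check against an established ROC implementation
  set.seed(33)
  s <- rnorm(200); pos <- sample(c(TRUE, FALSE), 200, replace = TRUE)
  expect_equal(roc_auc(s, pos),
               as.numeric(pROC::auc(pROC::roc(response = pos, predictor = s,
                                              quiet = TRUE, direction = "<"))))
})

test_that("k-fold splitting partitions and stratifies", {
  f <- kfold_split(10, k = 5, seed = 1)
  expect_equal(sort(unique(f)), 1:5)
  expect_equal(as.integer(table(f)), rep(2L, 5))

  labs <- c(rep("maj", 90), rep("min", 10))
  f <- kfold_split(100, k = 5, stratify = TRUE, labels = labs, seed = 2)
  for (i in 1:5) {
    expect_equal(sum(f == i & labs == "maj"), 18L)
    expect_equal(sum(f == i & labs == "min"), 2L)
  }
  expect_identical(f, kfold_split(100, k = 5, stratify = TRUE, labels = labs,
                                  seed = 2))
  expect_error(kfold_split(10, k = 5, stratify = TRUE,
                           labels = c(rep("a", 8), "b", "b")),
               "infeasible")
})

test_that("abstract-level aggregation follows its voting policies", {
  one <- tibble::tibble(doc_id = "d1", snp = "rs1", phenotype = "obesity",
                        label = "NEGATIVE")
  expect_equal(aggregate_to_abstract(one)$label, "NEGATIVE")

  two <- tibble::tibble(doc_id = "d1", snp = "rs1", phenotype = "obesity",
                        label = c("POSITIVE", "NEGATIVE"))
  expect_equal(aggregate_to_abstract(two, "any-positive")$label, "POSITIVE")
  expect_equal(aggregate_to_abstract(two, "majority")$label, "NEGATIVE")

  set.seed(37)
  for (i in 1:30) {
    n <- sample(1:8, 1)
    labs <- sample(c("POSITIVE", "NEGATIVE", "NEUTRAL"), n, replace = TRUE)
    d <- tibble::tibble(doc_id = "d", snp = "s", phenotype = "p", label = labs)
    # brute-force majority vote with NEGATIVE tie-break
    tab <- table(labs)
    winners <- names(tab)[tab == max(tab)]
    want <- if (length(winners) > 1) "NEGATIVE" else winners
    expect_equal(aggregate_to_abstract(d, "majority")$label, want)
    want_any <- if (any(labs == "POSITIVE")) "POSITIVE"
                else if (any(labs == "NEGATIVE")) "NEGATIVE" else "NEUTRAL"
    expect_equal(aggregate_to_abstract(d, "any-positive")$label, want_any)
  }
})

test_that("paired significance tests handle regular and degenerate cases", {
  same <- paired_significance(rep(1, 8), rep(1, 8), test = "sign")
  expect_equal(same$p_value, 1)
  expect_true(same$degenerate)

  sweep <- paired_significance(rep(1, 10), rep(0, 10), test = "sign")
  expect_equal(sweep$p_value, 2 * 0.5^10)
  expect_false(sweep$degenerate)

  set.seed(41)
  for (i in 1:20) {
    a <- sample(0:1, 12, replace = TRUE)
    b <- sample(0:1, 12, replace = TRUE)
    wins <- sum(a > b); losses <- sum(a < b)
    if (wins + losses == 0) next
    expect_equal(paired_significance(a, b, test = "sign")$p_value,
                 oracle_sign_p(wins, losses))
  }

  flat <- paired_significance(c(1, 2, 3), c(0, 1, 2), test = "t")
  expect_true(flat$degenerate)  # zero variance of differences
  tt <- paired_significance(c(0.9, 0.8, 0.95, 0.85), c(0.7, 0.75, 0.8, 0.72),
                            test = "t")
  expect_false(tt$degenerate)
  expect_equal(tt$p_value,
               t.test(c(0.9, 0.8, 0.95, 0.85), c(0.7, 0.75, 0.8, 0.72),
                      paired = TRUE)$p.value)
})
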