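# Shared fixtures and independent brute-force oracles for the test suite.
# Oracles are deliberately naive (loops and counting) so they stay
# independent of the implementation paths they check.

# A small hand-built corpus: one sentence, two SNPs, one phenotype.
two_snp_corpus <- function() {
  text <- "Both rs429358 and rs7412 were associated with obesity risk"
  snp_corpus(
    sentences = tibble::tibble(doc_id = "d1", sent_id = "s1", text = text,
                               is_key = TRUE),
    entities = tibble::tibble(
      doc_id = "d1", sent_id = "s1",
      mention_id = c("e1", "e2", "e3"),
      kind = c("SNP", "SNP", "PHENOTYPE"),
      start = c(5L, 18L, 46L), end = c(13L, 24L, 53L)
    )
  )
}

# Sentence corpus with one SNP, one phenotype at given spans.
pair_corpus <- function(text, snp_span, phen_span, gold_label = NULL,
                        annotated = FALSE, negations = NULL) {
  cand <- if (is.null(gold_label)) NULL else tibble::tibble(
    doc_id = "d1", sent_id = "s1", snp_id = "e1", phenotype_id = "e2",
    gold_label = gold_label, gold_certainty = "NONE")
  snp_corpus(
    sentences = tibble::tibble(doc_id = "d1", sent_id = "s1", text = text,
                               is_key = TRUE),
    entities = tibble::tibble(
      doc_id = "d1", sent_id = "s1", mention_id = c("e1", "e2"),
      kind = c("SNP", "PHENOTYPE"),
      start = c(snp_span[1], phen_span[1]),
      end = c(snp_span[2], phen_span[2])
    ),
    candidates = if (is.null(cand)) snprex:::empty_candidates() else cand,
    negations = if (is.null(negations)) snprex:::empty_negations() else negations,
    annotated = annotated
  )
}

# --- brute-force metric oracles ---------------------------------------

oracle_prf <- function(gold, pred) {
  classes <- sort(union(gold, pred))
  per <- lapply(classes, function(cl) {
    tp <- sum(gold == cl & pred == cl)
    fp <- sum(gold != cl & pred == cl)
    fn <- sum(gold == cl & pred != cl)
    p <- if (tp + fp == 0) 0 else tp / (tp + fp)
    r <- if (tp + fn == 0) 0 else tp / (tp + fn)
    f <- if (p + r == 0) 0 else 2 * p * r / (p + r)
    c(p = p, r = r, f = f, n = sum(gold == cl))
  })
  m <- do.call(rbind, per)
  list(classes = classes, precision = m[, "p"], recall = m[, "r"],
       f1 = m[, "f"], support = m[, "n"],
       macro_f1 = mean(m[, "f"]),
       weighted_f1 = sum(m[, "f"] * m[, "n"] / sum(m[, "n"])),
       accuracy = mean(gold == pred))
}

oracle_kappa <- function(a, b) {
  classes <- union(a, b)
  n <- length(a)
  po <- sum(a == b) / n
  pe <- 0
  for (cl in classes) pe <- pe + (sum(a == cl) / n) * (sum(b == cl) / n)
  (po - pe) / (1 - pe)
}

# AUC by direct pair counting (ties half).
oracle_auc <- function(scores, pos) {
  s1 <- scores[pos]; s0 <- scores[!pos]
  tot <- 0
  for (i in seq_along(s1)) {
    tot <- tot + sum(s1[i] > s0) + 0.5 * sum(s1[i] == s0)
  }
  tot / (length(s1) * length(s0))
}

# Exact two-sided sign-test p-value by binomial enumeration.
oracle_sign_p <- function(wins, losses) {
  m <- wins + losses
  probs <- stats::dbinom(0:m, m, 0.5)
  sum(probs[probs <= stats::dbinom(wins, m, 0.5) + 1e-12])
}

# Literal evaluation of the association decision formula.
oracle_nnb_label <- function(b_in, l_in, r_in, neutral) {
  if (neutral) return("NEUTRAL")
  if (b_in || l_in || r_in) return("NEGATIVE")
  "POSITIVE"
}
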