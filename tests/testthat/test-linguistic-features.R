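test_that("tokenization yields ordered spans that reconstruct the input", {
  expect_equal(nrow(tokenize("")), 0L)
  expect_equal(tokenize("rs1051730 variant")$token, c("rs1051730", "variant"))

  set.seed(9)
  alphabet <- c(letters, "0", "5", " ", " ", ",", ".", "(", ")", ";")
  for (i in 1:25) {
    s <- paste(sample(alphabet, sample(5:60, 1), replace = TRUE),
               collapse = "")
    toks <- tokenize(s)
    if (nrow(toks) > 0) {
      # surfaces equal the substrings at their spans, in order
      expect_equal(toks$token,
                   substring(s, toks$start + 1, toks$end))
      expect_true(all(diff(toks$start) > 0))
      expect_true(all(toks$end > toks$start))
      expect_true(all(toks$start >= 0 & toks$end <= nchar(s)))
    }
    # concatenated surfaces = input minus separator characters
    kept <- gsub("[^[:alnum:]'._-]", "", s)
    # separators stripped from token boundaries too
    expect_equal(gsub("[^[:alnum:]]", "", paste(toks$token, collapse = "")),
                 gsub("[^[:alnum:]]", "", s))
  }
})

test_that("heuristic negation finds cues and clause-bounded scopes", {
  corp <- demo_sentence_corpus(
    "There were no associations between APOE polymorphisms and serum HDL-C, APO-CIII, and triglycerides")
  ev <- detect_negation(corp)
  expect_equal(nrow(ev), 1L)
  expect_equal(tolower(ev$cue_text), "no")
  expect_equal(ev$scope_end, nchar(corp$sentences$text))

  expect_equal(nrow(detect_negation(demo_sentence_corpus(
    "a perfectly assertive sentence"))), 0L)

  text <- "X but not Y, although Z"
  ev <- detect_negation(demo_sentence_corpus(text))
  expect_equal(nrow(ev), 1L)
  # scope of "not" starts at Y and must end before "although"
  expect_equal(ev$scope_start, as.integer(regexpr("Y", text)) - 1L)
  expect_equal(ev$scope_end, as.integer(regexpr("although", text)) - 1L)
})

test_that("gold-mode extraction returns annotations and rejects unannotated corpora", {
  g <- generate_corpus(generator_config(n_abstracts = 6, seed = 2))
  expect_identical(detect_negation(g$corpus, mode = "gold"),
                   g$corpus$negations)
  expect_identical(detect_modality_markers(g$corpus, mode = "gold"),
                   g$corpus$modality)
  un <- demo_sentence_corpus("nothing annotated here")
  expect_error(detect_negation(un, mode = "gold"), "gold")
  expect_error(detect_modality_markers(un, mode = "gold"), "gold")
})

test_that("heuristic negation scopes never cross a clause connector", {
  g <- generate_corpus(generator_config(n_abstracts = 60, seed = 13))
  ev <- detect_negation(g$corpus, mode = "heuristic")
  cc <- detect_clause_connectors(g$corpus)
  for (i in seq_len(nrow(ev))) {
    inside <- cc$start[cc$doc_id == ev$doc_id[i] &
                         cc$sent_id == ev$sent_id[i]]
    crossing <- inside[inside >= ev$cue_end[i]]
    if (length(crossing)) {
      expect_lte(ev$scope_end[i], min(crossing))
    }
  }
})

test_that("positional features follow span arithmetic", {
  # hedged negation: SNP left of scope, phenotype inside -> one-left-one-in
  text <- "Moreover, the rs1051730 variant may not merely operate as a marker for dependence or heaviness of smoking"
  ev <- snprex:::heuristic_negation(text)
  snp <- c(14L, 23L)
  phen <- c(regexpr("dependence", text) - 1L, nchar(text))
  f <- positional_features(snp, phen, ev)
  expect_true(f$one_left_one_in)
  expect_false(any(unlist(f[c("both_in_scope", "one_right_one_in",
                              "both_left", "both_right",
                              "one_left_one_right")])))

  # no events: all six false
  f0 <- positional_features(c(0L, 3L), c(5L, 9L),
                            tibble::tibble(scope_start = integer(),
                                           scope_end = integer()))
  expect_false(any(unlist(f0[setdiff(names(f0), "is_neutral_cand")])))

  # both inside one scope
  fb <- positional_features(c(10L, 15L), c(20L, 25L),
                            tibble::tibble(scope_start = 5L, scope_end = 30L))
  expect_true(fb$both_in_scope)
  expect_equal(sum(unlist(fb[1:6])), 1L)
})

test_that("the six positional possibilities partition every configuration", {
  set.seed(31)
  for (i in 1:300) {
    len <- 100L
    sc <- sort(sample(0:len, 2))
    mk_span <- function() {
      a <- sample(0:(len - 1), 1); c(a, a + sample(1:10, 1))
    }
    ev <- tibble::tibble(scope_start = sc[1], scope_end = sc[2])
    f <- positional_features(mk_span(), mk_span(), ev)
    expect_equal(sum(unlist(f[1:6])), 1L)  # exactly one possibility holds
  }
})

test_that("neutral detection is rule-ordered and entity-blinded", {
  cfg <- snprex_config()
  ents <- tibble::tibble(kind = c("SNP", "PHENOTYPE"),
                         start = c(13L, 36L), end = c(19L, 43L))
  hit <- detect_neutral("We genotyped rs7412 in patients with obesity", ents, cfg)
  expect_true(hit$is_neutral)
  expect_equal(hit$rule_id, "genotyped")

  # no study-setup pattern
  miss <- detect_neutral("rs7412 was significantly associated with obesity",
                         tibble::tibble(kind = c("SNP", "PHENOTYPE"),
                                        start = c(0L, 41L), end = c(6L, 48L)),
                         cfg)
  expect_false(miss$is_neutral)

  # empty rule set never fires
  none <- snprex_config(neutral_rules = character())
  expect_false(detect_neutral("We genotyped rs7412 in obesity", NULL, none)$is_neutral)

  # invariance to the entity surfaces
  for (snp in c("rs1", "rs999999", "rs1800629")) {
    s <- sprintf("We genotyped %s in patients with obesity", snp)
    e <- tibble::tibble(kind = c("SNP", "PHENOTYPE"),
                        start = c(13L, 13L + nchar(snp) + 18L),
                        end = c(13L + nchar(snp), 13L + nchar(snp) + 25L))
    expect_true(detect_neutral(s, e, cfg)$is_neutral)
  }
})

test_that("connector detection distinguishes concessives", {
  cc <- detect_clause_connectors(demo_sentence_corpus(
    "although rs4680 was tested, smoking increased"))
  expect_equal(nrow(cc), 1L)
  expect_true(cc$is_concessive)
  expect_equal(nrow(detect_clause_connectors(demo_sentence_corpus(
    "X and Y"))), 0L)
  multi <- detect_clause_connectors(demo_sentence_corpus(
    "even though X held, Y rose because Z"))
  expect_equal(multi$text, c("even though", "because"))
  expect_equal(multi$is_concessive, c(TRUE, FALSE))
})

test_that("modality markers are matched as whole tokens", {
  mm <- detect_modality_markers(demo_sentence_corpus(
    "rs1051730 may not merely operate as a marker"))
  expect_equal(mm$text, "may")
  expect_equal(nrow(detect_modality_markers(demo_sentence_corpus(
    "this is assertive and final"))), 0L)
  empty_lex <- snprex_config(modality_markers = character())
  expect_equal(nrow(detect_modality_markers(demo_sentence_corpus(
    "it may possibly seem likely"), empty_lex)), 0L)
})

test_that("p-value mentions parse across typographies", {
  expect_equal(nrow(extract_pvalues(demo_sentence_corpus("no p-value here"))), 0L)

  pv <- extract_pvalues(demo_sentence_corpus("significant (P < 0.001) overall"))
  expect_equal(pv$comparator, "<")
  expect_equal(pv$value, 0.001)

  sci <- extract_pvalues(demo_sentence_corpus(
    "association held (p = 3.2 × 10−5) in replication"))
  expect_equal(sci$comparator, "=")
  expect_equal(sci$value, 3.2e-5)

  more <- extract_pvalues(demo_sentence_corpus(
    "first p-value = 0.04 then p ≤ 1e-3 then p > 0.5"))
  expect_equal(more$comparator, c("=", "<=", ">"))
  expect_equal(more$value, c(0.04, 0.001, 0.5))
})
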