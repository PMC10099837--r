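test_that("an empty corpus round-trips through XML", {
  corp <- snp_corpus(
    sentences = tibble::tibble(doc_id = character(), sent_id = character(),
                               text = character(), is_key = logical()))
  path <- withr::local_tempfile(fileext = ".xml")
  write_corpus(corp, path)
  back <- read_corpus(path)
  expect_equal(nrow(back$documents), 0L)
  expect_equal(nrow(back$sentences), 0L)
})

test_that("write/read round-trip restores the object and is byte-stable", {
  g <- generate_corpus(generator_config(n_abstracts = 12, seed = 11))
  p1 <- withr::local_tempfile(fileext = ".xml")
  p2 <- withr::local_tempfile(fileext = ".xml")
  write_corpus(g$corpus, p1)
  write_corpus(g$corpus, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
  back <- read_corpus(p1)
  expect_equal(back$sentences, g$corpus$sentences)
  expect_equal(back$entities, g$corpus$entities)
  expect_equal(back$candidates, g$corpus$candidates)
  expect_equal(back$negations, g$corpus$negations)
  expect_equal(back$modality, g$corpus$modality)
  expect_identical(back$annotated, TRUE)
  # and writing the re-read corpus reproduces the same bytes
  p3 <- withr::local_tempfile(fileext = ".xml")
  write_corpus(back, p3)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p3, "raw", file.size(p3)))
})

test_that("malformed XML and invalid spans are rejected informatively", {
  bad <- withr::local_tempfile(fileext = ".xml")
  writeLines("<snprex-corpus><abstract id='d1'>", bad)
  expect_error(read_corpus(bad))

  oob <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<snprex-corpus split="unsplit" provenance="" annotated="false">',
    '<abstract id="d1"><sentence id="s1" key="false"><text>short</text>',
    '<entity id="e1" kind="SNP" start="0" end="99"/>',
    '</sentence></abstract></snprex-corpus>'), oob)
  expect_error(read_corpus(oob), "s1")
})

test_that("unparseable candidate labels default to UNLABELED/NONE", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<snprex-corpus split="unsplit" provenance="" annotated="false">',
    '<abstract id="d1"><sentence id="s1" key="false">',
    '<text>rs7412 and obesity</text>',
    '<entity id="e1" kind="SNP" start="0" end="6"/>',
    '<entity id="e2" kind="PHENOTYPE" start="11" end="18"/>',
    '<candidate snp="e1" phenotype="e2" label="mystery" certainty="odd"/>',
    '</sentence></abstract></snprex-corpus>'), path)
  corp <- read_corpus(path)
  expect_identical(corp$candidates$gold_label, "UNLABELED")
  expect_identical(corp$candidates$gold_certainty, "NONE")
})

test_that("candidate enumeration forms the ordered SNP x phenotype cross product", {
  cands <- enumerate_candidates(two_snp_corpus())
  expect_equal(nrow(cands), 2L)
  expect_equal(cands$snp_id, c("e1", "e2"))

  no_snp <- demo_sentence_corpus("plain sentence with nothing annotated")
  expect_equal(nrow(enumerate_candidates(no_snp)), 0L)
})

test_that("enumeration matches a brute-force pairing oracle on random sentences", {
  set.seed(42)
  for (rep in 1:20) {
    n_snp <- sample(0:4, 1)
    n_phen <- sample(0:3, 1)
    n <- n_snp + n_phen
    text <- paste(rep("wwwww", max(n, 1) * 2), collapse = " ")
    starts <- seq(0L, by = 12L, length.out = max(n, 1))[seq_len(n)]
    if (n > 0) {
      ord <- sample(n)
      ents <- tibble::tibble(
        doc_id = "d1", sent_id = "s1",
        mention_id = paste0("e", seq_len(n)),
        kind = c(rep("SNP", n_snp), rep("PHENOTYPE", n_phen))[ord],
        start = starts, end = starts + 5L)
    } else {
      ents <- snprex:::empty_entities()
    }
    corp <- snp_corpus(
      sentences = tibble::tibble(doc_id = "d1", sent_id = "s1", text = text,
                                 is_key = FALSE),
      entities = ents)
    cands <- enumerate_candidates(corp)
    expect_equal(nrow(cands), n_snp * n_phen)
    if (nrow(cands) > 0) {
      # brute force: all pairs, ordered by span starts
      snps <- ents[ents$kind == "SNP", ]
      phens <- ents[ents$kind == "PHENOTYPE", ]
      exp_snp <- rep(snps$mention_id[order(snps$start)], each = nrow(phens))
      exp_phen <- rep(phens$mention_id[order(phens$start)],
                      times = nrow(snps))
      expect_equal(cands$snp_id, exp_snp)
      expect_equal(cands$phenotype_id, exp_phen)
    }
  }
})

test_that("JSONL sentences load into an unannotated corpus", {
  path <- withr::local_tempfile(fileext = ".jsonl")
  writeLines(c(
    '{"doc_id":"d1","sent_id":"s1","text":"rs7412 linked to obesity","entities":[{"id":"e1","kind":"SNP","start":0,"end":6},{"id":"e2","kind":"PHENOTYPE","start":17,"end":24}]}',
    '{"text":"no entities here"}'
  ), path)
  corp <- read_sentences_jsonl(path)
  expect_equal(nrow(corp$sentences), 2L)
  expect_equal(nrow(corp$entities), 2L)
  expect_false(corp$annotated)
  expect_equal(corp$entities$surface, c("rs7412", "obesity"))
})

test_that("corpus statistics match generator bookkeeping and handle empties", {
  empty <- snp_corpus(
    sentences = tibble::tibble(doc_id = character(), sent_id = character(),
                               text = character(), is_key = logical()))
  st <- corpus_statistics(empty)
  expect_equal(st$n_candidates, 0L)
  expect_equal(st$n_documents, 0L)
  expect_true(is.na(st$mean_tokens_per_sentence))

  g <- generate_corpus(generator_config(n_abstracts = 40, seed = 3))
  st <- corpus_statistics(g$corpus)
  expect_equal(st$n_positive, sum(g$ledger$label == "POSITIVE"))
  expect_equal(st$n_negative, sum(g$ledger$label == "NEGATIVE"))
  expect_equal(st$n_neutral, sum(g$ledger$label == "NEUTRAL"))
  expect_equal(st$n_weak, sum(g$ledger$certainty == "WEAK"))
  expect_equal(st$n_strong, sum(g$ledger$certainty == "STRONG"))
  expect_equal(st$n_candidates_with_negation_cue, sum(g$ledger$has_cue))
  expect_equal(st$n_candidates_with_connector, sum(g$ledger$has_connector))
  expect_equal(st$mean_snps_per_sentence, 1)
  expect_equal(st$mean_phenotypes_per_sentence, 1)
})

test_that("planted negation-cue fraction honours the configured rate", {
  # all-positive corpus so the extra-cue rate is the only cue source
  cfg <- generator_config(
    n_abstracts = 334, candidates_per_abstract = 3L,
    label_proportions = c(POSITIVE = 1, NEGATIVE = 0, NEUTRAL = 0),
    negation_cue_rate = 0.2, seed = 5)
  g <- generate_corpus(cfg)
  n <- nrow(g$ledger)
  expect_gte(n, 1000L)
  frac_bounds <- stats::qbinom(c(0.005, 0.995), n, 0.2) / n
  frac <- mean(g$ledger$has_cue)
  expect_gte(frac, frac_bounds[1])
  expect_lte(frac, frac_bounds[2])
})

test_that("the lenient importer accepts alternative element spellings", {
  path <- withr::local_tempfile(fileext = ".xml")
  writeLines(paste0(
    '<corpus><Document id="D1"><Sentence id="S1" text="rs4680 affects smoking">',
    '<SNP id="m1" start="0" end="6"/>',
    '<Phenotype id="m2" start="15" end="22"/>',
    '<Pair e1="m1" e2="m2" association="positive" confidence="high"/>',
    '</Sentence></Document></corpus>'), path)
  corp <- read_corpus(path, dialect = "snpphena")
  expect_equal(nrow(corp$sentences), 1L)
  expect_equal(corp$entities$kind, c("SNP", "PHENOTYPE"))
  expect_equal(corp$candidates$gold_label, "POSITIVE")
  expect_equal(corp$candidates$gold_certainty, "STRONG")
})
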