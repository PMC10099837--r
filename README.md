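# snprex

Ranked SNP–phenotype association extraction from biomedical text.

Genome-wide association studies report relations between single
nucleotide polymorphisms (SNPs, named by rs-identifiers) and phenotypes
(smoking, obesity, hypertension, ...). Mining those reports from abstracts
is a sentence-level relation extraction task with two traps that generic
classifiers fall into: **negation** ("there were *no* associations
between...") inverts an association, and **neutral candidates**
(study-setup sentences such as "we genotyped rs429358 in patients with
obesity") assert nothing at all, so negation must *not* flip them.
Beyond the bare label, the strength of a positively reported association
matters: a hedged claim ("may be associated") is weaker evidence than one
anchored by `P < 0.001`.

`snprex` is an R toolkit for this task, aimed at BioNLP practitioners and
anyone curating SNP–phenotype evidence from literature. It provides:

* **A rule-based association classifier (NNB).** Candidates are
  (SNP mention, phenotype mention) pairs within a sentence. Seven Boolean
  features drive the decision: six mutually exclusive positions of the
  two mentions relative to a negation scope (both inside; one left / one
  inside; one right / one inside; both left; both right; one on each
  side), plus a neutral-candidate flag from entity-blinded regular-
  expression rules. The association is labelled by

  `assoc = ¬(BothInScope ∨ OneLeftOneIn ∨ OneRightOneIn) ∧ ¬IsNeutral`

  with three-way output POSITIVE / NEGATIVE / NEUTRAL and a binary view
  that merges NEGATIVE and NEUTRAL.
* **A certainty grader (MBS).** Positive associations are graded weak /
  moderate / strong by a margin classifier (linear SVM) over modality
  markers (hedges), reported p-values and clause connectors, with
  concessive connectors ("although", "whereas", ...) treated as
  certainty-weakening signals.
* **Shallow ML baselines** (logistic regression, random forest, decision
  tree, gradient boosting, naive Bayes, k-NN, SVM) over entity-blinded
  bag-of-features vectors, with inverse-frequency class weights
  `w_c = N / (K · n_c)` for imbalanced labels and seeded grid search.
* **An evaluation harness**: per-class and macro/weighted P/R/F1, Cohen's
  kappa, rank-based ROC/AUC, stratified k-fold splitting, abstract-level
  label aggregation, paired t and exact sign tests.
* **Corpus I/O and a synthetic corpus generator**: a documented XML
  dialect (plus a lenient importer for externally produced files), JSONL
  sentence input, and a seeded template-based generator that emits fully
  annotated corpora together with a ground-truth ledger for every planted
  cue, scope, hedge, connector and p-value.

Everything is tidyverse-native: functions take and return tibbles,
results have `tidy()` / `glance()` methods, and `autoplot()` /
`plot_roc()` give ggplot2 figures.

## Worked example

Classify one negated sentence:

```r
library(snprex)

corp <- demo_sentence_corpus(
  "There were no associations between rs429358 and serum HDL-C",
  entities = tibble::tibble(mention_id = c("e1", "e2"),
                            kind = c("SNP", "PHENOTYPE"),
                            start = c(35L, 48L), end = c(43L, 59L)))
nnb_classify(corp, candidates = enumerate_candidates(corp))
#> # A tibble: 1 × 14
#>   doc_id sent_id snp_id phenotype_id both_in_scope one_left_one_in ...
#> 1 d1     s1      e1     e2           TRUE          FALSE           ...
#> #   label = "NEGATIVE", binary_view = "FALSE_ASSOC"
```

Both mentions fall inside the scope of the cue "no", so the association
is inverted to NEGATIVE.

Generate an annotated synthetic corpus and score the rule pipeline
against the generator's ledger:

```r
g <- generate_corpus(generator_config(n_abstracts = 40, seed = 7))
g$corpus
#> <snp_corpus> unsplit split
#>   abstracts:  40
#>   sentences:  120
#>   entities:   240 (120 SNP, 120 phenotype)
#>   candidates: 120
#>   gold negation/modality annotation: TRUE

pred <- nnb_classify(g$corpus, mode = "heuristic")
glance(prf_metrics(g$ledger$label, pred$label))
#> # A tibble: 1 × 11
#>   averaging precision recall    f1 macro_precision macro_recall macro_f1 ...
#> 1 macro             1      1     1               1            1        1
```

Macro P/R/F1 of 1.0 is expected here: the generator's templates are
written within the competence of the heuristic extractors, so a perfect
score is the designed parameter-recovery check, not a claim about real
abstracts.

Class weights for a published-style imbalanced training split
(623 positive, 86 negative, 77 neutral candidates):

```r
compute_class_weights(c(POSITIVE = 623, NEGATIVE = 86, NEUTRAL = 77))
#> POSITIVE NEGATIVE  NEUTRAL
#>   0.4205   3.0465   3.4026
```

A command-line front end for shell use ships in `inst/cli/snprex.R`
(subcommands `simulate`, `extract`, `stats`, `certainty`, `evaluate`).

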