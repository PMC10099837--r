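---
title: "Mining ranked SNP-phenotype associations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining ranked SNP-phenotype associations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(snprex)
```

## The task and the data model

A genome-wide association study abstract reports, sentence by sentence,
whether particular single nucleotide polymorphisms (SNPs) relate to
phenotypes. The unit of prediction in `snprex` is the **association
candidate**: one (SNP mention, phenotype mention) pair inside one
sentence, labelled POSITIVE, NEGATIVE or NEUTRAL, and — for positives
only — graded WEAK, MODERATE or STRONG in certainty. A corpus is a set
of abstracts whose sentences carry entity mentions, negation events
(cue plus scope), and modality markers, all as 0-based half-open
character intervals on the NFC-normalized sentence string; that offset
convention makes `substr(text, start + 1, end)` recover every annotated
surface unambiguously, and the constructor validates it.

Three label classes rather than the usual two matter because of how
negation interacts with them. A NEGATIVE candidate asserts the *absence*
of an association; a NEUTRAL candidate asserts nothing (typically
study-setup language: "we genotyped X in patients with Y"). Negation
inverts asserted associations but leaves neutral ones untouched, so a
pipeline that skips neutral detection will flip sentences that never
claimed anything.

## The rule-based association classifier

For each candidate and each negation event, exactly one of six
positional configurations holds: both mentions inside the scope, one
left (outside) and one inside, one right and one inside, both left, both
right, or one on each side. "Inside" means the mention span *intersects*
the scope span — intersection rather than containment, because mentions
in noisy annotation can straddle a scope boundary. Mentions outside the
scope are assigned left or right by their start offset. These six
possibilities partition all configurations (property-tested over random
spans), and only the first three invert an association: in each of them
at least one of the two mentions sits under the negation.

With several negation events in one sentence, the candidate-level
feature for each configuration is the disjunction over events: any one
inverting configuration suffices to invert the association. The decision
is then

> NEUTRAL if the neutral detector fires; otherwise NEGATIVE if
> (both-inside or one-left-one-inside or one-right-one-inside) holds for
> any event; otherwise POSITIVE.

Only three of the six positional features enter the formula; the other
three are carried because they complete the exhaustive partition, are
useful inputs to the ML baselines, and make the feature vector
self-documenting. A binary view (TRUE_ASSOC vs FALSE_ASSOC, merging
NEGATIVE and NEUTRAL) supports two-class evaluation, where neutral
candidates conventionally join the negative class.

The neutral detector is deliberately simple: ordered regular-expression
rules applied to the sentence after **entity blinding** (SNP and
phenotype surfaces replaced by `[SNP]`/`[PHENOTYPE]` tags), so the
decision cannot depend on which rs-number or phenotype happens to be
mentioned. The shipped default rules target study-setup verbs
(genotyped, examined, investigated, recruited, enrolled, measured, "aim
of this study"); they are configuration, not code (`snprex_config()`,
JSON-round-trippable via `read_config()`/`write_config()`), because any
learned rule set for a particular corpus should be swappable without
touching the package.

### Negation scopes

Gold scope annotations are used when a corpus carries them. For
unannotated text a heuristic is provided: cues are whole-token,
case-insensitive lexicon matches, and the scope runs from the token
after the cue to the sentence end or the first clause connector after
the cue, whichever is nearer. Bounding scopes at clause connectors is
the classic lightweight approximation of syntactic scope; the package
deliberately does not attempt parse-based or learned scope resolution.
Both modes share one interface (`mode = "gold"`/`"heuristic"`), and
requesting gold mode on an unannotated corpus is an error rather than a
silent fallback.

## Grading the certainty of positive associations

The certainty grader uses three signal families, extracted by regular
expressions and lexicon matching:

* **modality markers** (hedges: may, might, suggest, likely, ...) — one
  indicator per lexicon entry plus a count;
* **reported p-values** — parsed across the usual typographies,
  including scientific notation with the typographic multiplication sign
  and minus ("3.2 × 10−5"); a mention counts as significant when its
  comparator bounds the value below `alpha` (0.05 by default, a
  conventional choice that is configurable because it is a modelling
  assumption, not a fact of the text);
* **clause connectors**, with concessive connectors (although, whereas,
  but, ...) flagged separately, since a concession typically weakens the
  reported claim.

A linear-kernel SVM over this feature vector (the p-value encoded as
−log10 with an explicit absence indicator) is trained on labelled
positives, optionally with inverse-frequency class weights. Feature rows
with no signal at all fall back to the training majority class, with a
message — a deliberate, visible policy for degenerate input rather than
an arbitrary margin decision on an all-zero vector. Prediction refuses a
feature table whose schema (column set and order) differs from the
training schema.

## Class weighting, baselines and grid search

Imbalanced label distributions are handled by inverse-frequency weights
`w_c = N/(K · n_c)` (`compute_class_weights()`), the standard weighting
used with a categorical cross-entropy loss. Among the possible readings
of "weights based on the ratio of samples per class" this form was
chosen because it reduces to unit weights on balanced data and conserves
total mass (`Σ n_c w_c = N`), both of which are asserted in tests.

The shallow baselines (`train_baseline()`) are thin, seeded wrappers
over standard fitters — glmnet, ranger, rpart, xgboost, e1071, class —
over an entity-blinded bag-of-tokens representation concatenated with
the positional and certainty feature blocks. The vocabulary is built
from the training split only and must be passed explicitly for any
other split; a test asserts no test-only token can leak in.
`grid_search()` sweeps a full parameter cross product under stratified
k-fold CV with ties broken toward the first-listed point. The canonical
logistic-regression grid crosses seven powers of ten for the
regularization strength C with penalty l1/l2 and a `solver` axis; the
solver axis is inert under the single glmnet backend but preserved so
published grids transcribe one-to-one (glmnet's `alpha`/`lambda`
subsume it).

A deep CNN-LSTM architecture (embedding, two convolution + max-pooling
blocks, an LSTM layer, dense and softmax output, early stopping) is
represented as a declarative, JSON-round-trippable specification
(`build_cnn_lstm_spec()`); the core package performs no neural training
and requires no accelerator — the spec is the contract for an optional
plugin.

## Evaluation harness

`prf_metrics()` computes per-class P/R/F1 from the confusion matrix with
zero-division cases reported as 0 and flagged. Both macro and weighted
averages are always computed and the headline mode is carried in the
result, because on imbalanced three-class data the two can diverge
widely and published tables often omit which was used; macro is the
default. Cohen's kappa uses marginal-product expected agreement; AUC is
the rank-based (Mann-Whitney) formulation with ties counting one half,
invariant under monotone transforms. Stratified k-fold splitting deals
shuffled class members round-robin, keeping per-fold class counts within
one instance of exact proportionality. Abstract-level evaluation
aggregates candidate labels per (document, SNP, phenotype) group by an
any-positive or majority policy, with majority ties resolved to
NEGATIVE (the conservative choice: an unresolved conflict is not
evidence of an association). For system comparison, the paired t-test
operates on per-fold scores and the exact binomial sign test on
per-instance wins with ties dropped; all-tie and zero-variance cases are
flagged as degenerate instead of being reported as ordinary results.
Every metric is checked against brute-force counting oracles on random
small instances.

## The synthetic corpus generator

`generate_corpus()` emits template-based English sentences with one
candidate each, plus a **ledger** recording every planted label, grade,
cue, scope, hedge, connector and p-value. The generator is the package's
test bed: its defaults encode the summary statistics published for the
corpus this method family was developed on — label mix 811:325:180,
certainty mix 515:124:233, 18.5% extra negation-cue rate, 63.8%
connector rate, 87/895 concessive fraction. Those published tables are
internally inconsistent (the label counts sum past the candidate total,
and the overall cue rate is below the negative-class share), so the
rates are treated as sampling targets and the ledger — not any printed
table — is the ground truth of a generated corpus. Two resolutions
follow from the semantics: every NEGATIVE sentence carries a cue whose
scope covers at least one mention (a negative reading requires one), and
the configured cue rate applies as the probability of an *extra*,
non-inverting cue on positive and neutral sentences. The p-value mention
rate (0.4 by default) is not published anywhere; it was fixed once at a
value typical of association-reporting sentences and is configurable.

Realization respects the rule semantics by construction: neutral
sentences instantiate study-setup templates that match the shipped
neutral rules; strong positives always carry a significant p-value and
no hedge; weak positives carry a hedge and/or a concessive clause;
moderate positives carry neither, at most a non-significant p-value.
Concessive connectors are planted only where the sampled grade permits
them (weak positives, negatives, neutrals), so the realized concessive
fraction can sit above or below the configured target depending on the
grade mix — the ledger records what actually happened. Gold negation and
modality annotations are derived from the assembled sentence by the
package's own heuristic extractors — the templates are written within
their competence — and the generator *asserts* at build time that the
rule pipeline reproduces every planted label and grade, aborting rather
than emitting an inconsistent corpus. Generation is fully reproducible
from the seed, and serialization is canonical, so one configuration
yields byte-identical XML.

What passing tests on this generator do and do not show: they are
parameter-recovery checks — the extractors recover exactly what was
planted, the rule classifier scores 1.0 against the ledger, and the
certainty SVM recovers the deterministic grading rule (cross-validated
macro-F1 around 0.93–0.95 at 500 positives, approaching 1 as n grows;
the residual errors are the all-absent moderate vectors that the
majority fallback sends elsewhere). Real abstracts have unseen cue
vocabulary, parse-dependent scopes, discourse-level context and
annotation noise that templates do not emulate, so these scores are
upper bounds on pipeline consistency, not estimates of performance on
real text.

## Problem sizes and numerical choices

The shipped tests and the acceptance script use corpora of roughly
120–1000 candidates, 500 positives for certainty recovery with 5-fold
CV, 1000-instance metric-oracle sweeps, and 100 round-trip corpora —
sizes at which every stochastic check sits comfortably inside its 99%
sampling band while the full suite runs in a few minutes on one core.
Tie-breaking is deterministic throughout (first grid point, first
matching neutral rule, first maximum in probability ties, NEGATIVE on
majority ties); k-NN's random distance-tie resolution is pinned by the
stored seed. Offsets are integers end to end; the only floating-point
surface is model fitting and the −log10 p-value encoding, which clamps
at 1e-300 to avoid infinities on underflowing scientific notation.
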