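#' Construct an annotated SNP-phenotype corpus
#'
#' A corpus is a set of abstracts, each a sequence of sentences annotated
#' with entity mentions (SNPs and phenotypes), negation events (cue plus
#' scope), modality markers, and labelled association candidates.  It is
#' stored as a list of tidy tables sharing `doc_id`/`sent_id` keys, so every
#' component can be manipulated with ordinary dplyr verbs.
#'
#' All character offsets are 0-based half-open intervals on the sentence
#' text (assumed NFC-normalized), so `substr(text, start + 1, end)` recovers
#' the annotated surface.
#'
#' @param sentences Tibble with columns `doc_id`, `sent_id`, `text` and
#'   optionally `is_key` (logical, default `FALSE`).
#' @param entities Tibble with columns `doc_id`, `sent_id`, `mention_id`,
#'   `kind` (`"SNP"` or `"PHENOTYPE"`), `start`, `end`, and optionally
#'   `surface` (filled in from the sentence text when missing).
#' @param candidates Optional tibble of labelled association candidates:
#'   `doc_id`, `sent_id`, `snp_id`, `phenotype_id`, `gold_label` (one of
#'   `"POSITIVE"`, `"NEGATIVE"`, `"NEUTRAL"`, `"UNLABELED"`), and
#'   `gold_certainty` (`"WEAK"`, `"MODERATE"`, `"STRONG"`, `"NONE"`).
#' @param negations Optional tibble of gold negation events: `doc_id`,
#'   `sent_id`, `cue_start`, `cue_end`, `cue_text`, `scope_start`,
#'   `scope_end`, `source` (`"GOLD"` or `"HEURISTIC"`).
#' @param modality Optional tibble of gold modality markers: `doc_id`,
#'   `sent_id`, `start`, `end`, `text`, `source`.
#' @param split One of `"train"`, `"test"`, `"unsplit"`.
#' @param provenance Free-text metadata string.
#' @param annotated Logical: whether the corpus carries gold negation and
#'   modality annotation (an annotated corpus may still have sentences with
#'   zero events).  Controls what GOLD-mode extractors accept.
#'
#' @return An object of class `snp_corpus`.
#' @seealso [read_corpus()], [write_corpus()], [enumerate_candidates()],
#'   [generate_corpus()]
#' @export
snp_corpus <- function(sentences,
                       entities = empty_entities(),
                       candidates = empty_candidates(),
                       negations = empty_negations(),
                       modality = empty_modality(),
                       split = "unsplit",
                       provenance = "",
                       annotated = FALSE) {
  sentences <- as_tibble(sentences)
  if (!"is_key" %in% names(sentences)) sentences$is_key <- FALSE
  entities <- as_tibble(entities)
  candidates <- as_tibble(candidates)
  negations <- as_tibble(negations)
  modality <- as_tibble(modality)
  if (!"gold_certainty" %in% names(candidates) && nrow(candidates) > 0) {
    candidates$gold_certainty <- "NONE"
  }
  if (nrow(entities) > 0 && !"surface" %in% names(entities)) {
    entities <- left_join(entities,
                          select(sentences, "doc_id", "sent_id", "text"),
                          by = c("doc_id", "sent_id"))
    entities$surface <- substring(entities$text, entities$start + 1L, entities$end)
    entities$text <- NULL
  }
  x <- structure(
    list(
      documents = distinct(select(sentences, "doc_id")),
      sentences = select(sentences, "doc_id", "sent_id", "text", "is_key"),
      entities = entities[, names(empty_entities())],
      candidates = candidates[, names(empty_candidates())],
      negations = negations[, names(empty_negations())],
      modality = modality[, names(empty_modality())],
      split = match.arg(split, c("train", "test", "unsplit")),
      provenance = provenance,
      annotated = isTRUE(annotated)
    ),
    class = "snp_corpus"
  )
  validate_corpus(x)
  x
}

empty_entities <- function() {
  tibble(doc_id = character(), sent_id = character(), mention_id = character(),
         kind = character(), start = integer(), end = integer(),
         surface = character())
}

empty_candidates <- function() {
  tibble(doc_id = character(), sent_id = character(), snp_id = character(),
         phenotype_id = character(), gold_label = character(),
         gold_certainty = character())
}

empty_negations <- function() {
  tibble(doc_id = character(), sent_id = character(),
         cue_start = integer(), cue_end = integer(), cue_text = character(),
         scope_start = integer(), scope_end = integer(), source = character())
}

empty_modality <- function() {
  tibble(doc_id = character(), sent_id = character(), start = integer(),
         end = integer(), text = character(), source = character())
}

#' Validate corpus invariants
#'
#' Checks identifier uniqueness, span bounds, surface/substring agreement,
#' candidate entity kinds, label vocabularies, and the rule that a certainty
#' grade is only defined for POSITIVE candidates.  Called by the
#' constructor, the XML reader and the writer; errors name the offending
#' sentence.
#'
#' @param corpus An `snp_corpus`.
#' @return `corpus`, invisibly, on success; otherwise an error.
#' @export
validate_corpus <- function(corpus) {
  stopifnot(inherits(corpus, "snp_corpus"))
  s <- corpus$sentences
  if (anyDuplicated(paste(s$doc_id, s$sent_id))) {
    abort("sentence identifiers must be unique within a document.")
  }
  key <- function(d, sid) paste(d, sid, sep = "\r")
  slen <- setNames(nchar(s$text), key(s$doc_id, s$sent_id))

  check_spans <- function(tab, cols, what) {
    if (nrow(tab) == 0L) return(invisible())
    k <- key(tab$doc_id, tab$sent_id)
    if (any(is.na(slen[k]))) {
      abort(sprintf("%s refers to unknown sentence id.", what))
    }
    for (cc in cols) {
      lo <- tab[[cc[1]]]; hi <- tab[[cc[2]]]
      bad <- lo < 0L | hi > slen[k] | lo > hi
      if (any(bad)) {
        abort(sprintf("%s span out of bounds in sentence '%s' (doc '%s').",
                      what, tab$sent_id[which(bad)[1]], tab$doc_id[which(bad)[1]]))
      }
    }
  }
  check_spans(corpus$entities, list(c("start", "end")), "entity")
  check_spans(corpus$negations,
              list(c("cue_start", "cue_end"), c("scope_start", "scope_end")),
              "negation")
  check_spans(corpus$modality, list(c("start", "end")), "modality")

  e <- corpus$entities
  if (nrow(e) > 0L) {
    if (anyDuplicated(paste(e$doc_id, e$sent_id, e$mention_id))) {
      abort("entity mention identifiers must be unique within a sentence.")
    }
    if (!all(e$kind %in% c("SNP", "PHENOTYPE"))) {
      abort("entity kind must be 'SNP' or 'PHENOTYPE'.")
    }
    txt <- setNames(s$text, key(s$doc_id, s$sent_id))[key(e$doc_id, e$sent_id)]
    got <- substring(txt, e$start + 1L, e$end)
    bad <- got != e$surface
    if (any(bad)) {
      i <- which(bad)[1]
      abort(sprintf(
        "entity surface mismatch in sentence '%s': span yields '%s', surface is '%s'.",
        e$sent_id[i], got[i], e$surface[i]))
    }
  }

  cd <- corpus$candidates
  if (nrow(cd) > 0L) {
    if (!all(cd$gold_label %in% c("POSITIVE", "NEGATIVE", "NEUTRAL", "UNLABELED"))) {
      abort("gold_label must be POSITIVE, NEGATIVE, NEUTRAL or UNLABELED.")
    }
    if (!all(cd$gold_certainty %in% c("WEAK", "MODERATE", "STRONG", "NONE"))) {
      abort("gold_certainty must be WEAK, MODERATE, STRONG or NONE.")
    }
    if (any(cd$gold_certainty != "NONE" & cd$gold_label != "POSITIVE")) {
      abort("a certainty grade is only defined for POSITIVE candidates.")
    }
    ek <- key(e$doc_id, e$sent_id)
    kind_of <- setNames(e$kind, paste(ek, e$mention_id))
    ks <- paste(key(cd$doc_id, cd$sent_id), cd$snp_id)
    kp <- paste(key(cd$doc_id, cd$sent_id), cd$phenotype_id)
    if (any(is.na(kind_of[ks])) || any(is.na(kind_of[kp]))) {
      abort("candidate refers to an unknown entity mention.")
    }
    if (any(kind_of[ks] != "SNP") || any(kind_of[kp] != "PHENOTYPE")) {
      abort("candidate snp_id must point at an SNP mention and phenotype_id at a PHENOTYPE mention.")
    }
  }
  invisible(corpus)
}

#' @export
print.snp_corpus <- function(x, ...) {
  cat("<snp_corpus>", x$split, "split\n")
  cat("  abstracts: ", nrow(x$documents), "\n")
  cat("  sentences: ", nrow(x$sentences), "\n")
  cat("  entities:  ", nrow(x$entities),
      sprintf("(%d SNP, %d phenotype)",
              sum(x$entities$kind == "SNP"),
              sum(x$entities$kind == "PHENOTYPE")), "\n")
  cat("  candidates:", nrow(x$candidates), "\n")
  cat("  gold negation/modality annotation:", x$annotated, "\n")
  invisible(x)
}

#' Enumerate SNP-phenotype association candidates
#'
#' Forms one candidate per (SNP mention, phenotype mention) pair within each
#' sentence — the cross product of the two entity kinds — ordered by SNP
#' span start, then phenotype span start.  Gold labels and certainty grades
#' are attached from the corpus candidate table where a matching pair is
#' annotated; unannotated pairs get `UNLABELED`/`NONE`.
#'
#' @param corpus An `snp_corpus`.
#' @return A tibble with columns `doc_id`, `sent_id`, `snp_id`,
#'   `phenotype_id`, `gold_label`, `gold_certainty`; zero rows when no
#'   sentence contains both entity kinds.
#' @export
enumerate_candidates <- function(corpus) {
  stopifnot(inherits(corpus, "snp_corpus"))
  e <- corpus$entities
  if (nrow(e) == 0L) return(empty_candidates())
  snps <- filter(e, .data$kind == "SNP")
  phens <- filter(e, .data$kind == "PHENOTYPE")
  pairs <- dplyr::inner_join(
    select(snps, "doc_id", "sent_id", snp_id = "mention_id", snp_start = "start"),
    select(phens, "doc_id", "sent_id", phenotype_id = "mention_id",
           phen_start = "start"),
    by = c("doc_id", "sent_id"),
    relationship = "many-to-many"
  )
  if (nrow(pairs) == 0L) return(empty_candidates())
  sent_order <- mutate(select(corpus$sentences, "doc_id", "sent_id"),
                       .ord = row_number())
  pairs <- left_join(pairs, sent_order, by = c("doc_id", "sent_id"))
  pairs <- arrange(pairs, .data$.ord, .data$snp_start, .data$phen_start)
  out <- left_join(
    select(pairs, "doc_id", "sent_id", "snp_id", "phenotype_id"),
    corpus$candidates,
    by = c("doc_id", "sent_id", "snp_id", "phenotype_id")
  )
  out$gold_label[is.na(out$gold_label)] <- "UNLABELED"
  out$gold_certainty[is.na(out$gold_certainty)] <- "NONE"
  out
}

# Internal: fetch one sentence row + its annotations as plain lists.
sentence_record <- function(corpus, doc_id, sent_id) {
  s <- filter(corpus$sentences, .data$doc_id == !!doc_id, .data$sent_id == !!sent_id)
  if (nrow(s) != 1L) abort(sprintf("unknown sentence '%s' in doc '%s'.", sent_id, doc_id))
  list(
    text = s$text,
    is_key = s$is_key,
    entities = filter(corpus$entities, .data$doc_id == !!doc_id, .data$sent_id == !!sent_id),
    negations = filter(corpus$negations, .data$doc_id == !!doc_id, .data$sent_id == !!sent_id),
    modality = filter(corpus$modality, .data$doc_id == !!doc_id, .data$sent_id == !!sent_id)
  )
}
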