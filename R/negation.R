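#' Detect negation cues and scopes
#'
#' In `"gold"` mode the annotated negation events of the corpus are returned
#' unchanged (an error is raised for a corpus without gold annotation).  In
#' `"heuristic"` mode cues are whole-token, case-insensitive matches against
#' the cue lexicon, and each cue's scope runs from the token after the cue
#' to the sentence end or to the first clause connector after the cue,
#' whichever is nearer — so a heuristic scope never crosses a clause
#' connector.
#'
#' @param corpus An [snp_corpus()].
#' @param config A [snprex_config()].
#' @param mode `"heuristic"` or `"gold"`.
#' @return A tibble of negation events with columns `doc_id`, `sent_id`,
#'   `cue_start`, `cue_end`, `cue_text`, `scope_start`, `scope_end`,
#'   `source`.
#' @examples
#' corp <- demo_sentence_corpus(
#'   "There were no associations between rs429358 and obesity")
#' detect_negation(corp)
#' @export
detect_negation <- function(corpus, config = snprex_config(),
                            mode = c("heuristic", "gold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "snp_corpus"))
  if (mode == "gold") {
    if (!corpus$annotated) {
      abort("gold mode requested but the corpus carries no gold negation annotation.")
    }
    return(corpus$negations)
  }
  s <- corpus$sentences
  out <- pmap(list(s$doc_id, s$sent_id, s$text), function(d, sid, text) {
    ev <- heuristic_negation(text, config)
    if (nrow(ev) == 0L) return(NULL)
    bind_cols(tibble(doc_id = d, sent_id = sid), ev)
  })
  out <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0L) return(empty_negations())
  out
}

# Per-sentence heuristic negation worker.
heuristic_negation <- function(text, config = snprex_config()) {
  tokens <- tokenize(text)
  empty <- tibble(cue_start = integer(), cue_end = integer(),
                  cue_text = character(), scope_start = integer(),
                  scope_end = integer(), source = character())
  if (nrow(tokens) == 0L) return(empty)
  surf <- token_surfaces(tokens)
  hits <- which(surf %in% config$negation_cues)
  if (length(hits) == 0L) return(empty)
  connectors <- match_phrases(text, tokens, config$connectors)
  len <- nchar(text)
  rows <- map(hits, function(i) {
    scope_start <- if (i < nrow(tokens)) tokens$start[i + 1L] else tokens$end[i]
    after <- connectors$start[connectors$start >= tokens$end[i]]
    scope_end <- if (length(after)) min(len, min(after)) else len
    scope_end <- max(scope_end, scope_start)
    tibble(
      cue_start = tokens$start[i], cue_end = tokens$end[i],
      cue_text = tokens$token[i],
      scope_start = scope_start, scope_end = scope_end,
      source = "HEURISTIC"
    )
  })
  list_rbind(rows)
}

#' Detect clause connectors
#'
#' Whole-token (phrase-aware, longest-match-first) lexicon matching of
#' clause connectors; a match is flagged concessive when it belongs to the
#' configured concessive subset (contrastive connectors such as "although"
#' that weaken the certainty of a reported association).
#'
#' @inheritParams detect_negation
#' @return A tibble with columns `doc_id`, `sent_id`, `start`, `end`,
#'   `text`, `is_concessive`.
#' @examples
#' corp <- demo_sentence_corpus("although rs4680 was tested, smoking rose")
#' detect_clause_connectors(corp)
#' @export
detect_clause_connectors <- function(corpus, config = snprex_config()) {
  stopifnot(inherits(corpus, "snp_corpus"))
  s <- corpus$sentences
  out <- pmap(list(s$doc_id, s$sent_id, s$text), function(d, sid, text) {
    cc <- sentence_connectors(text, config)
    if (nrow(cc) == 0L) return(NULL)
    bind_cols(tibble(doc_id = d, sent_id = sid), cc)
  })
  out <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0L) {
    return(tibble(doc_id = character(), sent_id = character(),
                  start = integer(), end = integer(), text = character(),
                  is_concessive = logical()))
  }
  out
}

sentence_connectors <- function(text, config = snprex_config()) {
  m <- match_phrases(text, tokenize(text), config$connectors)
  m$is_concessive <- tolower(m$text) %in% config$concessive
  m
}

#' Build a one-sentence demonstration corpus
#'
#' Convenience for examples and interactive exploration: wraps a bare
#' sentence (with optional entity spans) into a minimal [snp_corpus()].
#'
#' @param text Sentence text.
#' @param entities Optional tibble with `mention_id`, `kind`, `start`, `end`.
#' @return An [snp_corpus()] with one document and one sentence.
#' @export
demo_sentence_corpus <- function(text, entities = NULL) {
  ent <- if (is.null(entities)) {
    empty_entities()
  } else {
    bind_cols(tibble(doc_id = "d1", sent_id = "s1"), as_tibble(entities))
  }
  snp_corpus(
    sentences = tibble(doc_id = "d1", sent_id = "s1", text = text, is_key = TRUE),
    entities = ent
  )
}
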