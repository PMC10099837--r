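#' Rule-based association prediction from positional features (NNB)
#'
#' The negation/neutral-based decision rule.  A candidate predicted neutral
#' is labelled `NEUTRAL` regardless of any negation (negation does not
#' change the status of a neutral candidate).  Otherwise the association is
#' inverted — labelled `NEGATIVE` — exactly when at least one of the three
#' inverting scope positions holds (both mentions inside a negation scope,
#' or one inside with the other out on either side); any other feature
#' combination yields `POSITIVE`.  As a Boolean formula on the binary view,
#'
#' \deqn{assoc = \neg(\mathrm{both\_in} \lor \mathrm{one\_left\_one\_in}
#'   \lor \mathrm{one\_right\_one\_in}) \land \neg \mathrm{is\_neutral}}
#'
#' The binary view collapses `NEGATIVE` and `NEUTRAL` into `FALSE_ASSOC`,
#' mirroring two-class evaluation where neutral candidates join the
#' negative class.
#'
#' @param features A tibble of positional feature rows as produced by
#'   [positional_features()] (any number of rows).
#' @return A tibble with columns `label` (`POSITIVE`/`NEGATIVE`/`NEUTRAL`)
#'   and `binary_view` (`TRUE_ASSOC`/`FALSE_ASSOC`), one row per input row.
#' @examples
#' nnb_predict(positional_features(c(0L, 9L), c(20L, 27L),
#'   tibble::tibble(scope_start = 15L, scope_end = 30L)))
#' @export
nnb_predict <- function(features) {
  features <- as_tibble(features)
  inverting <- features$both_in_scope | features$one_left_one_in |
    features$one_right_one_in
  label <- ifelse(features$is_neutral_cand, "NEUTRAL",
                  ifelse(inverting, "NEGATIVE", "POSITIVE"))
  tibble(label = label,
         binary_view = ifelse(label == "POSITIVE", "TRUE_ASSOC", "FALSE_ASSOC"))
}

#' Classify association candidates with the NNB pipeline
#'
#' Runs the full rule pipeline for every candidate of a corpus: negation
#' events (gold annotations or the heuristic cue/scope detector), the
#' neutral-candidate rules on the entity-blinded sentence, the seven
#' positional Booleans, and the [nnb_predict()] decision rule.  The output
#' records the fired features and any matched neutral rule alongside the
#' prediction, so individual decisions can be audited.
#'
#' @param corpus An [snp_corpus()].
#' @param config A [snprex_config()].
#' @param mode `"heuristic"` or `"gold"` (source of negation events).
#' @param candidates Optional candidate tibble (defaults to the corpus's
#'   annotated candidates, or to [enumerate_candidates()] when none exist).
#' @return A tibble with the candidate keys, the seven feature columns,
#'   `neutral_rule`, `label` and `binary_view`.
#' @export
nnb_classify <- function(corpus, config = snprex_config(),
                         mode = c("heuristic", "gold"), candidates = NULL) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "snp_corpus"))
  if (is.null(candidates)) {
    candidates <- if (nrow(corpus$candidates) > 0L) corpus$candidates
                  else enumerate_candidates(corpus)
  }
  if (nrow(candidates) == 0L) {
    return(bind_cols(empty_candidates()[0, 1:4],
                     positional_features(c(0L, 0L), c(0L, 0L),
                                         empty_negations())[0, ],
                     tibble(neutral_rule = character(), label = character(),
                            binary_view = character())))
  }
  events_all <- detect_negation(corpus, config, mode)
  ent <- corpus$entities
  rows <- map(seq_len(nrow(candidates)), function(i) {
    cd <- candidates[i, ]
    sent <- filter(corpus$sentences, .data$doc_id == cd$doc_id,
                   .data$sent_id == cd$sent_id)
    if (nrow(sent) != 1L) {
      abort(sprintf("candidate refers to unknown sentence '%s'.", cd$sent_id))
    }
    es <- filter(ent, .data$doc_id == cd$doc_id, .data$sent_id == cd$sent_id)
    snp <- filter(es, .data$mention_id == cd$snp_id)
    phen <- filter(es, .data$mention_id == cd$phenotype_id)
    if (nrow(snp) != 1L || nrow(phen) != 1L) {
      abort(sprintf("candidate in sentence '%s' refers to missing mentions.",
                    cd$sent_id))
    }
    ev <- filter(events_all, .data$doc_id == cd$doc_id,
                 .data$sent_id == cd$sent_id)
    neu <- detect_neutral(sent$text, es, config)
    feats <- positional_features(c(snp$start, snp$end), c(phen$start, phen$end),
                                 ev, neu$is_neutral)
    bind_cols(
      select(cd, "doc_id", "sent_id", "snp_id", "phenotype_id"),
      feats,
      tibble(neutral_rule = neu$rule_id),
      nnb_predict(feats)
    )
  })
  list_rbind(rows)
}
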