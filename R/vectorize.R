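#' Bag-of-features vectorization of association candidates
#'
#' Represents each candidate as an entity-blinded bag of lowercased tokens
#' over a fixed vocabulary, concatenated with the seven positional Booleans
#' and the certainty feature block (markers, p-value, connectors).  Entity
#' blinding replaces the SNP and phenotype surfaces with placeholder tags
#' before tokenization, so two sentences differing only in their mention
#' strings vectorize identically.  To avoid train/test leakage the
#' vocabulary is built from the supplied data only when `vocabulary` is
#' `NULL` (i.e. on the training split) and must be passed explicitly for
#' any other split.
#'
#' @param corpus An [snp_corpus()].
#' @param candidates Candidate tibble (defaults to the corpus candidates or
#'   [enumerate_candidates()]).
#' @param vocabulary Character vector of token types, or `NULL` to build it
#'   from this data.
#' @param config A [snprex_config()].
#' @param mode Negation/marker source for the Boolean blocks.
#' @return A tibble of candidate keys plus numeric feature columns
#'   (`tok_*`, positional and certainty blocks), with the vocabulary in
#'   `attr(, "vocabulary")`.
#' @export
vectorize_candidates <- function(corpus, candidates = NULL, vocabulary = NULL,
                                 config = snprex_config(),
                                 mode = c("heuristic", "gold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "snp_corpus"))
  if (is.null(candidates)) {
    candidates <- if (nrow(corpus$candidates) > 0L) corpus$candidates
                  else enumerate_candidates(corpus)
  }
  sent_tokens <- function(d, sid) {
    rec <- sentence_record(corpus, d, sid)
    tolower(tokenize(blind_entities(rec$text, rec$entities))$token)
  }
  key <- unique(paste(candidates$doc_id, candidates$sent_id, sep = "\r"))
  tok_by_sent <- setNames(
    map(key, function(k) {
      p <- strsplit(k, "\r", fixed = TRUE)[[1]]
      sent_tokens(p[1], p[2])
    }),
    key
  )
  if (is.null(vocabulary)) {
    vocabulary <- sort(unique(unlist(tok_by_sent)))
  }
  nnb <- nnb_classify(corpus, config, mode, candidates = candidates)
  cand_pos <- candidates
  cand_pos$gold_label <- NULL; cand_pos$gold_certainty <- NULL
  cert <- mbs_features(corpus, candidates = cand_pos, config = config,
                       mode = mode)

  bag <- matrix(0, nrow = nrow(candidates), ncol = length(vocabulary),
                dimnames = list(NULL, paste0("tok_", vocabulary)))
  for (i in seq_len(nrow(candidates))) {
    toks <- tok_by_sent[[paste(candidates$doc_id[i], candidates$sent_id[i],
                               sep = "\r")]]
    tab <- table(toks[toks %in% vocabulary])
    if (length(tab)) bag[i, paste0("tok_", names(tab))] <- as.integer(tab)
  }
  feat_cols <- c("both_in_scope", "one_left_one_in", "one_right_one_in",
                 "both_left", "both_right", "one_left_one_right",
                 "is_neutral_cand")
  out <- bind_cols(
    select(candidates, "doc_id", "sent_id", "snp_id", "phenotype_id"),
    as_tibble(bag),
    as_tibble(lapply(nnb[, feat_cols], as.numeric)),
    as_tibble(as.data.frame(mbs_feature_matrix(cert)))
  )
  attr(out, "vocabulary") <- vocabulary
  out
}
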