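#' Descriptive corpus statistics
#'
#' Computes the descriptive statistics used to characterise an annotated
#' SNP-phenotype corpus: document/sentence/mention/candidate counts, label
#' and certainty distributions, how many candidates carry a negation cue or
#' a clause connector, the concessive-clause percentage (reported to one
#' decimal place as `100 * n_concessive / n_connector_analyzed`, with both
#' denominator and numerator kept alongside), and mean tokens, SNPs and
#' phenotypes per sentence.  Counts are taken from the data, never from any
#' published summary table.
#'
#' Negation cues and connectors come from the gold annotation when the
#' corpus is annotated, otherwise from the heuristic extractors.
#' Connector-analyzed instances are connector *occurrences* in candidate
#' sentences, so a sentence with two connectors contributes two instances.
#'
#' @param corpus An [snp_corpus()]; mean statistics require at least one
#'   sentence (an empty corpus yields zero counts and `NA` means).
#' @param config A [snprex_config()].
#' @return A one-row tibble of class `snprex_corpus_stats` with count,
#'   percentage and mean columns; the per-cue negation frequency table is
#'   available via [negation_cue_frequencies()] and the long form via
#'   `tidy()`.
#' @export
corpus_statistics <- function(corpus, config = snprex_config()) {
  stopifnot(inherits(corpus, "snp_corpus"))
  s <- corpus$sentences
  e <- corpus$entities
  cand <- if (nrow(corpus$candidates) > 0L) corpus$candidates
          else enumerate_candidates(corpus)

  negs <- if (corpus$annotated) corpus$negations
          else detect_negation(corpus, config, "heuristic")
  conns <- detect_clause_connectors(corpus, config)

  skey <- function(tab) paste(tab$doc_id, tab$sent_id, sep = "\r")
  cand_sent <- unique(skey(cand))
  neg_sent <- unique(skey(negs))
  conn_in_cand <- conns[skey(conns) %in% cand_sent, , drop = FALSE]

  lab_counts <- table(factor(cand$gold_label,
                             levels = c("POSITIVE", "NEGATIVE", "NEUTRAL",
                                        "UNLABELED")))
  cert_counts <- table(factor(cand$gold_certainty,
                              levels = c("WEAK", "MODERATE", "STRONG", "NONE")))

  n_tok <- if (nrow(s)) map_int(s$text, ~ nrow(tokenize(.x))) else integer()
  ents_per_sent <- function(kind) {
    if (nrow(s) == 0L) return(NA_real_)
    tab <- table(factor(skey(e[e$kind == kind, ]), levels = skey(s)))
    mean(as.integer(tab))
  }

  n_conn_analyzed <- nrow(conn_in_cand)
  n_concessive <- sum(conn_in_cand$is_concessive)
  concessive_pct <- if (n_conn_analyzed > 0) {
    round(100 * n_concessive / n_conn_analyzed, 1)
  } else NA_real_

  cue_freq <- if (nrow(negs)) {
    count(mutate(negs, cue = tolower(.data$cue_text)), .data$cue,
          sort = TRUE, name = "n")
  } else tibble(cue = character(), n = integer())

  out <- tibble(
    n_documents = nrow(corpus$documents),
    n_sentences = nrow(s),
    n_key_sentences = sum(s$is_key),
    n_snp_mentions = sum(e$kind == "SNP"),
    n_phenotype_mentions = sum(e$kind == "PHENOTYPE"),
    n_candidates = nrow(cand),
    n_positive = as.integer(lab_counts[["POSITIVE"]]),
    n_negative = as.integer(lab_counts[["NEGATIVE"]]),
    n_neutral = as.integer(lab_counts[["NEUTRAL"]]),
    n_unlabeled = as.integer(lab_counts[["UNLABELED"]]),
    n_weak = as.integer(cert_counts[["WEAK"]]),
    n_moderate = as.integer(cert_counts[["MODERATE"]]),
    n_strong = as.integer(cert_counts[["STRONG"]]),
    n_candidates_with_negation_cue = sum(cand_sent %in% neg_sent),
    n_candidates_with_connector =
      length(intersect(cand_sent, unique(skey(conns)))),
    n_connector_analyzed = n_conn_analyzed,
    n_concessive = n_concessive,
    concessive_pct = concessive_pct,
    negation_sentence_pct = if (nrow(cand)) {
      round(100 * sum(cand_sent %in% neg_sent) / length(cand_sent), 1)
    } else NA_real_,
    mean_tokens_per_sentence = if (length(n_tok)) mean(n_tok) else NA_real_,
    mean_snps_per_sentence = ents_per_sent("SNP"),
    mean_phenotypes_per_sentence = ents_per_sent("PHENOTYPE")
  )
  structure(out, cue_freq = cue_freq,
            class = c("snprex_corpus_stats", class(out)))
}

#' @rdname corpus_statistics
#' @param stats A `snprex_corpus_stats` object.
#' @export
negation_cue_frequencies <- function(stats) {
  attr(stats, "cue_freq")
}

#' Tidy corpus statistics to long form
#'
#' @param x A `snprex_corpus_stats` object.
#' @param ... Unused.
#' @return A tibble with columns `statistic`, `value` — convenient for CSV
#'   export.
#' @export
tidy.snprex_corpus_stats <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(unclass(x)), dplyr::everything(),
                      names_to = "statistic", values_to = "value")
}
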