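#' Detect modality markers (hedges)
#'
#' Modality markers are words through which an author signals uncertainty
#' about a stated association ("may", "suggest", "likely", ...).  In
#' `"gold"` mode the corpus annotations are returned unchanged (error if the
#' corpus is unannotated); in `"heuristic"` mode markers are whole-token,
#' case-insensitive matches against the marker lexicon.
#'
#' @inheritParams detect_negation
#' @return A tibble with columns `doc_id`, `sent_id`, `start`, `end`,
#'   `text`, `source`.
#' @examples
#' corp <- demo_sentence_corpus("rs1051730 may not merely operate as a marker")
#' detect_modality_markers(corp)
#' @export
detect_modality_markers <- function(corpus, config = snprex_config(),
                                    mode = c("heuristic", "gold")) {
  mode <- match.arg(mode)
  stopifnot(inherits(corpus, "snp_corpus"))
  if (mode == "gold") {
    if (!corpus$annotated) {
      abort("gold mode requested but the corpus carries no gold modality annotation.")
    }
    return(corpus$modality)
  }
  s <- corpus$sentences
  out <- pmap(list(s$doc_id, s$sent_id, s$text), function(d, sid, text) {
    mm <- sentence_modality(text, config)
    if (nrow(mm) == 0L) return(NULL)
    bind_cols(tibble(doc_id = d, sent_id = sid), mm)
  })
  out <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0L) return(empty_modality())
  out
}

sentence_modality <- function(text, config = snprex_config()) {
  tokens <- tokenize(text)
  if (nrow(tokens) == 0L || length(config$modality_markers) == 0L) {
    return(tibble(start = integer(), end = integer(), text = character(),
                  source = character()))
  }
  hits <- which(token_surfaces(tokens) %in% config$modality_markers)
  tibble(start = tokens$start[hits], end = tokens$end[hits],
         text = tokens$token[hits],
         source = rep("HEURISTIC", length(hits)))
}
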