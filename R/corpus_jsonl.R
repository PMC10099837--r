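#' Read sentences with entity offsets from JSONL
#'
#' One JSON object per line, each describing a sentence:
#'
#' ```
#' {"doc_id": "d1", "sent_id": "s1", "text": "...",
#'  "entities": [{"id": "e1", "kind": "SNP", "start": 0, "end": 9}],
#'  "is_key": true}
#' ```
#'
#' `doc_id`/`sent_id` default to line-derived identifiers and entity ids to
#' `e1, e2, ...` within each sentence; gold annotations are not carried by
#' this format, so the result is an unannotated corpus ready for
#' HEURISTIC-mode extraction.
#'
#' @param path Path to a JSONL file.
#' @return An [snp_corpus()].
#' @export
read_sentences_jsonl <- function(path) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  sents <- list(); ents <- list()
  for (i in seq_along(lines)) {
    rec <- jsonlite::fromJSON(lines[i], simplifyVector = FALSE)
    d_id <- rec$doc_id %||% sprintf("d%d", i)
    s_id <- rec$sent_id %||% sprintf("s%d", i)
    sents[[i]] <- tibble(doc_id = d_id, sent_id = s_id,
                         text = rec$text %||% "",
                         is_key = isTRUE(rec$is_key))
    es <- rec$entities %||% list()
    for (j in seq_along(es)) {
      e <- es[[j]]
      ents[[length(ents) + 1L]] <- tibble(
        doc_id = d_id, sent_id = s_id,
        mention_id = e$id %||% sprintf("e%d", j),
        kind = toupper(e$kind), start = as.integer(e$start),
        end = as.integer(e$end)
      )
    }
  }
  snp_corpus(
    sentences = list_rbind(sents),
    entities = if (length(ents)) list_rbind(ents) else empty_entities(),
    annotated = FALSE
  )
}

#' Write candidate predictions as JSONL
#'
#' One JSON object per candidate with the identifiers, the predicted label,
#' its binary view, the fired positional features and any matched neutral
#' rule — the interchange format produced by the extraction pipeline.
#'
#' @param predictions A tibble as returned by [nnb_classify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_predictions_jsonl <- function(predictions, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  for (i in seq_len(nrow(predictions))) {
    row <- as.list(predictions[i, ])
    writeLines(jsonlite::toJSON(row, auto_unbox = TRUE, na = "null"), con,
               useBytes = TRUE)
  }
  invisible(path)
}
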