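#' Detect neutral association candidates
#'
#' A neutral candidate's sentence gives no evidence for or against the
#' association — typically study-setup language ("we genotyped rs429358 in
#' patients with obesity").  Detection is rule-based: the sentence text is
#' entity-blinded (the SNP and phenotype surfaces replaced by `[SNP]` and
#' `[PHENOTYPE]` placeholders, so the decision never depends on the specific
#' mention strings) and the configured regular-expression rules are tried in
#' order; the first match wins.
#'
#' @param text Sentence text.
#' @param entities Tibble of the sentence's entity mentions (`kind`,
#'   `start`, `end`), used for blinding; may have zero rows.
#' @param config A [snprex_config()]; `config$neutral_rules` is the ordered,
#'   named pattern vector.
#' @return A list with elements `is_neutral` (logical) and `rule_id`
#'   (matched rule name, or `NA_character_`).
#' @examples
#' detect_neutral("We genotyped rs429358 in patients with obesity",
#'                tibble::tibble(kind = c("SNP", "PHENOTYPE"),
#'                               start = c(13L, 35L), end = c(21L, 42L)))
#' @export
detect_neutral <- function(text, entities = NULL, config = snprex_config()) {
  blinded <- blind_entities(text, entities)
  rules <- config$neutral_rules
  for (i in seq_along(rules)) {
    if (grepl(rules[[i]], blinded, perl = TRUE, ignore.case = TRUE)) {
      return(list(is_neutral = TRUE, rule_id = names(rules)[i]))
    }
  }
  list(is_neutral = FALSE, rule_id = NA_character_)
}

#' Replace entity mentions by placeholder tags
#'
#' Rewrites a sentence with every SNP mention replaced by `[SNP]` and every
#' phenotype mention by `[PHENOTYPE]`, processing spans right to left so
#' earlier offsets stay valid.  Overlapping spans are blinded outer-first.
#'
#' @inheritParams detect_neutral
#' @return The blinded sentence text.
#' @export
blind_entities <- function(text, entities = NULL) {
  if (is.null(entities) || nrow(entities) == 0L) return(text)
  ord <- order(entities$start, decreasing = TRUE)
  for (i in ord) {
    tag <- if (entities$kind[i] == "SNP") "[SNP]" else "[PHENOTYPE]"
    text <- paste0(
      substring(text, 1L, entities$start[i]),
      tag,
      substring(text, entities$end[i] + 1L)
    )
  }
  text
}
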