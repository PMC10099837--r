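#' Extract reported p-values from sentence text
#'
#' Matches the usual typographies of reported significance levels: `p` or
#' `P` (optionally written "p-value"), a comparator among `<`, `>`, `=`,
#' `<=`, `>=` and the typographic `\u2264`/`\u2265`, and a decimal or
#' scientific-notation number, including the `3.2 \u00d7 10\u22125` form
#' with a typographic multiplication sign and minus, and `1e-5` style
#' exponents.  Values are parsed to numeric; a match whose number fails to
#' parse is skipped with a warning.
#'
#' @inheritParams detect_negation
#' @return A tibble with columns `doc_id`, `sent_id`, `comparator` (one of
#'   `<`, `<=`, `=`, `>`, `>=`), `value`, `start`, `end`.
#' @examples
#' corp <- demo_sentence_corpus("association was strong (P < 0.001)")
#' extract_pvalues(corp)
#' @export
extract_pvalues <- function(corpus, config = snprex_config()) {
  stopifnot(inherits(corpus, "snp_corpus"))
  s <- corpus$sentences
  out <- pmap(list(s$doc_id, s$sent_id, s$text), function(d, sid, text) {
    pv <- sentence_pvalues(text)
    if (nrow(pv) == 0L) return(NULL)
    bind_cols(tibble(doc_id = d, sent_id = sid), pv)
  })
  out <- list_rbind(out[!vapply(out, is.null, logical(1))])
  if (nrow(out) == 0L) {
    return(tibble(doc_id = character(), sent_id = character(),
                  comparator = character(), value = double(),
                  start = integer(), end = integer()))
  }
  out
}

# Regex worker on one sentence.
sentence_pvalues <- function(text) {
  num <- paste0(
    "[0-9]+(?:\\.[0-9]+)?",
    "(?:\\s*[\u00d7x*]\\s*10\\s*(?:\\^|\\*\\*)?\\s*[\u2212\u2013-]?\\s*[0-9]+",
    "|[eE][\u2212\u2013+-]?[0-9]+)?"
  )
  pat <- paste0(
    "(?i)\\bp\\s*(?:[- ]?values?)?\\s*",
    "(<=|>=|\u2264|\u2265|<|>|=)\\s*",
    "(", num, ")"
  )
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  empty <- tibble(comparator = character(), value = double(),
                  start = integer(), end = integer())
  if (m[1] == -1L) return(empty)
  starts <- as.integer(m) - 1L
  lens <- attr(m, "match.length")
  rows <- map(seq_along(starts), function(i) {
    frag <- substring(text, starts[i] + 1L, starts[i] + lens[i])
    cmp <- regmatches(frag, regexpr("<=|>=|\u2264|\u2265|<|>|=", frag))
    cmp <- switch(cmp, "\u2264" = "<=", "\u2265" = ">=", cmp)
    numtxt <- sub(paste0("(?i)^.*?(<=|>=|\u2264|\u2265|<|>|=)\\s*"), "", frag, perl = TRUE)
    value <- parse_pvalue_number(numtxt)
    if (is.na(value)) {
      warn(sprintf("could not parse p-value number '%s'; mention skipped.", numtxt))
      return(NULL)
    }
    tibble(comparator = cmp, value = value,
           start = starts[i], end = starts[i] + lens[i])
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0L) return(empty)
  list_rbind(rows)
}

parse_pvalue_number <- function(x) {
  x <- gsub("\u2212|\u2013", "-", x)      # typographic minus / en dash
  x <- gsub("\\s+", "", x)
  x <- gsub("(?i)[\u00d7x*]10(\\^|\\*\\*)?", "e", x, perl = TRUE)
  suppressWarnings(as.numeric(x))
}

# Is a reported p-value mention evidence of significance at `alpha`?
# A mention bounds the p-value below alpha when the comparator points
# downward (or is equality) and the stated number is below alpha; "p < alpha"
# itself also qualifies.
pvalue_is_significant <- function(comparator, value, alpha = 0.05) {
  (comparator %in% c("<", "<=", "=") & value < alpha) |
    (comparator == "<" & value == alpha)
}
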