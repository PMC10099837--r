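#' Tokenize a sentence into spans
#'
#' Whitespace-and-punctuation tokenization: a token is a maximal run of
#' alphanumeric characters, optionally joined by internal hyphens,
#' apostrophes, periods or underscores (so `rs1051730`, `p-value` and
#' `0.001` are single tokens).  Spans are 0-based half-open character
#' offsets on the input string; surfaces always equal the substring at the
#' span, and concatenated surfaces reconstruct the input minus separator
#' characters.
#'
#' @param text A character scalar (NFC-normalized sentence text).
#' @return A tibble with columns `token`, `start`, `end` (0-based half-open),
#'   in left-to-right order; zero rows for empty input.
#' @examples
#' tokenize("rs1051730 variant")
#' @export
tokenize <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || !nzchar(text)) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  m <- gregexpr("[[:alnum:]]+(?:[-'._][[:alnum:]]+|\\.[[:alnum:]]+)*",
                text, perl = TRUE)[[1]]
  if (m[1] == -1L) {
    return(tibble(token = character(), start = integer(), end = integer()))
  }
  start <- as.integer(m) - 1L
  len <- attr(m, "match.length")
  tibble(
    token = substring(text, start + 1L, start + len),
    start = start,
    end = start + as.integer(len)
  )
}

# Lowercased token surfaces, convenience for whole-token lexicon matching.
token_surfaces <- function(tokens) tolower(tokens$token)

# Match possibly multi-word lexicon phrases against a token table.
# Returns a tibble (start, end, text) of whole-token matches, longest
# phrase first at any anchor token, non-overlapping, in sentence order.
match_phrases <- function(text, tokens, phrases) {
  if (nrow(tokens) == 0L || length(phrases) == 0L) {
    return(tibble(start = integer(), end = integer(), text = character()))
  }
  words <- strsplit(tolower(phrases), " ", fixed = TRUE)
  ord <- order(lengths(words), decreasing = TRUE)
  words <- words[ord]
  toks <- token_surfaces(tokens)
  used <- rep(FALSE, nrow(tokens))
  out <- list()
  for (i in seq_len(nrow(tokens))) {
    if (used[i]) next
    for (w in words) {
      k <- length(w)
      if (i + k - 1L > nrow(tokens)) next
      if (any(used[i:(i + k - 1L)])) next
      if (identical(toks[i:(i + k - 1L)], w)) {
        s <- tokens$start[i]
        e <- tokens$end[i + k - 1L]
        out[[length(out) + 1L]] <- tibble(
          start = s, end = e, text = substring(text, s + 1L, e)
        )
        used[i:(i + k - 1L)] <- TRUE
        break
      }
    }
  }
  if (length(out) == 0L) {
    return(tibble(start = integer(), end = integer(), text = character()))
  }
  arrange(list_rbind(out), .data$start)
}
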