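#' Scope-position features of a candidate relative to negation events
#'
#' For one negation scope there are exactly six mutually exclusive
#' possibilities for where the SNP and phenotype mentions sit: both inside
#' the scope, one left (outside) and one inside, one right (outside) and one
#' inside, both left, both right, or one on each side.  An entity counts as
#' *inside* a scope when its span intersects the scope span; otherwise it is
#' *left* or *right* of the scope according to its start offset.  With
#' several negation events in a sentence, the candidate-level feature for
#' each possibility is the disjunction over events (any one inverting
#' configuration suffices to invert the association); with no event all six
#' are `FALSE`.  The seventh Boolean, `is_neutral_cand`, carries the
#' neutral-candidate prediction.
#'
#' @param snp_span,phen_span Length-2 integer vectors `c(start, end)`,
#'   0-based half-open, for the SNP and phenotype mentions.
#' @param events Tibble of negation events with columns `scope_start`,
#'   `scope_end` (zero rows allowed).
#' @param is_neutral Logical: the neutral-candidate flag.
#' @return A one-row tibble with logical columns `both_in_scope`,
#'   `one_left_one_in`, `one_right_one_in`, `both_left`, `both_right`,
#'   `one_left_one_right`, `is_neutral_cand`.
#' @examples
#' positional_features(c(14L, 23L), c(60L, 92L),
#'                     tibble::tibble(scope_start = 32L, scope_end = 92L))
#' @export
positional_features <- function(snp_span, phen_span, events,
                                is_neutral = FALSE) {
  cols <- c("both_in_scope", "one_left_one_in", "one_right_one_in",
            "both_left", "both_right", "one_left_one_right")
  acc <- setNames(rep(FALSE, 6L), cols)
  for (i in seq_len(nrow(events))) {
    scope <- c(events$scope_start[i], events$scope_end[i])
    acc[scope_position(snp_span, phen_span, scope)] <- TRUE
  }
  out <- as_tibble(as.list(acc))
  out$is_neutral_cand <- isTRUE(is_neutral)
  out
}

# Classify one (snp, phen, scope) triple into exactly one of the six
# positional possibilities.
scope_position <- function(snp_span, phen_span, scope) {
  side <- function(span) {
    if (span[1] < scope[2] && span[2] > scope[1]) return("in")  # intersects
    if (span[1] < scope[1]) "left" else "right"
  }
  a <- side(snp_span); b <- side(phen_span)
  n_in <- sum(c(a, b) == "in")
  if (n_in == 2L) return("both_in_scope")
  if (n_in == 1L) {
    outside <- setdiff(c(a, b), "in")
    return(if (outside == "left") "one_left_one_in" else "one_right_one_in")
  }
  if (a == "left" && b == "left") return("both_left")
  if (a == "right" && b == "right") return("both_right")
  "one_left_one_right"
}
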