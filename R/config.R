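#' Extraction configuration: lexicons and neutral-candidate rules
#'
#' Bundles every lexicon and rule list used by the rule-based extractors:
#' negation cues, clause connectors (with their concessive subset), modality
#' markers (hedges), the neutral-candidate regular-expression rules, and the
#' p-value significance threshold.  All defaults are editable; rule-based
#' behaviour is fully determined by this object, so alternative lexicons can
#' be supplied without touching code.
#'
#' Neutral rules are applied to the sentence with entity surfaces replaced by
#' `[SNP]` / `[PHENOTYPE]` placeholders, so they may reference those tags.
#' The shipped defaults target study-setup language ("we genotyped ...",
#' "this study examined ...") which describes an experiment without asserting
#' an association either way.
#'
#' @param negation_cues Character vector of single-token negation cue words,
#'   matched case-insensitively against whole tokens.
#' @param connectors Character vector of clause connectors (may be multi-word
#'   phrases); must contain `concessive` as a subset.
#' @param concessive Character vector: the concessive subset of `connectors`
#'   (contrastive connectors that weaken certainty).
#' @param modality_markers Character vector of hedging/modality tokens.
#' @param neutral_rules Named character vector of Perl-compatible regular
#'   expressions; names are rule identifiers.  Rules are tried in order and
#'   the first match wins.
#' @param alpha Significance threshold used to flag a reported p-value as
#'   significant (default 0.05).
#'
#' @return An object of class `snprex_config` (a named list).
#' @examples
#' cfg <- snprex_config()
#' cfg$negation_cues
#' @export
snprex_config <- function(negation_cues = default_negation_cues(),
                          connectors = default_connectors(),
                          concessive = default_concessive_connectors(),
                          modality_markers = default_modality_markers(),
                          neutral_rules = default_neutral_rules(),
                          alpha = 0.05) {
  if (!all(concessive %in% connectors)) {
    abort("`concessive` must be a subset of `connectors`.")
  }
  if (length(neutral_rules) > 0) {
    if (is.null(names(neutral_rules)) || any(names(neutral_rules) == "")) {
      abort("`neutral_rules` must be a fully named character vector.")
    }
    for (i in seq_along(neutral_rules)) {
      ok <- tryCatch(
        { grepl(neutral_rules[[i]], "", perl = TRUE); TRUE },
        error = function(e) FALSE
      )
      if (!ok) abort(sprintf("neutral rule '%s' does not compile.", names(neutral_rules)[i]))
    }
  }
  stopifnot(is.numeric(alpha), length(alpha) == 1L, alpha > 0, alpha < 1)
  structure(
    list(
      negation_cues = tolower(negation_cues),
      connectors = tolower(connectors),
      concessive = tolower(concessive),
      modality_markers = tolower(modality_markers),
      neutral_rules = neutral_rules,
      alpha = alpha
    ),
    class = "snprex_config"
  )
}

#' @rdname snprex_config
#' @export
default_negation_cues <- function() {
  c("no", "not", "without", "neither", "nor", "none", "never", "lack",
    "lacked", "absence", "absent")
}

#' @rdname snprex_config
#' @export
default_connectors <- function() {
  c(default_concessive_connectors(),
    "because", "since", "therefore", "moreover", "furthermore", "thus",
    "hence", "meanwhile")
}

#' @rdname snprex_config
#' @export
default_concessive_connectors <- function() {
  c("although", "though", "even though", "whereas", "while", "but",
    "however", "nevertheless")
}

#' @rdname snprex_config
#' @export
default_modality_markers <- function() {
  c("may", "might", "could", "suggest", "suggests", "suggested", "likely",
    "possibly", "appear", "appears", "seem", "seems")
}

#' @rdname snprex_config
#' @export
default_neutral_rules <- function() {
  c(
    genotyped     = "\\bgenotyp(?:ed|ing)\\b",
    examined      = "\\bexamined\\b",
    investigated  = "\\binvestigated\\b",
    recruited     = "\\brecruited\\b",
    enrolled      = "\\benrolled\\b",
    study_aim     = "\\baim of (?:this|the) study\\b",
    measured      = "\\bmeasured\\b"
  )
}

#' Read or write an extraction configuration as JSON
#'
#' The on-disk form is a plain JSON object with one array per lexicon plus
#' the scalar `alpha`; neutral rules are stored as an object mapping rule id
#' to pattern.  Hand-edited files are validated on read.
#'
#' @param path File path.
#' @param config A [snprex_config()] object.
#' @return `read_config()` returns a `snprex_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  rules <- unlist(raw$neutral_rules %||% list())
  snprex_config(
    negation_cues = raw$negation_cues %||% default_negation_cues(),
    connectors = raw$connectors %||% default_connectors(),
    concessive = raw$concessive %||% default_concessive_connectors(),
    modality_markers = raw$modality_markers %||% default_modality_markers(),
    neutral_rules = if (length(rules)) rules else default_neutral_rules(),
    alpha = raw$alpha %||% 0.05
  )
}

#' @rdname read_config
#' @export
write_config <- function(config, path) {
  stopifnot(inherits(config, "snprex_config"))
  jsonlite::write_json(
    list(
      negation_cues = config$negation_cues,
      connectors = config$connectors,
      concessive = config$concessive,
      modality_markers = config$modality_markers,
      neutral_rules = as.list(config$neutral_rules),
      alpha = config$alpha
    ),
    path, auto_unbox = TRUE, pretty = TRUE
  )
  invisible(path)
}

#' @export
print.snprex_config <- function(x, ...) {
  cat("<snprex_config>\n")
  cat("  negation cues:   ", length(x$negation_cues), "\n")
  cat("  connectors:      ", length(x$connectors),
      sprintf("(%d concessive)", length(x$concessive)), "\n")
  cat("  modality markers:", length(x$modality_markers), "\n")
  cat("  neutral rules:   ", length(x$neutral_rules), "\n")
  cat("  alpha:           ", x$alpha, "\n")
  invisible(x)
}
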