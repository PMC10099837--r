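#' Read an annotated corpus from XML
#'
#' The native `"snprex"` dialect is defined by this package (the annotated
#' corpus the method was developed on never published its schema):
#'
#' ```
#' <snprex-corpus split="train" provenance="...">
#'   <abstract id="d1">
#'     <sentence id="s1" key="true">
#'       <text>rs1051730 was associated with smoking</text>
#'       <entity id="e1" kind="SNP" start="0" end="9"/>
#'       <entity id="e2" kind="PHENOTYPE" start="30" end="37"/>
#'       <negation cue-start="..." cue-end="..." scope-start="..." scope-end="..." source="GOLD"/>
#'       <modality start="..." end="..." source="GOLD"/>
#'       <candidate snp="e1" phenotype="e2" label="POSITIVE" certainty="STRONG"/>
#'     </sentence>
#'   </abstract>
#' </snprex-corpus>
#' ```
#'
#' Offsets are 0-based half-open on the sentence text.  Unparseable or
#' missing optional fields (candidate `label`, `certainty`) default to
#' `UNLABELED` / `NONE`.  The `"snpphena"` dialect flag switches on a
#' lenient best-effort importer that additionally accepts common alternative
#' spellings (`document`/`Abstract` elements, `SNP`/`Phenotype` entity
#' elements, `begin`/`offset` attributes) for externally produced files.
#'
#' @param path Path to an XML file.
#' @param dialect `"snprex"` (native, strict) or `"snpphena"` (lenient).
#' @return An [snp_corpus()].
#' @export
read_corpus <- function(path, dialect = c("snprex", "snpphena")) {
  dialect <- match.arg(dialect)
  doc <- xml2::read_xml(path)  # malformed XML -> xml2 parse error with line info
  root <- xml2::xml_name(doc)
  if (dialect == "snprex" && root != "snprex-corpus") {
    abort(sprintf("expected <snprex-corpus> root element, found <%s>.", root))
  }

  lenient <- dialect == "snpphena"
  attr_of <- function(node, names_try, default = NA_character_) {
    for (nm in names_try) {
      v <- xml2::xml_attr(node, nm)
      if (!is.na(v)) return(v)
    }
    default
  }
  int_attr <- function(node, names_try) {
    v <- suppressWarnings(as.integer(attr_of(node, names_try)))
    v
  }

  abs_xp <- if (lenient) ".//abstract|.//Abstract|.//document|.//Document" else "./abstract"
  sen_xp <- if (lenient) ".//sentence|.//Sentence" else "./sentence"

  sents <- list(); ents <- list(); cands <- list(); negs <- list(); mods <- list()
  any_annot <- FALSE
  for (ab in xml2::xml_find_all(doc, abs_xp)) {
    d_id <- attr_of(ab, c("id", "doc_id", "origId"))
    for (sn in xml2::xml_find_all(ab, sen_xp)) {
      s_id <- attr_of(sn, c("id", "sent_id"))
      tnode <- xml2::xml_find_first(sn, "./text")
      text <- if (inherits(tnode, "xml_missing")) {
        attr_of(sn, c("text"), "")
      } else {
        xml2::xml_text(tnode)
      }
      text <- enc2utf8(text)
      is_key <- tolower(attr_of(sn, c("key", "is_key"), "false")) %in% c("true", "1", "yes")
      sents[[length(sents) + 1L]] <- tibble(
        doc_id = d_id, sent_id = s_id, text = text, is_key = is_key
      )
      ent_xp <- if (lenient) "./entity|./SNP|./Phenotype" else "./entity"
      for (en in xml2::xml_find_all(sn, ent_xp)) {
        kind <- attr_of(en, c("kind", "type"))
        if (is.na(kind)) {
          kind <- switch(xml2::xml_name(en), SNP = "SNP", Phenotype = "PHENOTYPE", NA_character_)
        }
        kind <- toupper(kind)
        if (lenient && kind %in% c("TRAIT", "PHEN")) kind <- "PHENOTYPE"
        st <- int_attr(en, c("start", "begin", "charOffsetStart"))
        enx <- int_attr(en, c("end", "charOffsetEnd"))
        ents[[length(ents) + 1L]] <- tibble(
          doc_id = d_id, sent_id = s_id,
          mention_id = attr_of(en, c("id", "mention_id")),
          kind = kind, start = st, end = enx,
          surface = substring(text, st + 1L, enx)
        )
      }
      for (ng in xml2::xml_find_all(sn, "./negation")) {
        any_annot <- TRUE
        cs <- int_attr(ng, c("cue-start", "cue_start"))
        ce <- int_attr(ng, c("cue-end", "cue_end"))
        negs[[length(negs) + 1L]] <- tibble(
          doc_id = d_id, sent_id = s_id,
          cue_start = cs, cue_end = ce,
          cue_text = substring(text, cs + 1L, ce),
          scope_start = int_attr(ng, c("scope-start", "scope_start")),
          scope_end = int_attr(ng, c("scope-end", "scope_end")),
          source = attr_of(ng, "source", "GOLD")
        )
      }
      for (md in xml2::xml_find_all(sn, "./modality")) {
        any_annot <- TRUE
        st <- int_attr(md, "start"); enx <- int_attr(md, "end")
        mods[[length(mods) + 1L]] <- tibble(
          doc_id = d_id, sent_id = s_id, start = st, end = enx,
          text = substring(text, st + 1L, enx),
          source = attr_of(md, "source", "GOLD")
        )
      }
      cand_xp <- if (lenient) "./candidate|./pair|./Pair" else "./candidate"
      for (cd in xml2::xml_find_all(sn, cand_xp)) {
        lab <- toupper(attr_of(cd, c("label", "association"), "UNLABELED"))
        if (!lab %in% c("POSITIVE", "NEGATIVE", "NEUTRAL")) lab <- "UNLABELED"
        cert <- toupper(attr_of(cd, c("certainty", "confidence"), "NONE"))
        if (lenient && cert %in% c("NORMAL", "MODERATED")) cert <- "MODERATE"
        if (lenient && cert == "HIGH") cert <- "STRONG"
        if (!cert %in% c("WEAK", "MODERATE", "STRONG")) cert <- "NONE"
        if (lab != "POSITIVE") cert <- "NONE"
        cands[[length(cands) + 1L]] <- tibble(
          doc_id = d_id, sent_id = s_id,
          snp_id = attr_of(cd, c("snp", "e1")),
          phenotype_id = attr_of(cd, c("phenotype", "e2")),
          gold_label = lab, gold_certainty = cert
        )
      }
    }
  }

  sentences <- if (length(sents)) list_rbind(sents) else
    tibble(doc_id = character(), sent_id = character(), text = character(),
           is_key = logical())
  split <- xml2::xml_attr(doc, "split")
  if (is.na(split) || !split %in% c("train", "test", "unsplit")) split <- "unsplit"
  annot_attr <- xml2::xml_attr(doc, "annotated")
  if (!is.na(annot_attr)) any_annot <- tolower(annot_attr) == "true"
  snp_corpus(
    sentences = sentences,
    entities = if (length(ents)) list_rbind(ents) else empty_entities(),
    candidates = if (length(cands)) list_rbind(cands) else empty_candidates(),
    negations = if (length(negs)) list_rbind(negs) else empty_negations(),
    modality = if (length(mods)) list_rbind(mods) else empty_modality(),
    split = split,
    provenance = xml2::xml_attr(doc, "provenance") %|na|% "",
    annotated = any_annot
  )
}

`%|na|%` <- function(x, y) if (length(x) == 1 && is.na(x)) y else x

#' Write a corpus as canonical XML
#'
#' Serializes in the native dialect documented under [read_corpus()], with a
#' fixed element and attribute order and UTF-8 encoding, so the same corpus
#' always produces byte-identical output and `read_corpus(write_corpus(x))`
#' restores an equal object.  Invariants are validated before anything is
#' written.
#'
#' @param corpus An [snp_corpus()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_corpus <- function(corpus, path) {
  validate_corpus(corpus)
  doc <- xml2::xml_new_root("snprex-corpus",
                            split = corpus$split,
                            provenance = corpus$provenance,
                            annotated = tolower(as.character(corpus$annotated)))
  fmt <- function(x) sprintf("%d", as.integer(x))
  for (d in corpus$documents$doc_id) {
    ab <- xml2::xml_add_child(doc, "abstract", id = d)
    srows <- filter(corpus$sentences, .data$doc_id == d)
    for (i in seq_len(nrow(srows))) {
      sid <- srows$sent_id[i]
      sn <- xml2::xml_add_child(ab, "sentence", id = sid,
                                key = tolower(as.character(srows$is_key[i])))
      tx <- xml2::xml_add_child(sn, "text")
      xml2::xml_text(tx) <- srows$text[i]
      er <- filter(corpus$entities, .data$doc_id == d, .data$sent_id == sid)
      for (j in seq_len(nrow(er))) {
        xml2::xml_add_child(sn, "entity", id = er$mention_id[j],
                            kind = er$kind[j],
                            start = fmt(er$start[j]), end = fmt(er$end[j]))
      }
      ng <- filter(corpus$negations, .data$doc_id == d, .data$sent_id == sid)
      for (j in seq_len(nrow(ng))) {
        xml2::xml_add_child(sn, "negation",
                            `cue-start` = fmt(ng$cue_start[j]),
                            `cue-end` = fmt(ng$cue_end[j]),
                            `scope-start` = fmt(ng$scope_start[j]),
                            `scope-end` = fmt(ng$scope_end[j]),
                            source = ng$source[j])
      }
      md <- filter(corpus$modality, .data$doc_id == d, .data$sent_id == sid)
      for (j in seq_len(nrow(md))) {
        xml2::xml_add_child(sn, "modality",
                            start = fmt(md$start[j]), end = fmt(md$end[j]),
                            source = md$source[j])
      }
      cd <- filter(corpus$candidates, .data$doc_id == d, .data$sent_id == sid)
      for (j in seq_len(nrow(cd))) {
        xml2::xml_add_child(sn, "candidate",
                            snp = cd$snp_id[j], phenotype = cd$phenotype_id[j],
                            label = cd$gold_label[j],
                            certainty = cd$gold_certainty[j])
      }
    }
  }
  xml2::write_xml(doc, path, options = "format")
  invisible(path)
}
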