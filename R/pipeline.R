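# End-to-end annotation: zoning -> tokenization -> tagging ->
# lemmatization -> NER -> negation -> relations -> document labels.

#' Annotate one report through the full pipeline
#'
#' Runs every stage in order on each section of the report. Entities in
#' the request section are recognized but marked ineligible for
#' labelling: phenotype labels are assigned only from the body and
#' conclusion.
#'
#' @param report A `radphen_report` (from [zone_report()] or
#'   [read_reports()]), or a raw text string.
#' @param lexicon A `radphen_lexicon`; defaults to the shipped lexicon.
#' @param rules Rule configuration from [rules_config()].
#' @param tagger Tagger function under the [pos_tag()] contract.
#' @param patterns Paraphrase patterns for [recognize_entities()].
#' @return Object of class `radphen_annotation`: list with `report_id`,
#'   `text`, `sentences`, `entities` (global `T` ids and offsets into
#'   the full text), `relations` (`R` ids), `labels` and `provenance`.
#' @export
#' @examples
#' ann <- annotate_report("REPORT: There is an old left parietal infarct.")
#' ann$labels
annotate_report <- function(report, lexicon = default_lexicon(),
                            rules = rules_config(), tagger = rule_tagger,
                            patterns = default_paraphrase_patterns()) {
  if (is.character(report)) report <- zone_report(report)
  stopifnot(inherits(report, "radphen_report"))

  sentences <- list()
  ent_all <- list()
  rel_all <- list()
  sid <- 0L

  for (si in seq_len(nrow(report$sections))) {
    sec <- report$sections[si, ]
    if (sec$end <= sec$start) next
    sents <- process_text(sec$text, sec$kind, tagger)
    for (sent in sents) {
      sid <- sid + 1L
      # shift to offsets into the full raw text
      sent$tokens$start <- sent$tokens$start + sec$start
      sent$tokens$end <- sent$tokens$end + sec$start
      sent$start <- sent$start + sec$start
      sent$end <- sent$end + sec$start
      sent$sentence_id <- sid
      chunks <- chunk_sentence(sent)
      ents <- recognize_entities(sent, lexicon, patterns)
      ents <- detect_negation(sent, ents, chunks, rules)
      rels <- extract_relations(sent, ents, chunks, rules)
      ents$sentence_id <- rep(sid, nrow(ents))
      ents$section_kind <- rep(sec$kind, nrow(ents))
      ents$local <- seq_len(nrow(ents))
      ents$surface <- vapply(seq_len(nrow(ents)), function(k)
        substr0(report$raw_text, ents$start[k], ents$end[k]), character(1))
      sentences[[sid]] <- list(tokens = sent$tokens, start = sent$start,
                               end = sent$end, section_kind = sec$kind,
                               chunks = chunks)
      ent_all[[sid]] <- ents
      rel_all[[sid]] <- cbind(rels, sentence_id = rep(sid, nrow(rels)))
    }
  }

  entities <- do.call(rbind, c(list(empty_entities_local()), ent_all))
  if (nrow(entities)) {
    entities$id <- sprintf("T%d", seq_len(nrow(entities)))
  } else entities$id <- character(0)

  relations <- empty_relations()
  rels_raw <- do.call(rbind, rel_all)
  if (!is.null(rels_raw) && nrow(rels_raw)) {
    idmap <- function(sid, local) {
      entities$id[entities$sentence_id == sid][local]
    }
    relations <- data.frame(
      id = sprintf("R%d", seq_len(nrow(rels_raw))),
      kind = rels_raw$kind,
      modifier_id = mapply(idmap, rels_raw$sentence_id, rels_raw$modifier),
      target_id = mapply(idmap, rels_raw$sentence_id, rels_raw$target),
      stringsAsFactors = FALSE)
  }

  entities <- entities[, c("id", "type", "subtype", "start", "end", "surface",
                           "sentence_id", "section_kind", "negated",
                           "uncertain", "tok_from", "tok_to")]
  lab <- assign_labels(entities, relations, report_id = report$report_id)

  structure(list(report_id = report$report_id, text = report$raw_text,
                 sentences = sentences, entities = entities,
                 relations = relations, labels = lab$labels,
                 provenance = lab$provenance),
            class = "radphen_annotation")
}

empty_entities_local <- function() {
  cbind(data.frame(type = character(0), subtype = character(0),
                   start = integer(0), end = integer(0),
                   surface = character(0), tok_from = integer(0),
                   tok_to = integer(0), negated = logical(0),
                   uncertain = logical(0), stringsAsFactors = FALSE),
        data.frame(sentence_id = integer(0), section_kind = character(0),
                   local = integer(0)))
}

#' @export
print.radphen_annotation <- function(x, ...) {
  cat(sprintf("<radphen_annotation> %s: %d sentences, %d entities, %d relations\n",
              x$report_id, length(x$sentences), nrow(x$entities),
              nrow(x$relations)))
  if (length(x$labels)) cat("  labels:", paste(x$labels, collapse = "; "), "\n")
  else cat("  labels: (none)\n")
  invisible(x)
}

#' Convert an annotation to a standoff document
#'
#' @param annotation A `radphen_annotation`.
#' @return A `standoff_doc` carrying the entities, relations and
#'   document labels, ready for [write_standoff()].
#' @export
as_standoff <- function(annotation) {
  standoff_doc(annotation$text, annotation$entities, annotation$relations,
               annotation$labels)
}

#' Annotate a list of reports
#'
#' @param reports List of `radphen_report` objects or character texts.
#' @param ... Passed to [annotate_report()].
#' @param lexicon Lexicon shared across reports (loaded once).
#' @return List of `radphen_annotation`.
#' @export
annotate_corpus <- function(reports, lexicon = default_lexicon(), ...) {
  lapply(reports, annotate_report, lexicon = lexicon, ...)
}
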