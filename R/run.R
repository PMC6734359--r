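# Batch orchestration behind the command-line interface: annotate a
# directory of reports, evaluate predictions against gold, generate a
# synthetic corpus, summarize a corpus.

#' Annotate a corpus on disk
#'
#' Reads reports, runs the full pipeline in stage order (zoning,
#' tokenization, tagging, lemmatization, NER, negation, relations,
#' labels), and writes per-report JSON-lines plus brat standoff pairs.
#' One log line per stage with counts when `options(radphen.verbose)`.
#'
#' @param input_path Directory of `.txt` reports (or single file).
#' @param output_dir Output directory (created if absent).
#' @param lexicon_path Optional lexicon TSV; default lexicon otherwise.
#' @param rules Rule configuration.
#' @return Invisibly, the list of annotations.
#' @export
run_annotate <- function(input_path, output_dir, lexicon_path = NULL,
                         rules = rules_config()) {
  lexicon <- if (is.null(lexicon_path)) default_lexicon() else
    load_lexicon(lexicon_path)
  reports <- read_reports(input_path)
  radphen_log("read %d report(s) from %s", length(reports), input_path)
  anns <- annotate_corpus(reports, lexicon = lexicon, rules = rules)
  radphen_log("annotated: %d entities, %d relations, %d labels",
              sum(vapply(anns, function(a) nrow(a$entities), integer(1))),
              sum(vapply(anns, function(a) nrow(a$relations), integer(1))),
              sum(lengths(lapply(anns, `[[`, "labels"))))
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  write_jsonl(anns, file.path(output_dir, "labels.jsonl"))
  for (a in anns)
    write_standoff(as_standoff(a), file.path(output_dir, a$report_id))
  invisible(anns)
}

read_labelled <- function(path) {
  if (dir.exists(path)) {
    reps <- read_reports(path, format = "standoff")
    return(lapply(reps, function(r)
      list(report_id = r$report_id,
           labels = if (is.null(r$gold)) character(0) else r$gold$labels)))
  }
  lines <- readLines(path, warn = FALSE)
  lapply(lines[nzchar(lines)], function(ln) {
    rec <- jsonlite::fromJSON(ln)
    list(report_id = rec$report_id, labels = unlist(rec$labels) %||% character(0))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate predicted labels against gold
#'
#' Both arguments may be a JSON-lines labels file (as written by
#' [run_annotate()]) or a directory of brat `.txt`/`.ann` pairs. Writes
#' (optionally) and returns the per-phenotype metrics table, including
#' the aggregate "Any ..." rows.
#'
#' @param pred_path,gold_path Predictions and reference.
#' @param out_path Optional TSV output path.
#' @param suppress_below Optional display suppression threshold.
#' @return The metrics table from [evaluate_labels()].
#' @export
run_evaluate <- function(pred_path, gold_path, out_path = NULL,
                         suppress_below = NULL) {
  pred <- read_labelled(pred_path)
  gold <- read_labelled(gold_path)
  tab <- evaluate_labels(pred, gold, suppress_below = suppress_below)
  if (!is.null(out_path)) {
    utils::write.table(format_metrics_table(tab), out_path, sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  tab
}

#' Generate a synthetic corpus on disk
#'
#' Writes one brat `.txt`/`.ann` pair per report, a `labels.jsonl`
#' export, and a `manifest.json` echoing the configuration and the
#' per-label counts.
#'
#' @param config A [synth_config()].
#' @param out_path Output directory (created if absent).
#' @return Invisibly, the generated corpus.
#' @export
run_generate <- function(config, out_path) {
  corpus <- generate_corpus(config)
  dir.create(out_path, recursive = TRUE, showWarnings = FALSE)
  for (sr in corpus)
    write_standoff(sr$gold, file.path(out_path, sr$report_id))
  write_jsonl(lapply(corpus, function(sr)
    list(report_id = sr$report_id, labels = sr$gold$labels)),
    file.path(out_path, "labels.jsonl"))
  st <- corpus_stats(corpus)
  manifest <- list(config = unclass(config),
                   summary = st$summary, per_label = st$per_label)
  jsonlite::write_json(manifest, file.path(out_path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(corpus)
}
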