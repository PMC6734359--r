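# Shared fixtures for the test suite. The lexicon is loaded once; small
# corpora are generated in code at test time.

LEX <- default_lexicon()

annotate_text <- function(text, ...) {
  annotate_report(text, lexicon = LEX, ...)
}

# process a single sentence and return it with chunks and entities
analyse_sentence <- function(text, section = "body") {
  sent <- process_text(text, section)[[1]]
  chunks <- chunk_sentence(sent)
  ents <- recognize_entities(sent, LEX)
  ents <- detect_negation(sent, ents, chunks)
  rels <- extract_relations(sent, ents, chunks)
  list(sentence = sent, chunks = chunks, entities = ents, relations = rels)
}

labelled <- function(id, labels) list(report_id = id, labels = labels)

three_section_report <- function() {
  paste0("CLINICAL DETAILS: ?stroke\n",
         "REPORT: Mature infarct in the basal ganglia. No acute haemorrhage.\n",
         "CONCLUSION: Old deep infarct.")
}

# numeric inversion of the binomial score test: the independent oracle
# for the Wilson interval
wilson_oracle <- function(k, n, conf = 0.95) {
  z <- qnorm(1 - (1 - conf) / 2)
  phat <- k / n
  se <- function(p) sqrt(p * (1 - p) / n)
  lo <- if (k == 0) 0 else
    uniroot(function(p) (phat - p) - z * se(p),
            c(1e-15, min(phat, 1 - 1e-12)), tol = 1e-12)$root
  hi <- if (k == n) 1 else
    uniroot(function(p) (p - phat) - z * se(p),
            c(max(phat, 1e-12), 1 - 1e-15), tol = 1e-12)$root
  c(low = lo, high = hi)
}
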