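test_that("sentence splitting handles negation examples and abbreviations", {
  s <- segment("No metastases. Exclude subdural bleed.")
  expect_length(s, 2)
  expect_identical(s[[1]]$tokens$surface, c("No", "metastases", "."))

  expect_length(segment(""), 0)
  expect_length(segment("Appearances (e.g. atrophy) are stable. New scan."), 2)
  expect_length(segment("First finding.\n\nSecond finding"), 2)
})

test_that("hyphenated medical terms stay single tokens", {
  s <- segment("intra-cranial haemorrhage")
  expect_identical(s[[1]]$tokens$surface, c("intra-cranial", "haemorrhage"))
  s2 <- segment("long-standing small-vessel disease")
  expect_identical(nrow(s2[[1]]$tokens), 3L)
})

test_that("detokenization by spans reproduces the section text", {
  texts <- c("There is an old, deep infarct; no new blood.",
             "Query SAH?  Low attenuation (2.5 cm) right frontal lobe.")
  for (tx in texts) {
    for (sent in segment(tx)) {
      for (i in seq_len(nrow(sent$tokens)))
        expect_identical(sent$tokens$surface[i],
                         substr(tx, sent$tokens$start[i] + 1,
                                sent$tokens$end[i]))
      expect_true(all(diff(sent$tokens$start) > 0))
      expect_true(all(sent$tokens$end > sent$tokens$start))
    }
  }
})

test_that("the rule tagger is total, deterministic and contract-checked", {
  surfaces <- c("haemorrhage", "bleeding", "the", "old", "3.5", ",",
                "excluded", "wibblewobble", "Basal")
  tags <- rule_tagger(surfaces)
  expect_length(tags, length(surfaces))
  expect_true(all(tags %in% c("NOUN", "VERB", "ADJ", "ADV", "DET", "PREP",
                              "CONJ", "NUM", "PUNCT", "OTHER")))
  expect_identical(tags[1], "NOUN")
  expect_identical(tags[5], "NUM")
  expect_identical(tags[6], "PUNCT")
  expect_identical(tags, rule_tagger(surfaces))

  sents <- segment("Old infarct.")
  expect_error(pos_tag(sents, function(x) rep("NOUN", length(x) + 1)),
               "contract violation")
  expect_error(pos_tag(sents, function(x) rep("WIBBLE", length(x))),
               "contract violation")
  # any conforming tagger can be injected
  tagged <- pos_tag(sents, function(x) rep("NOUN", length(x)))
  expect_identical(unique(tagged[[1]]$tokens$pos), "NOUN")
})

test_that("lemmatization canonicalizes inflected forms", {
  expect_identical(lemmatize("bled", "VERB"), "bleed")
  expect_identical(lemmatize("bleeding", "VERB"), "bleed")
  expect_identical(lemmatize("bleeds", "VERB"), "bleed")
  expect_identical(lemmatize("bleed", "VERB"), "bleed")
  expect_identical(lemmatize("infarct", "NOUN"), "infarct")
  expect_identical(lemmatize("metastases", "NOUN"), "metastasis")
  expect_identical(lemmatize("metastasis", "NOUN"), "metastasis")
  expect_identical(lemmatize("infarcts", "NOUN"), "infarct")
  expect_identical(lemmatize("changes", "NOUN"), "change")
  expect_identical(lemmatize("studies", "NOUN"), "study")
  expect_identical(lemmatize("excluded", "VERB"), "exclude")
  expect_identical(lemmatize("seen", "VERB"), "see")
  expect_identical(lemmatize("Haemorrhage", "NOUN"), "haemorrhage")
})

test_that("chunking builds the expected noun phrases", {
  sent <- process_text("redistribution of the original haematoma rather than new blood")[[1]]
  ch <- chunk_sentence(sent)
  nps <- ch[ch$kind == "noun_phrase", ]
  surf <- function(row) paste(sent$tokens$surface[row$from:row$to],
                              collapse = " ")
  np_texts <- vapply(seq_len(nrow(nps)), function(i) surf(nps[i, ]),
                     character(1))
  expect_true("the original haematoma" %in% np_texts)
  expect_true("new blood" %in% np_texts)
  # heads are the last nouns
  i <- which(np_texts == "the original haematoma")
  expect_identical(sent$tokens$surface[nps$head[i]], "haematoma")
  i <- which(np_texts == "new blood")
  expect_identical(sent$tokens$surface[nps$head[i]], "blood")
})

test_that("chunks cover every noun exactly once and never overlap", {
  corpus <- generate_corpus(synth_config(30, seed = 55,
                                         negated_distractor_rate = 0.8))
  for (sr in corpus) {
    for (si in seq_len(nrow(sr$report$sections))) {
      sec <- sr$report$sections[si, ]
      if (sec$end <= sec$start) next
      for (sent in process_text(sec$text, sec$kind)) {
        ch <- chunk_sentence(sent)
        seen <- rep(0L, nrow(sent$tokens))
        for (i in seq_len(nrow(ch)))
          seen[ch$from[i]:ch$to[i]] <- seen[ch$from[i]:ch$to[i]] + 1L
        expect_true(all(seen <= 1L))
        nouns <- which(sent$tokens$pos == "NOUN")
        in_np <- rep(FALSE, nrow(sent$tokens))
        nps <- ch[ch$kind == "noun_phrase", ]
        for (i in seq_len(nrow(nps))) in_np[nps$from[i]:nps$to[i]] <- TRUE
        expect_true(all(in_np[nouns]))
        if (nrow(ch))
          expect_true(all(ch$head >= ch$from & ch$head <= ch$to))
      }
    }
  }
  expect_identical(nrow(chunk_sentence(process_text(", ; .")[[1]])), 0L)
})
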