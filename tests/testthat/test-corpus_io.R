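test_that("zoning splits a structured report into three sections", {
  r <- zone_report("CLINICAL DETAILS: ?stroke\nREPORT: Mature infarct.\nCONCLUSION: Old infarct.")
  nz <- r$sections[r$sections$end > r$sections$start, ]
  expect_identical(nz$kind, c("request", "body", "conclusion"))
  # offsets verified by substring identity
  for (i in seq_len(nrow(nz)))
    expect_identical(nz$text[i],
                     substr(r$raw_text, nz$start[i] + 1, nz$end[i]))
  expect_identical(trimws(section_text(r, "body")), "Mature infarct.")
})

test_that("text with no headings falls back to an all-body zoning", {
  r <- zone_report("There is an old infarct with no heading structure.")
  expect_identical(section_text(r, "request"), "")
  expect_identical(section_text(r, "conclusion"), "")
  expect_identical(section_text(r, "body"), r$raw_text)
})

test_that("zoning is lossless: sections plus headings cover the text once", {
  corpus <- generate_corpus(synth_config(25, seed = 301))
  texts <- c(vapply(corpus, function(sr) sr$gold$text, character(1)),
             "no headings at all",
             "REPORT: body only",
             "CONCLUSION: tail only\n\nextra")
  for (tx in texts) {
    r <- zone_report(tx)
    covered <- rep(FALSE, nchar(r$raw_text))
    for (i in seq_len(nrow(r$sections))) {
      span <- r$sections$start[i] + seq_len(r$sections$end[i] - r$sections$start[i])
      expect_false(any(covered[span]))  # no character assigned twice
      covered[span] <- TRUE
    }
    # uncovered characters must all belong to heading lines
    gaps <- which(!covered)
    if (length(gaps)) {
      gap_text <- paste(strsplit(r$raw_text, "")[[1]][gaps], collapse = "")
      expect_match(gap_text, "(?i)(clinical details|report|conclusion)",
                   perl = TRUE)
    }
    # concatenation in span order restores every section substring
    for (i in seq_len(nrow(r$sections)))
      expect_identical(r$sections$text[i],
                       substr(r$raw_text, r$sections$start[i] + 1,
                              r$sections$end[i]))
  }
})

test_that("read_reports preserves count, skips empties, errors on bad path", {
  d <- withr::local_tempdir()
  for (i in 1:3)
    writeLines(sprintf("REPORT: Report number %d.", i),
               file.path(d, sprintf("r%d.txt", i)))
  reps <- read_reports(d)
  expect_length(reps, 3)
  expect_identical(vapply(reps, `[[`, character(1), "report_id"),
                   c("r1", "r2", "r3"))

  writeLines("", file.path(d, "empty.txt"))
  expect_warning(reps2 <- read_reports(d), "empty")
  expect_length(reps2, 3)

  expect_length(read_reports(withr::local_tempdir()), 0)
  expect_error(read_reports(file.path(d, "nope")), "does not exist")
})

test_that("standoff round trip is the identity modulo id renumbering", {
  corpus <- generate_corpus(synth_config(20, seed = 77,
                                         negated_distractor_rate = 1))
  d <- withr::local_tempdir()
  for (sr in corpus) {
    prefix <- file.path(d, sr$report_id)
    write_standoff(sr$gold, prefix)
    back <- read_standoff(prefix)
    expect_identical(back$text, sr$gold$text)
    expect_identical(back$labels, sr$gold$labels)
    cols <- c("type", "subtype", "start", "end", "surface", "negated",
              "uncertain")
    a <- sr$gold$entities[order(sr$gold$entities$start), cols]
    b <- back$entities[order(back$entities$start), cols]
    rownames(a) <- rownames(b) <- NULL
    expect_identical(a, b)
    # relations compare as (kind, modifier span, target span) triples
    span_of <- function(doc, id) {
      i <- match(id, doc$entities$id)
      sprintf("%d-%d", doc$entities$start[i], doc$entities$end[i])
    }
    rel_sig <- function(doc) {
      if (!nrow(doc$relations)) return(character(0))
      sort(sprintf("%s:%s>%s", doc$relations$kind,
                   vapply(doc$relations$modifier_id, span_of, character(1),
                          doc = doc),
                   vapply(doc$relations$target_id, span_of, character(1),
                          doc = doc)))
    }
    expect_identical(rel_sig(back), rel_sig(sr$gold))
  }
})

test_that("standoff writer validates spans and emits attribute lines", {
  doc <- standoff_doc("Exclude subdural bleed.",
                      data.frame(id = "T1", type = "subdural_haematoma",
                                 start = 8L, end = 22L, negated = TRUE,
                                 stringsAsFactors = FALSE))
  d <- withr::local_tempdir()
  paths <- write_standoff(doc, file.path(d, "doc"))
  ann <- readLines(paths[["ann"]])
  expect_length(grep("^T", ann), 1)
  expect_true(any(grepl("^A\\d+\tnegated T1", ann)))

  bad <- doc
  bad$entities$end <- 999L
  expect_error(write_standoff(bad, file.path(d, "bad")), "span")
  expect_false(file.exists(file.path(d, "bad.ann")))
})
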