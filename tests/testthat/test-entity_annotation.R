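test_that("entity recognition consumes matched tokens and covers paraphrases", {
  a <- analyse_sentence("subarachnoid blood is seen")
  expect_identical(a$entities$type, "subarachnoid_haemorrhage")

  b <- analyse_sentence("There is blood in the subarachnoid spaces")
  expect_identical(b$entities$type, "subarachnoid_haemorrhage")
  expect_identical(
    substr("There is blood in the subarachnoid spaces",
           b$entities$start + 1, b$entities$end),
    "blood in the subarachnoid spaces")

  for (phr in c("subarachnoid haemorrhage", "SAH", "subarachnoid blood")) {
    expect_identical(analyse_sentence(phr)$entities$type,
                     "subarachnoid_haemorrhage", info = phr)
  }

  expect_identical(nrow(analyse_sentence("The patient walked home")$entities), 0L)
})

test_that("entities never overlap and recognition is deterministic", {
  corpus <- generate_corpus(synth_config(30, seed = 9,
                                         negated_distractor_rate = 0.8))
  for (sr in corpus[1:10]) {
    a1 <- annotate_text(sr$report$raw_text)
    a2 <- annotate_text(sr$report$raw_text)
    expect_identical(a1$entities, a2$entities)
    e <- a1$entities[order(a1$entities$start), ]
    if (nrow(e) > 1)
      expect_true(all(e$start[-1] >= e$end[-nrow(e)]))
  }
})

test_that("pre- and post-trigger negation matches clinical phrasing", {
  expect_true(analyse_sentence("No metastases")$entities$negated)
  expect_true(analyse_sentence("Exclude subdural bleed.")$entities$negated)
  expect_true(analyse_sentence("No evidence of acute haemorrhage")$entities$negated[2])

  a <- analyse_sentence("diffusely sclerotic metastases are much less likely")
  expect_true(a$entities$negated[a$entities$type == "tumour"])

  b <- analyse_sentence("There is established small vessel disease.")
  expect_false(any(b$entities$negated))

  # clause boundary blocks the trigger scope
  cl <- analyse_sentence("No acute haemorrhage but there is an old infarct.")
  isch <- cl$entities$type == "ischaemic_stroke"
  expect_false(any(cl$entities$negated[isch]))
  expect_true(any(cl$entities$negated[cl$entities$type == "haemorrhagic_stroke"]))
})

test_that("hedged possibility is uncertain, not negated", {
  a <- analyse_sentence("Cannot exclude a subdural haematoma.")
  expect_false(a$entities$negated)
  expect_true(a$entities$uncertain)
  b <- analyse_sentence("Query SAH")
  expect_false(b$entities$negated[b$entities$type == "subarachnoid_haemorrhage"])
  expect_true(b$entities$uncertain[b$entities$type == "subarachnoid_haemorrhage"])
})

test_that("negation is idempotent and never set on modifiers", {
  corpus <- generate_corpus(synth_config(25, seed = 21,
                                         negated_distractor_rate = 1))
  for (sr in corpus[1:12]) {
    for (si in seq_len(nrow(sr$report$sections))) {
      sec <- sr$report$sections[si, ]
      if (sec$end <= sec$start) next
      for (sent in process_text(sec$text, sec$kind)) {
        ch <- chunk_sentence(sent)
        e0 <- recognize_entities(sent, LEX)
        e1 <- detect_negation(sent, e0, ch)
        e2 <- detect_negation(sent, e1, ch)
        expect_identical(e1, e2)
        expect_false(any(e1$negated[e1$type %in% modifier_types()]))
      }
    }
  }
})

test_that("modifiers attach inside their noun phrase first", {
  a <- analyse_sentence("Right frontal chronic haemorrhage")
  expect_identical(sort(a$relations$kind), c("location", "time"))
  tgt <- unique(a$entities$type[a$relations$target])
  expect_identical(tgt, "haemorrhagic_stroke")

  # NP-internal binding beats linear proximity across "rather than"
  b <- analyse_sentence(
    "I suspect this reflects redistribution of the original haematoma rather than new blood.")
  ents <- b$entities
  new_i <- which(ents$type == "time_recent")
  new_rel <- b$relations[b$relations$modifier == new_i, ]
  expect_identical(nrow(new_rel), 1L)
  target_surface <- substr(
    "I suspect this reflects redistribution of the original haematoma rather than new blood.",
    ents$start[new_rel$target] + 1, ents$end[new_rel$target])
  expect_identical(target_surface, "blood")  # not "haematoma"
  old_i <- which(ents$type == "time_old")
  old_rel <- b$relations[b$relations$modifier == old_i, ]
  old_target <- substr(
    "I suspect this reflects redistribution of the original haematoma rather than new blood.",
    ents$start[old_rel$target] + 1, ents$end[old_rel$target])
  expect_identical(old_target, "haematoma")
})

test_that("predicative modifiers link through the copula", {
  a <- analyse_sentence("The infarct in the right thalamus is old.")
  old_i <- which(a$entities$type == "time_old")
  rel <- a$relations[a$relations$modifier == old_i, ]
  expect_identical(a$entities$type[rel$target], "ischaemic_stroke")
  thal_i <- which(a$entities$type == "loc_deep")
  rel2 <- a$relations[a$relations$modifier == thal_i, ]
  expect_identical(a$entities$type[rel2$target], "ischaemic_stroke")
})

test_that("a modifier without any disease entity yields no relation", {
  a <- analyse_sentence("Chronic changes only.")
  expect_identical(nrow(a$relations), 0L)
})

test_that("a modifier more than the window away does not attach", {
  a <- analyse_sentence(
    "An old scar is present and further along we also note one tiny focal cortical nodule and an infarct.")
  old_i <- which(a$entities$type == "time_old")
  rel <- a$relations[a$relations$modifier %in% old_i, ]
  expect_identical(nrow(rel), 0L)
})
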