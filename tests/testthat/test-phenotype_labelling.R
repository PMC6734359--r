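test_that("presence phenotypes require one non-negated entity in body/conclusion", {
  ann <- annotate_text("CONCLUSION: There is established small vessel disease.")
  expect_identical(ann$labels, "Small vessel disease")

  # the same entity in the request section yields nothing
  ann2 <- annotate_text("CLINICAL DETAILS: known small vessel disease\nREPORT: Normal study.")
  expect_identical(ann2$labels, character(0))
  expect_true(any(ann2$entities$type == "small_vessel_disease"))
})

test_that("located and timed stroke mentions get fully specified labels", {
  ann <- annotate_text("REPORT: There is an acute cortical infarct.")
  expect_identical(ann$labels, "Ischaemic stroke, cortical, recent")

  ann2 <- annotate_text("REPORT: Right frontal chronic haemorrhage.")
  expect_identical(ann2$labels, "Haemorrhagic stroke, lobar, old")

  # incomplete modifier pair degrades to underspecified
  ann3 <- annotate_text("REPORT: There is an old infarct.")
  expect_identical(ann3$labels, "Ischaemic stroke, underspecified")
  ann4 <- annotate_text("REPORT: There is a lacunar infarct.")
  expect_identical(ann4$labels, "Ischaemic stroke, underspecified")
})

test_that("the classic two-phenotype report yields exactly two labels", {
  ann <- annotate_text(paste0(
    "CLINICAL DETAILS: ?stroke\n",
    "REPORT: There is an old left parietal infarct. ",
    "There is established small vessel disease.\n",
    "CONCLUSION: Old cortical infarct and small vessel disease."))
  expect_identical(ann$labels,
                   c("Ischaemic stroke, cortical, old", "Small vessel disease"))
})

test_that("negated mentions yield no labels", {
  expect_identical(annotate_text("REPORT: Exclude subdural bleed.")$labels,
                   character(0))
  expect_identical(annotate_text("REPORT: No metastases.")$labels,
                   character(0))
  expect_identical(
    annotate_text("REPORT: Diffusely sclerotic metastases are much less likely.")$labels,
    character(0))
})

test_that("subarachnoid haemorrhage splits by aneurysmal attribution", {
  a <- annotate_text("REPORT: Subarachnoid haemorrhage secondary to a ruptured aneurysm.")
  expect_identical(a$labels, "Subarachnoid haemorrhage, aneurysmal")
  b <- annotate_text("REPORT: There is subarachnoid blood within the sulci.")
  expect_identical(b$labels, "Subarachnoid haemorrhage, other")
})

test_that("microbleed and tumour labels follow location and subtype", {
  expect_identical(
    annotate_text("REPORT: Several microbleeds are seen in the basal ganglia.")$labels,
    "Microbleed, deep")
  expect_identical(
    annotate_text("REPORT: There are multiple lobar microbleeds.")$labels,
    "Microbleed, lobar")
  expect_identical(
    annotate_text("REPORT: A single microbleed is noted.")$labels,
    "Microbleed, underspecified")
  expect_identical(
    annotate_text("REPORT: Appearances are typical of a glioblastoma.")$labels,
    "Tumour, glioma")
  expect_identical(
    annotate_text("REPORT: Multiple metastases are demonstrated.")$labels,
    "Tumour, metastasis")
})

test_that("labelling is a pure, deterministic function of its inputs", {
  ann <- annotate_text("REPORT: There is an old lacunar infarct in the pons.")
  l1 <- assign_labels(ann$entities, ann$relations)
  l2 <- assign_labels(ann$entities, ann$relations)
  expect_identical(l1, l2)
  expect_identical(l1$labels, "Ischaemic stroke, deep, old")
  # every label has non-empty provenance
  expect_true(all(lengths(l1$provenance[l1$labels]) > 0))
})

test_that("adding a negated entity never changes the label set", {
  ann <- annotate_text("REPORT: There is an acute thalamic infarct.")
  base <- assign_labels(ann$entities, ann$relations)$labels
  extra <- ann$entities[1, ]
  extra$id <- "T99"
  extra$type <- "haemorrhagic_stroke"
  extra$subtype <- NA_character_
  extra$negated <- TRUE
  with_neg <- assign_labels(rbind(ann$entities, extra), ann$relations)$labels
  expect_identical(with_neg, base)
})

test_that("removing a relation only moves a stroke label toward underspecified", {
  ann <- annotate_text("REPORT: There is an acute thalamic infarct.")
  full <- assign_labels(ann$entities, ann$relations)$labels
  expect_identical(full, "Ischaemic stroke, deep, recent")
  for (drop in seq_len(nrow(ann$relations))) {
    part <- assign_labels(ann$entities, ann$relations[-drop, , drop = FALSE])$labels
    expect_identical(part, "Ischaemic stroke, underspecified")
  }
})

test_that("relations targeting negated entities are ignored with a log line", {
  ann <- annotate_text("REPORT: No evidence of acute haemorrhage.")
  expect_true(any(ann$entities$negated))
  expect_identical(ann$labels, character(0))
  withr::local_options(radphen.verbose = TRUE)
  expect_message(assign_labels(ann$entities, ann$relations), "negated")
})
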