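# Synthetic radiology-report generator with gold annotations.
#
# Reports follow the request/body/conclusion structure of UK brain
# CT/MR reports. Each sampled phenotype label is realized by a sentence
# template that places a disease term and its required modifiers (as
# noun-phrase-internal adjectives, prepositional phrases or predicative
# complements), with exact gold character offsets. Negated distractor
# sentences, lexical variants and out-of-lexicon paraphrases are
# injected at configurable rates. Templates deliberately include the
# hard constructions of real reporting prose ("rather than", "much less
# likely", "blood in the subarachnoid spaces") as stress cases.

#' Phenotype prevalence profiles
#'
#' `validation_sample` reflects a 700-report random sample of unselected NHS
#' reports
#' used for external validation (n = 700; counts suppressed below 5 are
#' set to 2, the midpoint of the allowed range). `routine_practice`
#' reflects the label mix over a whole health board's scan archive
#' (n = 110,695): atrophy-heavy, with rare microbleeds.
#'
#' @param profile `"validation_sample"` or `"routine_practice"`.
#' @return Named numeric vector of per-report label probabilities over
#'   [phenotype_labels()].
#' @export
prevalence_profile <- function(profile = c("validation_sample", "routine_practice")) {
  profile <- match.arg(profile)
  labs <- phenotype_labels()
  counts <- switch(profile,
    validation_sample = c(164, 145, 2, 2, 2, 2, 2, 15, 26, 12, 41, 2, 15, 2, 8,
                     2, 7, 2, 2, 2, 2, 2, 37, 12) / 700,
    routine_practice = c(28757, 15015, 1609, 168, 397, 288, 415, 5702,
                         4385, 1860, 10636, 771, 9172, 279, 2272, 55, 1381,
                         15, 5, 19, 667, 1458, 2621, 4191) / 110695)
  setNames(counts, labs)
}

#' Configuration for the synthetic corpus generator
#'
#' @param n_reports Number of reports to generate (>= 1).
#' @param phenotype_prevalences Named per-label probabilities; defaults
#'   to the `validation_sample` profile.
#' @param negated_distractor_rate Probability that a report contains a
#'   negated-finding sentence ("No evidence of acute haemorrhage.").
#' @param variant_rate Probability that a mention uses a non-canonical
#'   lexical variant (spelling/hyphenation/synonym).
#' @param paraphrase_rate Probability that a disease mention uses an
#'   out-of-lexicon paraphrase; a stress knob emulating unseen phrasing.
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return List of class `synth_config`.
#' @export
synth_config <- function(n_reports,
                         phenotype_prevalences = prevalence_profile(),
                         negated_distractor_rate = 0.3,
                         variant_rate = 0.25,
                         paraphrase_rate = 0,
                         seed = 1L) {
  if (!is.numeric(n_reports) || n_reports < 1)
    stop("config error: n_reports must be >= 1")
  bad <- setdiff(names(phenotype_prevalences), phenotype_labels())
  if (length(bad))
    stop("config error: no template for label(s): ", paste(bad, collapse = "; "))
  p <- c(phenotype_prevalences, negated_distractor_rate, variant_rate,
         paraphrase_rate)
  if (any(p < 0 | p > 1)) stop("config error: probabilities must be in [0,1]")
  structure(list(n_reports = as.integer(n_reports),
                 phenotype_prevalences = phenotype_prevalences,
                 negated_distractor_rate = negated_distractor_rate,
                 variant_rate = variant_rate,
                 paraphrase_rate = paraphrase_rate,
                 seed = as.integer(seed)),
            class = "synth_config")
}

# ---- template vocabulary -------------------------------------------------

# first element of each pool is the canonical form
synth_vocab <- list(
  ischaemic_stroke = c("infarct", "infarction", "ischaemic change"),
  haemorrhagic_stroke = c("haemorrhage", "haematoma", "intracerebral haemorrhage"),
  stroke_unspecified = c("stroke", "cerebrovascular accident"),
  subarachnoid_haemorrhage = c("subarachnoid haemorrhage", "subarachnoid blood", "SAH"),
  subdural_haematoma = c("subdural haematoma", "subdural collection"),
  microbleed = c("microbleed", "microhaemorrhage"),
  haemorrhagic_transformation = c("haemorrhagic transformation"),
  atrophy = c("atrophy", "cerebral atrophy", "involution", "volume loss"),
  small_vessel_disease = c("small vessel disease", "small-vessel disease",
                           "microangiopathic change", "leukoaraiosis"),
  tumour_glioma = c("glioma", "glioblastoma", "astrocytoma"),
  tumour_meningioma = c("meningioma"),
  tumour_metastasis = c("metastasis", "secondary deposit"),
  tumour_other = c("tumour", "mass"),
  time_old = c("old", "chronic", "mature", "established", "long-standing"),
  time_recent = c("acute", "recent", "new", "fresh"),
  loc_deep_adj = c("lacunar", "thalamic", "deep", "pontine"),
  loc_cortical_adj = c("cortical", "frontal", "parietal", "temporal", "occipital"),
  hs_lobar_adj = c("lobar", "frontal", "parietal")
)

# out-of-lexicon paraphrases (must not be recognizable by the pipeline)
synth_paraphrases <- list(
  ischaemic_stroke = "area of encephalomalacia",
  haemorrhagic_stroke = "focus of hyperdensity",
  stroke_unspecified = "prior vascular insult",
  subarachnoid_haemorrhage = "sulcal hyperdensity",
  subdural_haematoma = "crescentic extra-axial fluid",
  microbleed = "susceptibility focus",
  haemorrhagic_transformation = "parenchymal staining",
  atrophy = "sulcal widening",
  small_vessel_disease = "leukoencephalopathy",
  tumour_glioma = "infiltrative intrinsic abnormality",
  tumour_meningioma = "dural-based abnormality",
  tumour_metastasis = "disseminated deposits of disease",
  tumour_other = "enhancing abnormality"
)

loc_pp <- list(
  deep = list(
    list(t = "in the basal ganglia", sub = "basal ganglia"),
    list(t = "in the left thalamus", sub = "thalamus"),
    list(t = "in the pons", sub = "pons"),
    list(t = "in the internal capsule", sub = "internal capsule")),
  cortical = list(
    list(t = "in the right frontal lobe", sub = "frontal lobe"),
    list(t = "in the left parietal lobe", sub = "parietal lobe"),
    list(t = "in the temporal lobe", sub = "temporal lobe"))
)

fr <- function(t, type = NULL, subtype = NA_character_, neg = FALSE,
               unc = FALSE, sub = NULL) {
  list(t = t, type = type, subtype = subtype, neg = neg, unc = unc, sub = sub)
}

indef_article <- function(following) {
  if (grepl("^[aeiou]", tolower(following))) "an" else "a"
}

# Assemble a sentence from fragments: text, entity table with offsets
# local to the sentence, relations between fragment indices.
realize_sentence <- function(frags, rels = NULL) {
  texts <- vapply(frags, `[[`, character(1), "t")
  starts <- integer(length(frags))
  off <- 0L
  for (i in seq_along(frags)) {
    starts[i] <- off
    off <- off + nchar(texts[i]) + 1L  # joining space
  }
  text <- paste0(paste(texts, collapse = " "), ".")
  ent_rows <- list()
  frag_ent <- rep(NA_integer_, length(frags))
  for (i in seq_along(frags)) {
    f <- frags[[i]]
    if (is.null(f$type)) next
    if (is.null(f$sub)) {
      s <- starts[i]; e <- starts[i] + nchar(f$t)
    } else {
      rel <- regexpr(f$sub, f$t, fixed = TRUE)
      s <- starts[i] + rel - 1L
      e <- s + attr(rel, "match.length")
    }
    ent_rows[[length(ent_rows) + 1L]] <- data.frame(
      type = f$type, subtype = f$subtype, start = s, end = e,
      negated = f$neg, uncertain = f$unc, stringsAsFactors = FALSE)
    frag_ent[i] <- length(ent_rows)
  }
  entities <- if (length(ent_rows)) do.call(rbind, ent_rows) else
    data.frame(type = character(0), subtype = character(0),
               start = integer(0), end = integer(0), negated = logical(0),
               uncertain = logical(0), stringsAsFactors = FALSE)
  relations <- data.frame(kind = character(0), modifier = integer(0),
                          target = integer(0), stringsAsFactors = FALSE)
  if (!is.null(rels) && nrow(rels)) {
    relations <- data.frame(kind = rels$kind,
                            modifier = frag_ent[rels$mod],
                            target = frag_ent[rels$target],
                            stringsAsFactors = FALSE)
  }
  list(text = text, entities = entities, relations = relations)
}

# ---- realizers -----------------------------------------------------------

pick1 <- function(x) x[[sample.int(length(x), 1L)]]

pick_term <- function(pool, variant_rate) {
  if (length(pool) > 1L && stats::runif(1) < variant_rate)
    pick1(pool[-1]) else pool[[1]]
}

# A stroke-like sentence with optional location and time modifiers.
# dis_key indexes synth_vocab/synth_paraphrases; loc/time in
# {NA,"deep","cortical"} x {NA,"old","recent"}; lobar_adj switches the
# cortical adjective pool for haemorrhagic stroke.
realize_stroke <- function(dis_type, dis_key, loc, time, cfg, paraphrase,
                           subtype = NA_character_, lobar_adj = FALSE) {
  dis_term <- if (paraphrase) synth_paraphrases[[dis_key]] else
    pick_term(synth_vocab[[dis_key]], cfg$variant_rate)
  dis_fr <- fr(dis_term, type = dis_type, subtype = subtype)
  time_term <- if (!is.na(time))
    pick_term(synth_vocab[[paste0("time_", time)]], cfg$variant_rate) else NA
  loc_mode <- if (!is.na(loc) && stats::runif(1) < 0.5) "adj" else "pp"
  loc_frag <- NULL
  if (!is.na(loc)) {
    if (loc_mode == "adj") {
      pool_key <- if (loc == "deep") "loc_deep_adj" else
        if (lobar_adj) "hs_lobar_adj" else "loc_cortical_adj"
      loc_frag <- fr(pick_term(synth_vocab[[pool_key]], cfg$variant_rate),
                     type = paste0("loc_", loc))
    } else {
      pp <- pick1(loc_pp[[loc]])
      loc_frag <- fr(pp$t, type = paste0("loc_", loc), sub = pp$sub)
    }
  }
  predicative <- !is.na(time) && stats::runif(1) < 0.4

  frags <- list(); rels <- data.frame()
  if (predicative) {
    # "The lacunar infarct is old." / "The infarct in the pons appears old."
    frags <- c(list(fr("The")),
               if (!is.null(loc_frag) && loc_mode == "adj") list(loc_frag),
               list(dis_fr),
               if (!is.null(loc_frag) && loc_mode == "pp") list(loc_frag),
               list(fr(pick1(c("is", "appears"))), fr(time_term,
                                                      type = paste0("time_", time))))
    di <- which(vapply(frags, function(f) identical(f$type, dis_type), logical(1)))
    ti <- length(frags)
    rels <- data.frame(kind = "time", mod = ti, target = di)
    if (!is.null(loc_frag)) {
      li <- which(vapply(frags, function(f)
        identical(f$type, paste0("loc_", loc)), logical(1)))
      rels <- rbind(rels, data.frame(kind = "location", mod = li, target = di))
    }
  } else {
    head_words <- c(if (!is.na(time)) time_term,
                    if (!is.null(loc_frag) && loc_mode == "adj") loc_frag$t,
                    dis_term)
    frags <- c(list(fr("There is"), fr(indef_article(head_words[1]))),
               if (!is.na(time)) list(fr(time_term, type = paste0("time_", time))),
               if (!is.null(loc_frag) && loc_mode == "adj") list(loc_frag),
               list(dis_fr),
               if (!is.null(loc_frag) && loc_mode == "pp") list(loc_frag))
    di <- which(vapply(frags, function(f) identical(f$type, dis_type), logical(1)))
    if (!is.na(time)) {
      ti <- which(vapply(frags, function(f)
        identical(f$type, paste0("time_", time)), logical(1)))
      rels <- rbind(rels, data.frame(kind = "time", mod = ti, target = di))
    }
    if (!is.null(loc_frag)) {
      li <- which(vapply(frags, function(f)
        identical(f$type, paste0("loc_", loc)), logical(1)))
      rels <- rbind(rels, data.frame(kind = "location", mod = li, target = di))
    }
  }
  # paraphrased mentions keep their gold modifiers but the disease span
  # is the paraphrase itself
  realize_sentence(frags, if (nrow(rels)) rels else NULL)
}

realize_presence <- function(dis_type, dis_key, cfg, paraphrase,
                             subtype = NA_character_) {
  term <- if (paraphrase) synth_paraphrases[[dis_key]] else
    pick_term(synth_vocab[[dis_key]], cfg$variant_rate)
  form <- sample.int(3L, 1L)
  if (form == 1L) {
    realize_sentence(list(fr("There is"), fr(indef_article(term)),
                          fr(term, type = dis_type, subtype = subtype)))
  } else if (form == 2L) {
    realize_sentence(list(fr("Appearances are in keeping with"),
                          fr(term, type = dis_type, subtype = subtype)))
  } else {
    realize_sentence(list(fr(term, type = dis_type, subtype = subtype),
                          fr("is demonstrated")))
  }
}

label_realizers <- function(cfg, paraphrase) {
  vr <- cfg$variant_rate
  list(
    "Atrophy" = function() {
      if (paraphrase)
        return(realize_sentence(list(fr("There is"),
                                     fr(synth_paraphrases$atrophy,
                                        type = "atrophy"))))
      term <- pick_term(synth_vocab$atrophy, vr)
      realize_sentence(list(fr("There is"),
                            fr(pick1(c("generalised", "moderate", "mild"))),
                            fr(term, type = "atrophy")))
    },
    "Small vessel disease" = function() {
      if (paraphrase)
        return(realize_sentence(list(fr("There is"),
                                     fr(synth_paraphrases$small_vessel_disease,
                                        type = "small_vessel_disease"))))
      term <- pick_term(synth_vocab$small_vessel_disease, vr)
      if (stats::runif(1) < 0.5) {
        frs <- list(fr("There is"), fr("established", type = "time_old"),
                    fr(term, type = "small_vessel_disease"))
        realize_sentence(frs, data.frame(kind = "time", mod = 2L, target = 3L))
      } else {
        realize_sentence(list(fr("Changes of"),
                              fr(term, type = "small_vessel_disease"),
                              fr("are present")))
      }
    },
    "Stroke, underspecified" = function() {
      term <- if (paraphrase) synth_paraphrases$stroke_unspecified else
        pick_term(synth_vocab$stroke_unspecified, vr)
      realize_sentence(list(fr("Appearances are in keeping with"),
                            fr(indef_article(term)),
                            fr(term, type = "stroke_unspecified")))
    },
    "Haemorrhagic stroke, deep, old" = function()
      realize_stroke("haemorrhagic_stroke", "haemorrhagic_stroke",
                     "deep", "old", cfg, paraphrase, lobar_adj = TRUE),
    "Haemorrhagic stroke, deep, recent" = function()
      realize_stroke("haemorrhagic_stroke", "haemorrhagic_stroke",
                     "deep", "recent", cfg, paraphrase, lobar_adj = TRUE),
    "Haemorrhagic stroke, lobar, old" = function()
      realize_stroke("haemorrhagic_stroke", "haemorrhagic_stroke",
                     "cortical", "old", cfg, paraphrase, lobar_adj = TRUE),
    "Haemorrhagic stroke, lobar, recent" = function()
      realize_stroke("haemorrhagic_stroke", "haemorrhagic_stroke",
                     "cortical", "recent", cfg, paraphrase, lobar_adj = TRUE),
    "Haemorrhagic stroke, underspecified" = function() {
      if (!paraphrase && stats::runif(1) < 0.3) {
        # the classic contrast construction: old blood, not new blood
        frs <- list(fr("I suspect this reflects redistribution of the"),
                    fr("original", type = "time_old"),
                    fr("haematoma", type = "haemorrhagic_stroke"),
                    fr("rather than"),
                    fr("new", type = "time_recent"),
                    fr("blood", type = "haemorrhagic_stroke", neg = TRUE))
        realize_sentence(frs, data.frame(kind = c("time", "time"),
                                         mod = c(2L, 5L), target = c(3L, 6L)))
      } else {
        realize_stroke("haemorrhagic_stroke", "haemorrhagic_stroke",
                       NA, NA, cfg, paraphrase)
      }
    },
    "Ischaemic stroke, cortical, old" = function()
      realize_stroke("ischaemic_stroke", "ischaemic_stroke",
                     "cortical", "old", cfg, paraphrase),
    "Ischaemic stroke, cortical, recent" = function()
      realize_stroke("ischaemic_stroke", "ischaemic_stroke",
                     "cortical", "recent", cfg, paraphrase),
    "Ischaemic stroke, deep, old" = function()
      realize_stroke("ischaemic_stroke", "ischaemic_stroke",
                     "deep", "old", cfg, paraphrase),
    "Ischaemic stroke, deep, recent" = function()
      realize_stroke("ischaemic_stroke", "ischaemic_stroke",
                     "deep", "recent", cfg, paraphrase),
    "Ischaemic stroke, underspecified" = function()
      realize_stroke("ischaemic_stroke", "ischaemic_stroke",
                     NA, NA, cfg, paraphrase),
    "Haemorrhagic transformation" = function()
      realize_presence("haemorrhagic_transformation",
                       "haemorrhagic_transformation", cfg, paraphrase),
    "Subdural haematoma" = function() {
      term <- if (paraphrase) synth_paraphrases$subdural_haematoma else
        pick_term(synth_vocab$subdural_haematoma, vr)
      realize_sentence(list(fr("There is"), fr(indef_article(term)),
                            fr(term, type = "subdural_haematoma"),
                            fr("over the"), fr(pick1(c("left", "right"))),
                            fr("convexity")))
    },
    "Subarachnoid haemorrhage, aneurysmal" = function() {
      term <- if (paraphrase) synth_paraphrases$subarachnoid_haemorrhage else
        pick_term(synth_vocab$subarachnoid_haemorrhage, vr)
      frs <- list(fr("There is"),
                  fr(term, type = "subarachnoid_haemorrhage"),
                  fr("secondary to a ruptured"),
                  fr("aneurysm", type = "mod_aneurysmal"))
      realize_sentence(frs, data.frame(kind = "attribute", mod = 4L,
                                       target = 2L))
    },
    "Subarachnoid haemorrhage, other" = function() {
      if (!paraphrase && stats::runif(1) < 0.3) {
        # prepositional paraphrase kept in-coverage via the pattern rules
        return(realize_sentence(list(
          fr("There is"),
          fr("blood in the subarachnoid spaces",
             type = "subarachnoid_haemorrhage"))))
      }
      term <- if (paraphrase) synth_paraphrases$subarachnoid_haemorrhage else
        pick_term(synth_vocab$subarachnoid_haemorrhage, vr)
      realize_sentence(list(fr("There is"),
                            fr(term, type = "subarachnoid_haemorrhage"),
                            fr("within the sulci")))
    },
    "Microbleed, deep" = function() {
      term <- if (paraphrase) synth_paraphrases$microbleed else
        paste0(pick_term(synth_vocab$microbleed, vr), "s")
      pp <- pick1(loc_pp$deep)
      frs <- list(fr("Several"), fr(term, type = "microbleed"),
                  fr("are seen"), fr(pp$t, type = "loc_deep", sub = pp$sub))
      realize_sentence(frs, data.frame(kind = "location", mod = 4L,
                                       target = 2L))
    },
    "Microbleed, lobar" = function() {
      term <- if (paraphrase) synth_paraphrases$microbleed else
        paste0(pick_term(synth_vocab$microbleed, vr), "s")
      frs <- list(fr("There are multiple"), fr("lobar", type = "loc_cortical"),
                  fr(term, type = "microbleed"))
      realize_sentence(frs, data.frame(kind = "location", mod = 2L,
                                       target = 3L))
    },
    "Microbleed, underspecified" = function() {
      term <- if (paraphrase) synth_paraphrases$microbleed else
        pick_term(synth_vocab$microbleed, vr)
      realize_sentence(list(fr("A single"), fr(term, type = "microbleed"),
                            fr("is noted")))
    },
    "Tumour, glioma" = function()
      realize_presence("tumour", "tumour_glioma", cfg, paraphrase,
                       subtype = "glioma"),
    "Tumour, meningioma" = function()
      realize_presence("tumour", "tumour_meningioma", cfg, paraphrase,
                       subtype = "meningioma"),
    "Tumour, metastasis" = function() {
      if (paraphrase)
        return(realize_sentence(list(
          fr("There are"), fr(synth_paraphrases$tumour_metastasis,
                              type = "tumour", subtype = "metastasis"))))
      if (stats::runif(1) < 0.5) {
        realize_sentence(list(fr("Multiple"),
                              fr("metastases", type = "tumour",
                                 subtype = "metastasis"),
                              fr("are demonstrated")))
      } else {
        term <- pick_term(synth_vocab$tumour_metastasis, vr)
        realize_sentence(list(fr("There is"), fr(indef_article(term)),
                              fr(term, type = "tumour",
                                 subtype = "metastasis")))
      }
    },
    "Tumour, other" = function() {
      term <- if (paraphrase) synth_paraphrases$tumour_other else
        pick_term(synth_vocab$tumour_other, vr)
      realize_sentence(list(fr("There is"), fr(indef_article(term)),
                            fr(term, type = "tumour", subtype = "other"),
                            fr("in the pineal region")))
    }
  )
}

distractor_sentences <- function() {
  list(
    realize_sentence(list(fr("No"),
                          fr("metastases", type = "tumour",
                             subtype = "metastasis", neg = TRUE))),
    realize_sentence(list(fr("No evidence of"),
                          fr("acute", type = "time_recent"),
                          fr("haemorrhage", type = "haemorrhagic_stroke",
                             neg = TRUE))),
    realize_sentence(list(fr("Exclude"),
                          fr("subdural bleed", type = "subdural_haematoma",
                             neg = TRUE))),
    realize_sentence(list(fr("Diffusely sclerotic"),
                          fr("metastases", type = "tumour",
                             subtype = "metastasis", neg = TRUE),
                          fr("are much less likely"))),
    realize_sentence(list(fr("There is no"),
                          fr("subdural collection",
                             type = "subdural_haematoma", neg = TRUE))),
    realize_sentence(list(fr("No"), fr("acute", type = "time_recent"),
                          fr("infarct", type = "ischaemic_stroke",
                             neg = TRUE),
                          fr("is identified")))
  )
}

filler_sentences <- function() {
  c("The ventricles are normal in size.",
    "Normal grey-white differentiation.",
    "The basal cisterns are patent.",
    "No midline shift.",
    "The orbits are unremarkable.")
}

request_pool <- function() {
  list(
    list(text = "?stroke.", entities = data.frame(
      type = "stroke_unspecified", subtype = NA_character_,
      start = 1L, end = 7L, negated = FALSE, uncertain = TRUE,
      stringsAsFactors = FALSE)),
    list(text = "Sudden onset weakness.", entities = NULL),
    list(text = "Confusion and falls.", entities = NULL),
    list(text = "Known malignancy, assess for intracranial involvement.",
         entities = NULL),
    list(text = "Collapse, cause unclear.", entities = NULL)
  )
}

conclusion_generic <- function() {
  c("No significant interval change.", "Stable appearances.",
    "Satisfactory study.")
}

# ---- generator -----------------------------------------------------------

#' Generate a synthetic annotated corpus
#'
#' Samples a label set per report from the configured prevalences,
#' realizes each label as a findings sentence with gold entities and
#' relations at exact offsets, injects negated distractors and lexical
#' variants, wraps everything in request/body/conclusion sections, and
#' returns reports paired with gold standoff annotations. By
#' construction, [assign_labels()] on the gold entities and relations
#' reproduces the intended label set of every report. Fully
#' deterministic given the seed.
#'
#' @param config A [synth_config()].
#' @return List of length `n_reports`; each element has `report` (a
#'   `radphen_report`) and `gold` (a `standoff_doc` whose `labels` are
#'   the intended phenotypes).
#' @export
generate_corpus <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  prev <- config$phenotype_prevalences
  reqs <- request_pool()
  gens <- conclusion_generic()
  fills <- filler_sentences()

  lapply(seq_len(config$n_reports), function(r) {
    labels <- names(prev)[stats::runif(length(prev)) < prev]
    # one paraphrase decision per (report, label), reused on restatement
    para <- stats::runif(length(labels)) < config$paraphrase_rate
    names(para) <- labels

    sents <- list()  # each: list(text, entities, relations, section)
    add_sent <- function(s, section) {
      s$section <- section
      sents[[length(sents) + 1L]] <<- s
    }

    req <- pick1(reqs)
    add_sent(list(text = req$text,
                  entities = if (is.null(req$entities))
                    data.frame(type = character(0), subtype = character(0),
                               start = integer(0), end = integer(0),
                               negated = logical(0), uncertain = logical(0))
                  else req$entities,
                  relations = data.frame(kind = character(0),
                                         modifier = integer(0),
                                         target = integer(0))),
             "request")

    body <- list()
    for (lab in labels) {
      rl <- label_realizers(config, para[[lab]])[[lab]]
      body[[length(body) + 1L]] <- rl()
    }
    n_fill <- sample.int(3L, 1L) - 1L
    for (k in seq_len(n_fill)) {
      body[[length(body) + 1L]] <- list(
        text = pick1(fills),
        entities = data.frame(type = character(0), subtype = character(0),
                              start = integer(0), end = integer(0),
                              negated = logical(0), uncertain = logical(0)),
        relations = data.frame(kind = character(0), modifier = integer(0),
                               target = integer(0)))
    }
    if (stats::runif(1) < config$negated_distractor_rate) {
      body[[length(body) + 1L]] <- pick1(distractor_sentences())
    }
    if (!length(body)) {
      body[[1L]] <- list(
        text = pick1(fills),
        entities = data.frame(type = character(0), subtype = character(0),
                              start = integer(0), end = integer(0),
                              negated = logical(0), uncertain = logical(0)),
        relations = data.frame(kind = character(0), modifier = integer(0),
                               target = integer(0)))
    }
    body <- body[sample.int(length(body))]
    for (s in body) add_sent(s, "body")

    if (length(labels) && stats::runif(1) < 0.5) {
      lab <- pick1(labels)
      add_sent(label_realizers(config, para[[lab]])[[lab]](), "conclusion")
    } else {
      add_sent(list(text = pick1(gens),
                    entities = data.frame(type = character(0),
                                          subtype = character(0),
                                          start = integer(0), end = integer(0),
                                          negated = logical(0),
                                          uncertain = logical(0)),
                    relations = data.frame(kind = character(0),
                                           modifier = integer(0),
                                           target = integer(0))),
               "conclusion")
    }

    # assemble text with global offsets
    headers <- c(request = "CLINICAL DETAILS: ", body = "\nREPORT: ",
                 conclusion = "\nCONCLUSION: ")
    text <- ""
    cur_section <- ""
    ent_all <- list(); rel_all <- list()
    sid <- 0L
    for (s in sents) {
      sid <- sid + 1L
      prefix <- if (s$section != cur_section) headers[[s$section]] else " "
      cur_section <- s$section
      text <- paste0(text, prefix)
      off <- nchar(text)
      text <- paste0(text, s$text)
      if (nrow(s$entities)) {
        e <- s$entities
        e$start <- e$start + off
        e$end <- e$end + off
        e$sentence_id <- sid
        e$section_kind <- s$section
        e$.rel <- seq_len(nrow(e))
        e$.sid <- sid
        ent_all[[length(ent_all) + 1L]] <- e
      }
      if (nrow(s$relations)) {
        rel_all[[length(rel_all) + 1L]] <- cbind(s$relations, .sid = sid)
      }
    }
    text <- paste0(text, "\n")

    entities <- if (length(ent_all)) do.call(rbind, ent_all) else
      empty_entities()
    if (nrow(entities)) {
      entities$id <- sprintf("T%d", seq_len(nrow(entities)))
    }
    relations <- empty_relations()
    rels_raw <- if (length(rel_all)) do.call(rbind, rel_all) else NULL
    if (!is.null(rels_raw) && nrow(rels_raw)) {
      idmap <- function(sid, local) entities$id[entities$.sid == sid][local]
      relations <- data.frame(
        id = sprintf("R%d", seq_len(nrow(rels_raw))),
        kind = rels_raw$kind,
        modifier_id = mapply(idmap, rels_raw$.sid, rels_raw$modifier),
        target_id = mapply(idmap, rels_raw$.sid, rels_raw$target),
        stringsAsFactors = FALSE)
    }
    entities$.rel <- NULL; entities$.sid <- NULL

    id <- sprintf("synth-%05d", r)
    gold <- standoff_doc(text, entities, relations, labels)
    gold$entities$sentence_id <- entities$sentence_id
    gold$entities$section_kind <- entities$section_kind
    list(report = zone_report(text, report_id = id), gold = gold,
         report_id = id)
  })
}

#' Corpus summary statistics
#'
#' Counts reports, sentences, tokens, disease and modifier entities and
#' labels over a corpus with gold annotations. Counts are additive over
#' corpus concatenation.
#'
#' @param corpus List of `list(report, gold)` pairs as produced by
#'   [generate_corpus()], or parallel lists via `gold`.
#' @param gold Optional list of `standoff_doc`s parallel to `corpus`
#'   when `corpus` is a list of `radphen_report`s.
#' @return List with `summary` (data frame of overall counts) and
#'   `per_label` (data frame of per-phenotype label counts).
#' @export
corpus_stats <- function(corpus, gold = NULL) {
  if (is.null(gold)) {
    reports <- lapply(corpus, `[[`, "report")
    gold <- lapply(corpus, `[[`, "gold")
  } else reports <- corpus
  stopifnot(length(reports) == length(gold))
  n_sent <- 0L; n_tok <- 0L
  for (rep in reports) {
    for (si in seq_len(nrow(rep$sections))) {
      if (rep$sections$end[si] <= rep$sections$start[si]) next
      ss <- segment(rep$sections$text[si], rep$sections$kind[si])
      n_sent <- n_sent + length(ss)
      n_tok <- n_tok + sum(vapply(ss, function(s) nrow(s$tokens), integer(1)))
    }
  }
  ents <- do.call(rbind, c(list(empty_entities()),
                           lapply(gold, function(g)
                             g$entities[, names(empty_entities())[
                               names(empty_entities()) %in% names(g$entities)],
                               drop = FALSE])))
  all_labels <- unlist(lapply(gold, `[[`, "labels"))
  per_label <- data.frame(label = phenotype_labels(),
                          count = vapply(phenotype_labels(), function(l)
                            sum(all_labels == l), integer(1)),
                          row.names = NULL, stringsAsFactors = FALSE)
  list(summary = data.frame(
    stat = c("reports", "sentences", "tokens", "disease_entities",
             "modifier_entities", "total_labels"),
    value = c(length(reports), n_sent, n_tok,
              sum(ents$type %in% disease_types()),
              sum(ents$type %in% modifier_types()),
              length(all_labels)),
    stringsAsFactors = FALSE),
    per_label = per_label)
}
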