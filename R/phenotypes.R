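#' The 24 report-level phenotype labels
#'
#' The closed set of document-level phenotype labels assigned by the
#' pipeline: presence findings (atrophy, small vessel disease, subdural
#' haematoma, haemorrhagic transformation), stroke labels stratified by
#' type, location and age, subarachnoid haemorrhage by aetiology,
#' microbleeds by location, and tumours by subtype.
#'
#' @return Character vector of length 24, in canonical display order.
#' @export
#' @examples
#' phenotype_labels()
phenotype_labels <- function() {
  c(
    "Atrophy",
    "Small vessel disease",
    "Stroke, underspecified",
    "Haemorrhagic stroke, deep, old",
    "Haemorrhagic stroke, deep, recent",
    "Haemorrhagic stroke, lobar, old",
    "Haemorrhagic stroke, lobar, recent",
    "Haemorrhagic stroke, underspecified",
    "Ischaemic stroke, cortical, old",
    "Ischaemic stroke, cortical, recent",
    "Ischaemic stroke, deep, old",
    "Ischaemic stroke, deep, recent",
    "Ischaemic stroke, underspecified",
    "Haemorrhagic transformation",
    "Subdural haematoma",
    "Subarachnoid haemorrhage, aneurysmal",
    "Subarachnoid haemorrhage, other",
    "Microbleed, deep",
    "Microbleed, lobar",
    "Microbleed, underspecified",
    "Tumour, glioma",
    "Tumour, meningioma",
    "Tumour, metastasis",
    "Tumour, other"
  )
}

#' Disease and modifier entity types
#'
#' Disease entities are the findings themselves; modifier entities carry
#' time (recent/old), location (deep/cortical) or aneurysmal attribution
#' and attach to disease entities through relations.
#'
#' @return Character vector of type names.
#' @export
disease_types <- function() {
  c("ischaemic_stroke", "haemorrhagic_stroke", "stroke_unspecified",
    "subarachnoid_haemorrhage", "subdural_haematoma", "microbleed",
    "haemorrhagic_transformation", "atrophy", "small_vessel_disease",
    "tumour")
}

#' @rdname disease_types
#' @export
modifier_types <- function() {
  c("time_recent", "time_old", "loc_deep", "loc_cortical", "mod_aneurysmal")
}

#' Aggregate phenotype groups
#'
#' Groups of sub-labels pooled into "any" rows of an evaluation table:
#' a report counts as positive for the group if it carries any member
#' label.
#'
#' @return Named list of character vectors of member labels.
#' @export
phenotype_groups <- function() {
  labs <- phenotype_labels()
  list(
    "Any ischaemic stroke"    = grep("^Ischaemic stroke",    labs, value = TRUE),
    "Any haemorrhagic stroke" = grep("^Haemorrhagic stroke", labs, value = TRUE),
    "Any tumour"              = grep("^Tumour",              labs, value = TRUE)
  )
}
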