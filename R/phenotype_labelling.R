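# Mapping from entities and relations to the 24 document-level
# phenotype labels.

radphen_log <- function(...) {
  if (isTRUE(getOption("radphen.verbose"))) message(sprintf(...))
}

#' Assign document-level phenotype labels
#'
#' Maps a report's entities and relations to its set of phenotype
#' labels. Rules are applied per disease entity and unioned over the
#' report:
#' \itemize{
#'   \item presence phenotypes (atrophy, small vessel disease, subdural
#'     haematoma, haemorrhagic transformation): a non-negated entity in
#'     the body or conclusion suffices;
#'   \item ischaemic stroke with both a location (deep/cortical) and a
#'     time (old/recent) relation yields the fully specified label; an
#'     incomplete pair yields "Ischaemic stroke, underspecified";
#'   \item haemorrhagic stroke analogously, with the cortical location
#'     rendered as "lobar";
#'   \item an unspecified stroke entity yields "Stroke, underspecified";
#'   \item microbleed location maps deep/lobar, defaulting to
#'     underspecified;
#'   \item subarachnoid haemorrhage is "aneurysmal" when an aneurysmal
#'     modifier is linked or present in the same sentence, else "other";
#'   \item tumours take their lexicon subtype.
#' }
#' Negated entities, and entities in the request section, never yield
#' labels. Relations whose target is negated are ignored (logged when
#' `options(radphen.verbose = TRUE)`). Labels form a set: duplicate
#' evidence yields one label.
#'
#' @param entities Entity data frame with columns `id`, `type`,
#'   `subtype`, `sentence_id`, `section_kind`, `negated`, `uncertain`.
#' @param relations Relation data frame with columns `kind`,
#'   `modifier_id`, `target_id`.
#' @param report_id Identifier carried through to the result.
#' @return A labelled report: list with `report_id`, `labels` (sorted
#'   character vector, subset of [phenotype_labels()]) and `provenance`
#'   (named list mapping label to supporting entity ids).
#' @export
assign_labels <- function(entities, relations = empty_relations(),
                          report_id = "report") {
  labels <- character(0)
  provenance <- list()
  add <- function(lab, ids) {
    labels <<- c(labels, lab)
    provenance[[lab]] <<- unique(c(provenance[[lab]], ids))
  }

  if (nrow(relations) && nrow(entities)) {
    neg_ids <- entities$id[entities$negated]
    bad <- relations$target_id %in% neg_ids
    if (any(bad)) {
      radphen_log("ignoring %d relation(s) targeting negated entities",
                  sum(bad))
      relations <- relations[!bad, , drop = FALSE]
    }
  }

  eligible <- which(entities$type %in% disease_types() &
                      !entities$negated &
                      entities$section_kind %in% c("body", "conclusion"))
  mod_type_of <- setNames(entities$type, entities$id)

  for (i in eligible) {
    e <- entities[i, ]
    rels <- relations[relations$target_id == e$id, , drop = FALSE]
    mtypes <- unname(mod_type_of[rels$modifier_id])
    loc <- mtypes[mtypes %in% c("loc_deep", "loc_cortical")]
    tim <- mtypes[mtypes %in% c("time_old", "time_recent")]
    loc1 <- if (length(loc)) sub("^loc_", "", loc[1]) else NA
    tim1 <- if (length(tim)) sub("^time_", "", tim[1]) else NA

    lab <- switch(e$type,
      atrophy = "Atrophy",
      small_vessel_disease = "Small vessel disease",
      subdural_haematoma = "Subdural haematoma",
      haemorrhagic_transformation = "Haemorrhagic transformation",
      stroke_unspecified = "Stroke, underspecified",
      ischaemic_stroke = if (!is.na(loc1) && !is.na(tim1))
        sprintf("Ischaemic stroke, %s, %s", loc1, tim1)
      else "Ischaemic stroke, underspecified",
      haemorrhagic_stroke = if (!is.na(loc1) && !is.na(tim1))
        sprintf("Haemorrhagic stroke, %s, %s",
                ifelse(loc1 == "cortical", "lobar", loc1), tim1)
      else "Haemorrhagic stroke, underspecified",
      microbleed = sprintf("Microbleed, %s",
                           if (is.na(loc1)) "underspecified"
                           else if (loc1 == "cortical") "lobar" else "deep"),
      subarachnoid_haemorrhage = {
        linked_aneur <- "mod_aneurysmal" %in% mtypes
        same_sent <- any(entities$type == "mod_aneurysmal" &
                           entities$sentence_id == e$sentence_id)
        sprintf("Subarachnoid haemorrhage, %s",
                if (linked_aneur || same_sent) "aneurysmal" else "other")
      },
      tumour = sprintf("Tumour, %s",
                       if (!is.na(e$subtype) &&
                             e$subtype %in% c("glioma", "meningioma",
                                              "metastasis")) e$subtype
                       else "other"),
      NULL)
    if (!is.null(lab)) add(lab, e$id)
  }

  bad <- setdiff(labels, phenotype_labels())
  if (length(bad)) stop("internal error: label outside taxonomy: ",
                        paste(bad, collapse = ", "))
  list(report_id = report_id, labels = sort(unique(labels)),
       provenance = provenance)
}
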