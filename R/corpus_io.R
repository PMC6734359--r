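# Report reading, section zoning and brat standoff interchange.
# All character offsets are 0-based, half-open, counted after CRLF -> LF
# normalization, so they are directly interchangeable with brat standoff.

substr0 <- function(text, start, end) {
  # 0-based half-open interval into text
  if (end <= start) return("")
  substr(text, start + 1L, end)
}

normalize_newlines <- function(x) gsub("\r\n?", "\n", x)

#' Default section-heading patterns
#'
#' Radiology reports in UK practice are conventionally structured as a
#' clinical request, a findings body and a conclusion. Headings are
#' matched case-insensitively at line start, followed by a colon or end
#' of line. The set is fully overridable because heading conventions vary
#' between departments.
#'
#' @return Named list mapping section kind (`request`, `body`,
#'   `conclusion`) to a character vector of heading phrases.
#' @export
default_heading_patterns <- function() {
  list(
    request    = c("clinical details", "clinical history", "clinical indication",
                   "history", "indication"),
    body       = c("report", "findings"),
    conclusion = c("conclusion", "conclusions", "impression", "comment",
                   "opinion", "summary")
  )
}

#' Zone a raw report into request, body and conclusion sections
#'
#' Splits the raw text of a radiology report into its request, body and
#' conclusion sections by matching configurable heading patterns with
#' regular expressions. Text before any heading defaults to the body.
#' Zoning is lossless: every character belongs either to exactly one
#' section span or to a heading; concatenating headings and section texts
#' in offset order reproduces the raw text.
#'
#' @param raw_text Report text (single string, non-empty).
#' @param report_id Identifier to attach to the report.
#' @param heading_patterns Named list as [default_heading_patterns()].
#' @return An object of class `radphen_report`: a list with `report_id`,
#'   `raw_text` (newline-normalized), `modality` (`"CT"`, `"MR"` or
#'   `"unknown"`), and `sections`, a data frame with columns `kind`,
#'   `start`, `end` (0-based half-open into `raw_text`) and `text`.
#'   All three kinds are always present; missing sections have empty
#'   spans.
#' @export
#' @examples
#' r <- zone_report("CLINICAL DETAILS: ?stroke\nREPORT: Mature infarct.\nCONCLUSION: Old infarct.")
#' r$sections
zone_report <- function(raw_text, report_id = "report",
                        heading_patterns = default_heading_patterns()) {
  stopifnot(is.character(raw_text), length(raw_text) == 1L, nzchar(raw_text))
  text <- normalize_newlines(raw_text)

  kinds <- rep(names(heading_patterns), lengths(heading_patterns))
  phrases <- unlist(heading_patterns, use.names = FALSE)
  # heading at line start, optional indentation, colon (consuming trailing
  # blanks) or bare end of line
  pats <- sprintf("(?mi)^[ \t]*%s[ \t]*(:[ \t]*|(?=\n)|$)", gsub(" ", "[ \t]+", phrases))

  hits <- data.frame(start = integer(0), end = integer(0), kind = character(0))
  for (i in seq_along(pats)) {
    m <- gregexpr(pats[i], text, perl = TRUE)[[1]]
    if (m[1] == -1L) next
    hits <- rbind(hits, data.frame(
      start = as.integer(m) - 1L,
      end   = as.integer(m) + attr(m, "match.length") - 1L,
      kind  = kinds[i]))
  }
  hits <- hits[order(hits$start), , drop = FALSE]
  # overlapping matches of different phrases ("clinical details" vs
  # "clinical history"): keep the earliest, longest
  if (nrow(hits) > 1L) {
    keep <- rep(TRUE, nrow(hits))
    last_end <- -1L
    for (i in seq_len(nrow(hits))) {
      if (hits$start[i] < last_end) keep[i] <- FALSE
      else last_end <- hits$end[i]
    }
    hits <- hits[keep, , drop = FALSE]
  }

  seg <- data.frame(kind = character(0), start = integer(0), end = integer(0))
  n <- nchar(text)
  if (nrow(hits) == 0L) {
    seg <- data.frame(kind = "body", start = 0L, end = n)
  } else {
    if (hits$start[1] > 0L)
      seg <- rbind(seg, data.frame(kind = "body", start = 0L, end = hits$start[1]))
    for (i in seq_len(nrow(hits))) {
      s <- hits$end[i]
      e <- if (i < nrow(hits)) hits$start[i + 1L] else n
      seg <- rbind(seg, data.frame(kind = hits$kind[i], start = s, end = e))
    }
  }
  seg <- seg[seg$end >= seg$start, , drop = FALSE]
  # guarantee all three kinds exist (empty spans appended at text end)
  for (k in c("request", "body", "conclusion")) {
    if (!k %in% seg$kind) seg <- rbind(seg, data.frame(kind = k, start = n, end = n))
  }
  seg$text <- vapply(seq_len(nrow(seg)), function(i)
    substr0(text, seg$start[i], seg$end[i]), character(1))
  rownames(seg) <- NULL

  modality <- if (grepl("\\bMRI?\\b|magnetic resonance", text, ignore.case = TRUE)) "MR"
  else if (grepl("\\bCT\\b|computed tomography", text, ignore.case = TRUE)) "CT"
  else "unknown"

  structure(list(report_id = report_id, raw_text = text,
                 sections = seg, modality = modality),
            class = "radphen_report")
}

#' @export
print.radphen_report <- function(x, ...) {
  cat(sprintf("<radphen_report> %s (%s), %d chars\n", x$report_id,
              x$modality, nchar(x$raw_text)))
  nz <- x$sections[x$sections$end > x$sections$start, , drop = FALSE]
  for (i in seq_len(nrow(nz)))
    cat(sprintf("  %-10s [%d,%d)\n", nz$kind[i], nz$start[i], nz$end[i]))
  invisible(x)
}

#' Concatenated text of one section kind
#'
#' @param report A `radphen_report`.
#' @param kind `"request"`, `"body"` or `"conclusion"`.
#' @return Single string (possibly empty).
#' @export
section_text <- function(report, kind) {
  paste(report$sections$text[report$sections$kind == kind], collapse = "")
}

#' Read reports from disk
#'
#' Reads plain-text reports (one per `.txt` file) or brat standoff pairs
#' (`.txt` plus `.ann`). Text is newline-normalized (CRLF to LF) but
#' otherwise preserved byte for byte. Empty files are skipped with a
#' warning.
#'
#' @param path Directory containing report files, or a single file.
#' @param format `"plain"` or `"standoff"`.
#' @param heading_patterns Passed to [zone_report()].
#' @return List of `radphen_report` objects; in standoff mode each has a
#'   `gold` element holding the parsed annotations (see
#'   [read_standoff()]).
#' @export
read_reports <- function(path, format = c("plain", "standoff"),
                         heading_patterns = default_heading_patterns()) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("path does not exist: ", path)
  files <- if (dir.exists(path)) {
    sort(list.files(path, pattern = "\\.txt$", full.names = TRUE))
  } else path

  out <- list()
  for (f in files) {
    txt <- tryCatch(readChar(f, file.size(f), useBytes = FALSE),
                    error = function(e) stop("cannot read file: ", f, call. = FALSE))
    if (!nzchar(trimws(txt))) {
      warning("skipping empty report file: ", f)
      next
    }
    id <- tools::file_path_sans_ext(basename(f))
    rep <- zone_report(txt, report_id = id, heading_patterns = heading_patterns)
    if (format == "standoff") {
      ann <- sub("\\.txt$", ".ann", f)
      rep$gold <- if (file.exists(ann)) read_standoff(f) else NULL
    }
    out[[length(out) + 1L]] <- rep
  }
  out
}

empty_entities <- function() {
  data.frame(id = character(0), type = character(0), subtype = character(0),
             start = integer(0), end = integer(0), surface = character(0),
             sentence_id = integer(0), section_kind = character(0),
             negated = logical(0), uncertain = logical(0),
             stringsAsFactors = FALSE)
}

empty_relations <- function() {
  data.frame(id = character(0), kind = character(0),
             modifier_id = character(0), target_id = character(0),
             stringsAsFactors = FALSE)
}

#' Construct a standoff annotation document
#'
#' A standoff document pairs raw text with offset-anchored entity,
#' relation and attribute records plus a set of document-level phenotype
#' labels, mirroring the brat annotation model.
#'
#' @param text Document text.
#' @param entities Data frame with columns `id`, `type`, `subtype`,
#'   `start`, `end`, `surface`, `negated`, `uncertain` (missing columns
#'   are filled with defaults).
#' @param relations Data frame with columns `id`, `kind`, `modifier_id`,
#'   `target_id`.
#' @param labels Character vector of document-level phenotype labels.
#' @return Object of class `standoff_doc`.
#' @export
standoff_doc <- function(text, entities = empty_entities(),
                         relations = empty_relations(), labels = character(0)) {
  text <- normalize_newlines(text)
  defaults <- list(subtype = NA_character_, surface = NA_character_,
                   sentence_id = NA_integer_, section_kind = NA_character_,
                   negated = FALSE, uncertain = FALSE)
  for (col in names(defaults))
    if (is.null(entities[[col]])) entities[[col]] <- rep(defaults[[col]],
                                                         nrow(entities))
  if (nrow(entities)) {
    entities$surface <- vapply(seq_len(nrow(entities)), function(i)
      substr0(text, entities$start[i], entities$end[i]), character(1))
    if (anyDuplicated(entities$id)) stop("entity ids not unique")
  }
  if (nrow(relations)) {
    bad <- setdiff(c(relations$modifier_id, relations$target_id), entities$id)
    if (length(bad)) stop("relation references unknown entity id: ",
                          paste(bad, collapse = ", "))
  }
  structure(list(text = text, entities = entities, relations = relations,
                 labels = sort(unique(labels))), class = "standoff_doc")
}

encode_label <- function(x) gsub(" ", "_", x, fixed = TRUE)
decode_label <- function(x) gsub("_", " ", x, fixed = TRUE)

#' Write a standoff document as a brat .txt/.ann pair
#'
#' Entities become `T` lines, relations `R` lines, and negation,
#' uncertainty, subtype and document-label attributes become `A` lines
#' (document labels are written against a synthetic whole-document
#' target so they survive the round trip).
#'
#' @param doc A `standoff_doc`.
#' @param prefix Output path without extension; `prefix.txt` and
#'   `prefix.ann` are written.
#' @return Invisibly, the two file paths.
#' @export
write_standoff <- function(doc, prefix) {
  stopifnot(inherits(doc, "standoff_doc"))
  ent <- doc$entities
  if (nrow(ent)) {
    bad <- ent$start < 0 | ent$end > nchar(doc$text) | ent$end <= ent$start
    if (any(bad)) stop("entity span outside text: ",
                       paste(ent$id[bad], collapse = ", "))
  }
  txt_path <- paste0(prefix, ".txt")
  ann_path <- paste0(prefix, ".ann")
  writeLines(doc$text, txt_path, sep = "", useBytes = TRUE)

  lines <- character(0)
  tmap <- setNames(sprintf("T%d", seq_len(nrow(ent))), ent$id)
  a <- 0L
  for (i in seq_len(nrow(ent))) {
    surf <- gsub("\n", " ", substr0(doc$text, ent$start[i], ent$end[i]))
    lines <- c(lines, sprintf("%s\t%s %d %d\t%s", tmap[[ent$id[i]]],
                              ent$type[i], ent$start[i], ent$end[i], surf))
    if (!is.na(ent$subtype[i]) && nzchar(ent$subtype[i])) {
      a <- a + 1L
      lines <- c(lines, sprintf("A%d\tsubtype %s %s", a, tmap[[ent$id[i]]],
                                ent$subtype[i]))
    }
    if (isTRUE(ent$negated[i])) {
      a <- a + 1L
      lines <- c(lines, sprintf("A%d\tnegated %s", a, tmap[[ent$id[i]]]))
    }
    if (isTRUE(ent$uncertain[i])) {
      a <- a + 1L
      lines <- c(lines, sprintf("A%d\tuncertain %s", a, tmap[[ent$id[i]]]))
    }
  }
  rel <- doc$relations
  for (i in seq_len(nrow(rel))) {
    lines <- c(lines, sprintf("R%d\t%s Arg1:%s Arg2:%s", i, rel$kind[i],
                              tmap[[rel$modifier_id[i]]], tmap[[rel$target_id[i]]]))
  }
  for (lab in doc$labels) {
    a <- a + 1L
    lines <- c(lines, sprintf("A%d\tlabel Doc %s", a, encode_label(lab)))
  }
  writeLines(lines, ann_path, useBytes = TRUE)
  invisible(c(txt = txt_path, ann = ann_path))
}

#' Read a brat .txt/.ann pair
#'
#' @param path Path to the `.txt` file (or prefix without extension);
#'   the `.ann` file is expected beside it.
#' @return A `standoff_doc`.
#' @export
read_standoff <- function(path) {
  prefix <- sub("\\.(txt|ann)$", "", path)
  txt_path <- paste0(prefix, ".txt")
  ann_path <- paste0(prefix, ".ann")
  if (!file.exists(txt_path)) stop("missing text file: ", txt_path)
  if (!file.exists(ann_path)) stop("missing annotation file: ", ann_path)
  text <- normalize_newlines(readChar(txt_path, file.size(txt_path)))
  lines <- readLines(ann_path, warn = FALSE)
  lines <- lines[nzchar(lines)]

  ent <- empty_entities(); rel <- empty_relations(); labels <- character(0)
  neg <- character(0); unc <- character(0); subtys <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    id <- parts[1]
    if (startsWith(id, "T")) {
      hdr <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      ent <- rbind(ent, data.frame(
        id = id, type = hdr[1], subtype = NA_character_,
        start = as.integer(hdr[2]), end = as.integer(hdr[3]),
        surface = NA_character_, sentence_id = NA_integer_,
        section_kind = NA_character_, negated = FALSE, uncertain = FALSE,
        stringsAsFactors = FALSE))
    } else if (startsWith(id, "R")) {
      hdr <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      rel <- rbind(rel, data.frame(
        id = id, kind = hdr[1],
        modifier_id = sub("^Arg1:", "", hdr[2]),
        target_id = sub("^Arg2:", "", hdr[3]), stringsAsFactors = FALSE))
    } else if (startsWith(id, "A")) {
      hdr <- strsplit(parts[2], " ", fixed = TRUE)[[1]]
      switch(hdr[1],
             negated   = { neg <- c(neg, hdr[2]) },
             uncertain = { unc <- c(unc, hdr[2]) },
             subtype   = { subtys[[hdr[2]]] <- hdr[3] },
             label     = { labels <- c(labels, decode_label(hdr[3])) })
    }
  }
  if (nrow(ent)) {
    ent$negated <- ent$id %in% neg
    ent$uncertain <- ent$id %in% unc
    for (id in names(subtys)) ent$subtype[ent$id == id] <- subtys[[id]]
  }
  standoff_doc(text, ent, rel, labels)
}

#' Write labelled reports as JSON lines
#'
#' One JSON object per report with `report_id`, `labels` and the entity
#' table, a convenient machine-readable export alongside brat standoff.
#'
#' @param annotations List of annotation results (see [annotate_report()])
#'   or labelled-report lists with `report_id` and `labels`.
#' @param path Output file.
#' @return Invisibly, `path`.
#' @export
write_jsonl <- function(annotations, path) {
  con <- file(path, open = "w")
  on.exit(close(con))
  for (a in annotations) {
    rec <- list(report_id = a$report_id, labels = as.list(a$labels))
    if (!is.null(a$entities) && nrow(a$entities)) {
      rec$entities <- a$entities[, c("id", "type", "subtype", "start", "end",
                                     "surface", "negated")]
    }
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, null = "null",
                                na = "null"), con)
  }
  invisible(path)
}
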