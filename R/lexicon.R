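# Domain lexicons: disease and modifier terms with spelling/hyphenation
# variant expansion and longest-match lookup over lemmas.

fusable_prefixes <- c("intra", "extra", "peri", "sub", "infra")

expand_variant_strings <- function(variants) {
  step <- function(vs) {
    out <- vs
    for (v in vs) {
      # British/American ae -> e spelling pair
      if (grepl("ae", v, fixed = TRUE))
        out <- c(out, gsub("ae", "e", v, fixed = TRUE))
      words <- strsplit(v, " ", fixed = TRUE)[[1]]
      for (wi in seq_along(words)) {
        w <- words[wi]
        pre <- fusable_prefixes[startsWith(w, paste0(fusable_prefixes, "-")) |
                                  (startsWith(w, fusable_prefixes) &
                                     nchar(w) >= nchar(fusable_prefixes) + 4)]
        if (!length(pre)) next
        p <- pre[which.max(nchar(pre))]
        rest <- sub(paste0("^", p, "-?"), "", w)
        if (nchar(rest) < 3) next
        forms <- c(paste0(p, rest),                 # fused
                   paste0(p, "-", rest),            # hyphenated
                   paste(p, rest))                  # spaced
        for (f in forms) {
          nw <- words; nw[wi] <- f
          out <- c(out, paste(nw, collapse = " "))
        }
      }
      # spaced prefix followed by its stem: "intra cranial" -> fused forms
      if (length(words) >= 2) {
        for (wi in seq_len(length(words) - 1L)) {
          if (words[wi] %in% fusable_prefixes && nchar(words[wi + 1L]) >= 3) {
            nw1 <- words; nw2 <- words
            nw1[wi] <- paste0(words[wi], words[wi + 1L]); nw1 <- nw1[-(wi + 1L)]
            nw2[wi] <- paste0(words[wi], "-", words[wi + 1L]); nw2 <- nw2[-(wi + 1L)]
            out <- c(out, paste(nw1, collapse = " "), paste(nw2, collapse = " "))
          }
        }
      }
    }
    sort(unique(out))
  }
  cur <- sort(unique(tolower(variants)))
  repeat {
    nxt <- step(cur)
    if (identical(nxt, cur)) return(cur)
    cur <- nxt
  }
}

#' Expand hyphenation and spelling variants of a lexicon entry
#'
#' For every variant containing a fusable prefix (intra, extra, peri,
#' sub, infra) the fused, hyphenated and spaced forms are generated
#' ("intracranial", "intra-cranial", "intra cranial"), and every "ae"
#' spelling gains its "e" counterpart ("haemorrhage"/"hemorrhage").
#' Idempotent: expanding an already-expanded entry changes nothing.
#'
#' @param entry A list with at least `canonical` and `variants`
#'   (character vector).
#' @return The entry with `variants` enlarged (canonical always
#'   included).
#' @export
#' @examples
#' e <- expand_variants(list(canonical = "intracranial", variants = "intracranial"))
#' e$variants
expand_variants <- function(entry) {
  entry$variants <- expand_variant_strings(unique(c(entry$canonical,
                                                    entry$variants)))
  entry
}

variant_key <- function(variant) {
  toks <- tokenize_string(variant)$surface
  pos <- rule_tagger(toks)
  tolower(mapply(lemmatize, toks, pos, USE.NAMES = FALSE))
}

build_lexicon <- function(entries_df) {
  variants <- list()
  seen <- list()  # variant string -> entity_type, for conflict detection
  for (i in seq_len(nrow(entries_df))) {
    e <- expand_variants(list(
      canonical = entries_df$canonical[i],
      variants = strsplit(entries_df$variants[i], "|", fixed = TRUE)[[1]]))
    for (v in e$variants) {
      prev <- seen[[v]]
      if (!is.null(prev) && prev != entries_df$entity_type[i])
        stop("duplicate variant '", v, "' across entity types ", prev,
             " and ", entries_df$entity_type[i])
      seen[[v]] <- entries_df$entity_type[i]
      key <- variant_key(v)
      if (!length(key)) next
      variants[[length(variants) + 1L]] <-
        list(entry_id = i, variant = v, key = key, n = length(key))
    }
  }
  first <- vapply(variants, function(v) v$key[1], character(1))
  index <- split(seq_along(variants), first)
  structure(list(entries = entries_df, variants = variants, index = index),
            class = "radphen_lexicon")
}

#' @export
print.radphen_lexicon <- function(x, ...) {
  cat(sprintf("<radphen_lexicon> %d entries, %d variant forms\n",
              nrow(x$entries), length(x$variants)))
  print(table(x$entries$entity_type))
  invisible(x)
}

#' Load a lexicon from a TSV file
#'
#' The file has a header line and four tab-separated columns:
#' `canonical`, `entity_type`, `subtype` (`-` for none) and `variants`
#' (pipe-separated surface forms; the canonical form is always
#' included). Variants are expanded with [expand_variants()] and indexed
#' by first-token lemma for longest-match lookup. A variant appearing
#' under two different entity types, or an unknown entity type, is a
#' load error naming the offending line.
#'
#' @param path Path to the TSV file.
#' @return A `radphen_lexicon` object.
#' @export
load_lexicon <- function(path) {
  if (!file.exists(path)) stop("lexicon file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) stop("lexicon file is empty: ", path)
  header <- strsplit(lines[1], "\t", fixed = TRUE)[[1]]
  if (!identical(header[1:4], c("canonical", "entity_type", "subtype", "variants")))
    stop("lexicon header must be: canonical entity_type subtype variants")
  valid_types <- c(disease_types(), modifier_types())
  rows <- lapply(seq_along(lines[-1]), function(i) {
    parts <- strsplit(lines[i + 1L], "\t", fixed = TRUE)[[1]]
    if (length(parts) < 4)
      stop("malformed lexicon row at line ", i + 1L, ": expected 4 columns")
    if (!parts[2] %in% valid_types)
      stop("unknown entity_type '", parts[2], "' at line ", i + 1L)
    data.frame(canonical = tolower(parts[1]), entity_type = parts[2],
               subtype = if (parts[3] %in% c("-", "")) NA_character_ else parts[3],
               variants = tolower(parts[4]),
               match_on_lemma = if (length(parts) >= 5)
                 !identical(parts[5], "surface") else TRUE,
               stringsAsFactors = FALSE)
  })
  build_lexicon(do.call(rbind, rows))
}

#' The default brain-imaging lexicon
#'
#' The package ships a lexicon of disease and modifier terms for the ten
#' disease entity types and five modifier types, assembled from standard
#' UK neuroradiology vocabulary (infarct/infarction/ischaemic change;
#' haematoma/haemorrhage/bleed/blood; lacunar and deep grey-matter terms
#' mapping to deep location; lobe names and cortex mapping to cortical
#' location; acute/recent/new versus old/chronic/mature/established;
#' etc.). It is a reproducible starting point, fully overridable by
#' supplying your own TSV to [load_lexicon()].
#'
#' @return A `radphen_lexicon`.
#' @export
default_lexicon <- function() {
  load_lexicon(system.file("extdata", "default_lexicon.tsv",
                           package = "radphen", mustWork = TRUE))
}

#' Longest dictionary match at a token position
#'
#' Scans the lexicon for the longest variant (in tokens) whose lemma
#' sequence matches the sentence at `position`, comparing
#' case-insensitively on lemmas (or surfaces for entries flagged
#' `match_on_lemma = FALSE`). Ties are broken by file order of the
#' entries. The result is independent of tokens after the matched range.
#'
#' @param sentence A processed sentence (tokens with `lemma`).
#' @param lexicon A `radphen_lexicon`.
#' @param position 1-based token index.
#' @return `NULL` if no match; otherwise a list with `entry` (one row of
#'   the entry table), `from`, `to` (token indices) and `variant`.
#' @export
lookup_longest <- function(sentence, lexicon, position) {
  toks <- sentence$tokens
  n <- nrow(toks)
  if (position > n || position < 1L) return(NULL)
  lemmas <- tolower(toks$lemma)
  cand_idx <- lexicon$index[[lemmas[position]]]
  if (is.null(cand_idx)) return(NULL)
  best <- NULL
  for (ci in cand_idx) {
    v <- lexicon$variants[[ci]]
    if (position + v$n - 1L > n) next
    if (!identical(v$key, lemmas[position:(position + v$n - 1L)])) next
    if (is.null(best) || v$n > best$n ||
        (v$n == best$n && v$entry_id < best$entry_id)) best <- v
  }
  if (is.null(best)) return(NULL)
  list(entry = lexicon$entries[best$entry_id, ], from = position,
       to = position + best$n - 1L, variant = best$variant)
}
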