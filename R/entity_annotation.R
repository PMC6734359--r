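# The rule-based annotation core: lexicon-driven named entity
# recognition, trigger-based negation detection with clause scoping, and
# chunk-based attachment of time/location modifiers to disease entities.

#' Rule configuration for negation and relation extraction
#'
#' Trigger lists are lemma sequences, so inflected forms ("excludes",
#' "excluded") are covered by their lemma. The proximity window and the
#' trigger lists are tunable because they are conventions rather than
#' physiology; the defaults reproduce standard negation/attachment
#' behaviour in UK neuroradiology prose.
#'
#' @param window Maximum token gap for fallback modifier attachment.
#' @return List of rule parameters.
#' @export
rules_config <- function(window = 5L) {
  list(
    pre_triggers = list(
      c("no"), c("without"), c("absence", "of"), c("exclude"),
      c("rule", "out"), c("free", "of"), c("clear", "of"),
      c("no", "evidence", "of"), c("no", "sign", "of")),
    uncertain_pre = list(
      c("cannot", "exclude"), c("can", "not", "exclude"),
      c("could", "not", "exclude"), c("unable", "to", "exclude"),
      c("query"), c("?")),
    post_triggers = list(
      c("unlikely"), c("less", "likely"), c("not", "see"),
      c("not", "identify"), c("be", "exclude")),
    contrast_cues = list(c("rather", "than"), c("as", "opposed", "to")),
    clause_boundaries = c(";", "but", "although", "though", "whereas",
                          "however"),
    copulas = c("be", "appear", "remain", "seem", "look"),
    window = as.integer(window)
  )
}

# multi-word prepositional paraphrases the plain dictionary scan misses
default_paraphrase_patterns <- function() {
  list(
    list(lemmas = c("blood", "in", "the", "subarachnoid", "space"),
         optional = c(FALSE, FALSE, TRUE, FALSE, FALSE),
         type = "subarachnoid_haemorrhage", subtype = NA_character_)
  )
}

match_pattern_at <- function(lemmas, i, pattern) {
  # returns last matched token index, or NA
  pos <- i
  for (k in seq_along(pattern$lemmas)) {
    if (pos > length(lemmas)) {
      if (isTRUE(pattern$optional[k])) next else return(NA_integer_)
    }
    if (lemmas[pos] == pattern$lemmas[k]) {
      pos <- pos + 1L
    } else if (!isTRUE(pattern$optional[k])) {
      return(NA_integer_)
    }
  }
  pos - 1L
}

seq_matches <- function(lemmas, pat) {
  # all occurrences of lemma sequence pat; data.frame(from, to)
  n <- length(lemmas); k <- length(pat)
  if (k == 0L || n < k)
    return(data.frame(from = integer(0), to = integer(0)))
  from <- which(lemmas == pat[1])
  from <- from[from + k - 1L <= n]
  ok <- vapply(from, function(f)
    identical(lemmas[f:(f + k - 1L)], pat), logical(1))
  data.frame(from = from[ok], to = from[ok] + k - 1L)
}

#' Recognize disease and modifier entities in a sentence
#'
#' A left-to-right longest-match scan over the lexicon on lemmas;
#' matched tokens are consumed so entities never overlap. A small set of
#' multi-word prepositional paraphrase patterns ("blood in the
#' subarachnoid spaces") is checked before the dictionary at each
#' position and wins when it matches.
#'
#' @param sentence Processed sentence (tagged and lemmatized).
#' @param lexicon A `radphen_lexicon`.
#' @param patterns Paraphrase pattern list.
#' @return Data frame of entities with columns `type`, `subtype`,
#'   `start`, `end` (character offsets in the sentence's source text),
#'   `surface`, `tok_from`, `tok_to`, `negated`, `uncertain`.
#' @export
recognize_entities <- function(sentence, lexicon,
                               patterns = default_paraphrase_patterns()) {
  toks <- sentence$tokens
  n <- nrow(toks)
  lemmas <- tolower(toks$lemma)
  rows <- list()
  i <- 1L
  while (i <= n) {
    hit_to <- NA_integer_; type <- NULL; subtype <- NA_character_
    for (p in patterns) {
      m <- match_pattern_at(lemmas, i, p)
      if (!is.na(m)) { hit_to <- m; type <- p$type; subtype <- p$subtype; break }
    }
    if (is.na(hit_to)) {
      hit <- lookup_longest(sentence, lexicon, i)
      if (!is.null(hit)) {
        hit_to <- hit$to; type <- hit$entry$entity_type
        subtype <- hit$entry$subtype
      }
    }
    if (!is.na(hit_to)) {
      rows[[length(rows) + 1L]] <- data.frame(
        type = type, subtype = subtype,
        start = toks$start[i], end = toks$end[hit_to],
        surface = NA_character_, tok_from = i, tok_to = hit_to,
        negated = FALSE, uncertain = FALSE, stringsAsFactors = FALSE)
      i <- hit_to + 1L
    } else i <- i + 1L
  }
  if (!length(rows))
    return(data.frame(type = character(0), subtype = character(0),
                      start = integer(0), end = integer(0),
                      surface = character(0), tok_from = integer(0),
                      tok_to = integer(0), negated = logical(0),
                      uncertain = logical(0), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

clause_ids <- function(sentence, rules) {
  toks <- sentence$tokens
  lem <- tolower(toks$lemma)
  n <- length(lem)
  boundary <- lem %in% rules$clause_boundaries
  # a comma bounds a clause when a finite verb follows it closely
  commas <- which(toks$surface == ",")
  for (ci in commas) {
    ahead <- seq(ci + 1L, length.out = min(2L, n - ci))
    if (length(ahead) && any(toks$pos[ahead] == "VERB")) boundary[ci] <- TRUE
  }
  cumsum(boundary) - ifelse(boundary, 1L, 0L)  # boundary token joins left clause
}

#' Detect negated (and uncertain) disease mentions
#'
#' A disease entity is negated when a pre-trigger ("no", "without",
#' "absence of", "exclude", "rule out", "free of", "clear of", "no
#' evidence of", "no sign(s) of") precedes it in the same clause, or a
#' post-trigger ("unlikely", "less likely", "not seen", "not
#' identified", "is/are excluded") follows it in the same clause, or it
#' sits inside the contrasted phrase of "rather than X". Hedged
#' possibility ("cannot exclude X", "query X", "?X") is flagged
#' `uncertain`, not negated, and the labeller treats it as present.
#' Modifier entities are never negated. Idempotent: flags are recomputed
#' from scratch.
#'
#' @param sentence Processed sentence.
#' @param entities Entity data frame from [recognize_entities()].
#' @param chunks Chunk data frame from [chunk_sentence()].
#' @param rules Rule configuration from [rules_config()].
#' @return The entity data frame with `negated`/`uncertain` flags set.
#' @export
detect_negation <- function(sentence, entities, chunks, rules = rules_config()) {
  if (!nrow(entities)) return(entities)
  lem <- tolower(sentence$tokens$lemma)
  cl <- clause_ids(sentence, rules)
  is_disease <- entities$type %in% disease_types()
  entities$negated <- FALSE
  entities$uncertain <- FALSE

  occ <- function(pats) {
    do.call(rbind, c(list(data.frame(from = integer(0), to = integer(0))),
                     lapply(pats, function(p) seq_matches(lem, p))))
  }
  unc <- occ(rules$uncertain_pre)
  pre <- occ(rules$pre_triggers)
  # pre-triggers swallowed by an uncertainty trigger ("cannot exclude")
  # do not negate
  if (nrow(pre) && nrow(unc)) {
    covered <- vapply(seq_len(nrow(pre)), function(i)
      any(pre$from[i] >= unc$from & pre$to[i] <= unc$to), logical(1))
    pre <- pre[!covered, , drop = FALSE]
  }

  post <- occ(rules$post_triggers)
  for (i in which(is_disease)) {
    ef <- entities$tok_from[i]
    if (nrow(pre) && any(pre$to < ef & cl[pmax(pre$to, 1L)] == cl[ef]))
      entities$negated[i] <- TRUE
    if (nrow(unc) && any(unc$to < ef & cl[pmax(unc$to, 1L)] == cl[ef]))
      entities$uncertain[i] <- TRUE
    et <- entities$tok_to[i]
    if (nrow(post) && any(post$from > et & cl[post$from] == cl[et]))
      entities$negated[i] <- TRUE
  }

  # "rather than X": entities inside the contrasted noun phrase
  rt <- occ(rules$contrast_cues)
  if (nrow(rt) && nrow(chunks)) {
    nps <- chunks[chunks$kind == "noun_phrase", , drop = FALSE]
    for (r in seq_len(nrow(rt))) {
      cand <- nps[nps$from > rt$to[r], , drop = FALSE]
      if (!nrow(cand)) next
      np <- cand[which.min(cand$from), ]
      inside <- is_disease & entities$tok_from >= np$from &
        entities$tok_to <= np$to
      entities$negated[inside] <- TRUE
    }
  }
  entities
}

#' Extract time and location relations
#'
#' Attaches each modifier entity to at most one disease entity, in
#' priority order: (a) a disease entity in the same noun phrase; (b) the
#' subject of a copula for predicative modifiers ("the infarct is old");
#' (c) the nearest disease entity within the proximity window, unless a
#' contrast cue ("rather than", "as opposed to") intervenes. When an
#' NP-internal link exists no cross-NP link is emitted for that
#' modifier.
#'
#' @param sentence Processed sentence.
#' @param entities Entity data frame (negation flags may be set).
#' @param chunks Chunks from [chunk_sentence()].
#' @param rules Rule configuration.
#' @return Data frame with columns `kind` (`time`/`location`/
#'   `attribute`), `modifier` and `target` (row indices into
#'   `entities`).
#' @export
extract_relations <- function(sentence, entities, chunks,
                              rules = rules_config()) {
  out <- data.frame(kind = character(0), modifier = integer(0),
                    target = integer(0), stringsAsFactors = FALSE)
  if (!nrow(entities)) return(out)
  lem <- tolower(sentence$tokens$lemma)
  cl <- clause_ids(sentence, rules)
  mods <- which(entities$type %in% modifier_types())
  dis <- which(entities$type %in% disease_types())
  if (!length(mods) || !length(dis)) return(out)
  nps <- chunks[chunks$kind == "noun_phrase", , drop = FALSE]
  cues <- do.call(rbind, c(list(data.frame(from = integer(0), to = integer(0))),
                           lapply(rules$contrast_cues,
                                  function(p) seq_matches(lem, p))))
  rel_kind <- function(mtype) {
    if (startsWith(mtype, "time")) "time"
    else if (startsWith(mtype, "loc")) "location"
    else "attribute"
  }

  for (m in mods) {
    mf <- entities$tok_from[m]; mt <- entities$tok_to[m]
    target <- NA_integer_

    # (a) same noun phrase
    if (nrow(nps)) {
      np_i <- which(nps$from <= mf & nps$to >= mt)
      if (length(np_i)) {
        np <- nps[np_i[1], ]
        cand <- dis[entities$tok_from[dis] >= np$from &
                      entities$tok_to[dis] <= np$to]
        if (length(cand)) {
          # prefer the phrase head, else the nearest
          hd <- cand[entities$tok_from[cand] <= np$head &
                       entities$tok_to[cand] >= np$head]
          target <- if (length(hd)) hd[1] else
            cand[which.min(abs(entities$tok_from[cand] - mf))]
        }
      }
    }

    # (b) predicative: subject disease ... copula ... modifier
    if (is.na(target)) {
      before <- dis[entities$tok_to[dis] < mf]
      if (length(before)) {
        before <- before[order(-entities$tok_to[before])]
        for (d in before) {
          between <- if (mf - 1L >= entities$tok_to[d] + 1L)
            (entities$tok_to[d] + 1L):(mf - 1L) else integer(0)
          if (length(between) &&
              any(lem[between] %in% rules$copulas &
                    sentence$tokens$pos[between] == "VERB") &&
              cl[entities$tok_to[d]] == cl[mf]) {
            target <- d
            break
          }
        }
      }
    }

    # (c) nearest within window, no contrast cue intervening
    if (is.na(target)) {
      gap <- vapply(dis, function(d) {
        if (entities$tok_from[d] > mt) entities$tok_from[d] - mt - 1L
        else if (entities$tok_to[d] < mf) mf - entities$tok_to[d] - 1L
        else 0L
      }, integer(1))
      blocked <- vapply(dis, function(d) {
        if (!nrow(cues)) return(FALSE)
        lo <- min(mt, entities$tok_to[d]); hi <- max(mf, entities$tok_from[d])
        any(cues$from > lo & cues$to < hi)
      }, logical(1))
      ok <- which(gap <= rules$window & !blocked)
      if (length(ok)) {
        best <- ok[order(gap[ok], entities$tok_from[dis[ok]])]
        target <- dis[best[1]]
      }
    }

    if (!is.na(target)) {
      out <- rbind(out, data.frame(kind = rel_kind(entities$type[m]),
                                   modifier = m, target = target,
                                   stringsAsFactors = FALSE))
    }
  }
  out
}
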