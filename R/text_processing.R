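# Sentence/token segmentation, coarse POS tagging, lemmatization and
# noun/verb-phrase chunking. The tagger is deliberately dependency-free:
# downstream rules only consume a coarse 10-tag set
# (NOUN VERB ADJ ADV DET PREP CONJ NUM PUNCT OTHER), so a lexicon plus
# suffix rules is sufficient, and any external tagger honouring the
# contract (surfaces in, equal-length tags out) can be injected.

radphen_tagset <- function() {
  c("NOUN", "VERB", "ADJ", "ADV", "DET", "PREP", "CONJ", "NUM", "PUNCT", "OTHER")
}

#' Default protected abbreviations for sentence splitting
#'
#' Radiology reports are abbreviation-dense; a terminal period after one
#' of these does not end a sentence. Case-insensitive; fully overridable.
#'
#' @return Character vector of abbreviations (without the trailing dot).
#' @export
default_abbreviations <- function() {
  c("e.g", "i.e", "vs", "etc", "approx", "ca", "cf", "dr", "mr", "mrs",
    "prof", "no", "fig", "max", "min", "wk", "yr", "rt", "lt")
}

tokenize_string <- function(text) {
  # words (keeping internal hyphens/apostrophes), decimals, single symbols
  pat <- "[0-9]+\\.[0-9]+|[A-Za-z0-9]+(?:[-'][A-Za-z0-9]+)*|\\S"
  m <- gregexpr(pat, text, perl = TRUE)[[1]]
  if (m[1] == -1L)
    return(data.frame(surface = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  start <- as.integer(m) - 1L
  end <- start + attr(m, "match.length")
  data.frame(surface = regmatches(text, list(m))[[1]],
             start = start, end = end, stringsAsFactors = FALSE)
}

#' Segment section text into sentences and tokens
#'
#' Sentences are split on terminal punctuation (`.`, `?`, `!`) followed
#' by whitespace, and on blank lines. Periods after protected
#' abbreviations, single initials and inside decimal numbers do not
#' split. Tokens are split on whitespace and punctuation; hyphenated
#' medical terms ("intra-cranial", "long-standing") stay single tokens.
#'
#' @param section_text Text of one report section (may be empty).
#' @param section_kind Section kind carried on each sentence.
#' @param abbreviations Protected abbreviation list.
#' @return List of sentences; each is a list with `tokens` (data frame
#'   `surface`, `start`, `end` — 0-based half-open offsets into
#'   `section_text` — plus `pos`/`lemma` once tagged), `start`, `end`,
#'   and `section_kind`.
#' @export
#' @examples
#' length(segment("No metastases. Exclude subdural bleed."))
segment <- function(section_text, section_kind = "body",
                    abbreviations = default_abbreviations()) {
  if (!nzchar(section_text)) return(list())
  toks <- tokenize_string(section_text)
  if (nrow(toks) == 0L) return(list())

  n <- nrow(toks)
  is_break <- rep(FALSE, n)
  abbrev <- tolower(abbreviations)
  for (i in seq_len(n)) {
    s <- toks$surface[i]
    if (grepl("^[.?!]+$", s)) {
      prev <- if (i > 1L) tolower(sub("\\.$", "", toks$surface[i - 1L])) else ""
      if (s == "." && (prev %in% abbrev || grepl("^[a-z]$", prev))) next
      # "?stroke" (query marker glued to the next word) is not terminal
      if (i < n && toks$start[i + 1L] == toks$end[i]) next
      is_break[i] <- TRUE
    } else if (i < n) {
      # blank line between this token and the next
      gap <- substr0(section_text, toks$end[i], toks$start[i + 1L])
      if (grepl("\n[ \t]*\n", gap)) is_break[i] <- TRUE
    }
  }
  is_break[n] <- TRUE
  bounds <- which(is_break)
  sent_id <- rep(seq_along(bounds), times = diff(c(0L, bounds)))

  lapply(seq_along(bounds), function(si) {
    tk <- toks[sent_id == si, , drop = FALSE]
    rownames(tk) <- NULL
    list(tokens = tk, start = tk$start[1], end = tk$end[nrow(tk)],
         section_kind = section_kind)
  })
}

# ---- rule-based coarse tagger -------------------------------------------

tagger_lexicon <- local({
  det <- c("the", "a", "an", "this", "that", "these", "those", "some",
           "any", "no", "each", "either", "neither", "both")
  prep <- c("in", "on", "of", "at", "with", "within", "without", "into",
            "from", "to", "by", "over", "under", "near", "around", "through",
            "across", "between", "during", "against", "for", "since",
            "toward", "towards", "along", "beside", "behind", "above",
            "below", "throughout", "involving")
  conj <- c("and", "or", "but", "nor", "although", "though", "while",
            "whereas", "than", "because", "if", "as")
  adv <- c("not", "also", "very", "much", "less", "more", "most", "rather",
           "now", "again", "still", "only", "just", "quite", "too", "there",
           "here", "however", "therefore")
  verb <- c("is", "are", "was", "were", "be", "been", "being", "am",
            "has", "have", "had", "does", "do", "did", "can", "cannot",
            "could", "may", "might", "would", "should", "will", "shall",
            "must", "seen", "see", "shows", "show", "shown", "suggest",
            "suggests", "appear", "appears", "represent", "represents",
            "reflect", "reflects", "lie", "lies", "extend", "extends",
            "remain", "remains", "seem", "seems", "arise", "arises",
            "exclude", "excludes", "note", "notes", "look", "looks")
  adj <- c("old", "new", "recent", "acute", "chronic", "mature", "subacute",
           "small", "large", "left", "right", "bilateral", "deep", "cortical",
           "lobar", "frontal", "parietal", "temporal", "occipital", "lacunar",
           "subdural", "extradural", "epidural", "subarachnoid", "intracranial",
           "intracerebral", "aneurysmal", "ischaemic", "ischemic",
           "haemorrhagic", "hemorrhagic", "normal", "prominent", "extensive",
           "mild", "moderate", "severe", "diffuse", "focal", "multiple",
           "several", "single", "previous", "prior", "longstanding",
           "long-standing", "thalamic", "pontine", "capsular",
           "periventricular", "white", "grey", "low", "high", "sclerotic",
           "metastatic", "vascular", "microangiopathic", "original",
           "underlying", "unlikely", "likely", "early", "late", "significant",
           "consistent", "compatible", "possible", "probable", "uncertain",
           "generalised", "generalized", "petechial", "dural", "pineal",
           "ruptured", "established", "hyperdense", "hypodense", "fresh",
           "ancient", "secondary", "intrinsic", "infiltrative", "widespread")
  noun <- c("infarct", "infarction", "infarcts", "haemorrhage", "hemorrhage",
            "haematoma", "hematoma", "bleed", "bleeding", "blood", "stroke",
            "atrophy", "involution", "metastasis", "metastases", "glioma",
            "glioblastoma", "astrocytoma", "meningioma", "tumour", "tumor",
            "mass", "lesion", "neoplasm", "microbleed", "microbleeds",
            "microhaemorrhage", "aneurysm", "collection", "attenuation",
            "disease", "change", "changes", "evidence", "sign", "signs",
            "absence", "ventricles", "sulci", "thalamus", "pons", "ganglia",
            "capsule", "matter", "transformation", "sah", "cva", "space",
            "spaces", "lobe", "lobes", "report", "conclusion", "area",
            "region", "appearance", "appearances", "loss", "shift", "age",
            "scan", "study", "leukoaraiosis", "microangiopathy",
            "encephalomalacia", "leukoencephalopathy", "hyperdensity",
            "deposit", "deposits", "fossa", "falx", "convexity", "midline")
  list(DET = det, PREP = prep, CONJ = conj, ADV = adv, VERB = verb,
       ADJ = adj, NOUN = noun)
})

#' Built-in rule-based coarse POS tagger
#'
#' Tags a vector of token surfaces with a coarse 10-tag set using
#' closed-class word lists, a small domain lexicon and suffix rules
#' (`-ly` adverb, `-ing`/`-ed` verb, `-ic`/`-al`/`-ous`/`-ive`
#' adjective); unknown capitalized words and everything else default to
#' `NOUN`. Deterministic and dependency-free; serves as the default
#' implementation of the tagger contract.
#'
#' @param surfaces Character vector of token surfaces.
#' @return Character vector of tags, same length.
#' @export
rule_tagger <- function(surfaces) {
  lex <- tagger_lexicon
  vapply(surfaces, function(s) {
    if (grepl("^[0-9]+([.,][0-9]+)?$", s)) return("NUM")
    if (!grepl("[A-Za-z0-9]", s)) return("PUNCT")
    w <- tolower(s)
    for (tag in c("DET", "PREP", "CONJ", "ADV", "VERB", "ADJ", "NOUN"))
      if (w %in% lex[[tag]]) return(tag)
    if (grepl("ly$", w) && nchar(w) > 3) return("ADV")
    if (grepl("(ing|ed)$", w) && nchar(w) > 4) return("VERB")
    if (grepl("(ic|al|ous|ive|ar)$", w) && nchar(w) > 4) return("ADJ")
    "NOUN"
  }, character(1), USE.NAMES = FALSE)
}

#' Attach part-of-speech tags to segmented sentences
#'
#' Applies a tagger honouring the tagger contract: a function from a
#' character vector of token surfaces to an equal-length character
#' vector of tags drawn from the coarse tagset. A wrong-length or
#' out-of-set result is a contract violation and raises an error.
#'
#' @param sentences List of sentences from [segment()].
#' @param tagger Tagging function; defaults to [rule_tagger()].
#' @return The sentences with a `pos` column filled in on each token
#'   data frame.
#' @export
pos_tag <- function(sentences, tagger = rule_tagger) {
  lapply(sentences, function(sent) {
    tags <- tagger(sent$tokens$surface)
    if (length(tags) != nrow(sent$tokens))
      stop("tagger contract violation: returned ", length(tags),
           " tags for ", nrow(sent$tokens), " tokens")
    if (!all(tags %in% radphen_tagset()))
      stop("tagger contract violation: unknown tag(s) ",
           paste(setdiff(tags, radphen_tagset()), collapse = ", "))
    sent$tokens$pos <- tags
    sent
  })
}

# ---- lemmatizer ----------------------------------------------------------

lemma_exceptions <- c(
  bled = "bleed", bleeding = "bleed", bleeds = "bleed",
  was = "be", were = "be", is = "be", are = "be", been = "be", being = "be",
  am = "be", has = "have", had = "have", having = "have",
  seen = "see", saw = "see", shown = "show", did = "do", done = "do",
  noted = "note", noting = "note", excluded = "exclude",
  excluding = "exclude", involved = "involve", involving = "involve",
  demonstrated = "demonstrate", demonstrating = "demonstrate",
  lying = "lie", arisen = "arise", arose = "arise",
  foci = "focus", nuclei = "nucleus", lacunae = "lacuna", gyri = "gyrus",
  sulci = "sulcus", secondaries = "secondary"
)

strip_double <- function(w) {
  n <- nchar(w)
  if (n >= 3) {
    a <- substr(w, n - 1, n - 1); b <- substr(w, n, n)
    if (a == b && !a %in% c("l", "s", "f") && grepl("[b-df-hj-np-tv-z]", b))
      return(substr(w, 1, n - 1))
  }
  w
}

restore_e <- function(w) {
  if (grepl("[cgvz]$", w)) paste0(w, "e") else w
}

#' Lemmatize a token
#'
#' Maps an inflected surface form to its canonical lowercase lemma:
#' irregulars through an exception table (so "bled", "bleeding" and
#' "bleeds" all map to "bleed"), Latin plurals like "metastases" to
#' "metastasis", regular noun plurals by suffix stripping, and regular
#' verb inflection with doubled-consonant and silent-e handling.
#'
#' @param surface Token surface form.
#' @param pos Coarse POS tag (noun and verb rules differ).
#' @return Lemma string, lowercased.
#' @export
#' @examples
#' lemmatize("bled", "VERB")        # "bleed"
#' lemmatize("metastases", "NOUN")  # "metastasis"
lemmatize <- function(surface, pos = "NOUN") {
  w <- tolower(surface)
  if (w %in% names(lemma_exceptions)) return(unname(lemma_exceptions[w]))
  n <- nchar(w)
  if (pos == "VERB") {
    if (grepl("ies$", w) && n > 4) return(paste0(substr(w, 1, n - 3), "y"))
    if (grepl("ied$", w) && n > 4) return(paste0(substr(w, 1, n - 3), "y"))
    if (grepl("ing$", w) && n > 5)
      return(restore_e(strip_double(substr(w, 1, n - 3))))
    if (grepl("ed$", w) && !grepl("eed$", w) && n > 4)
      return(restore_e(strip_double(substr(w, 1, n - 2))))
    if (grepl("([sxz]|ch|sh)es$", w) && n > 4) return(substr(w, 1, n - 2))
    if (grepl("[^sui]s$", w) && n > 3) return(substr(w, 1, n - 1))
    return(w)
  }
  if (pos == "NOUN") {
    if (grepl("(oses|ases|eses)$", w) && n > 5 &&
        substr(w, n - 4, n - 4) != "s")
      return(paste0(substr(w, 1, n - 2), "is"))
    if (grepl("ies$", w) && n > 4) return(paste0(substr(w, 1, n - 3), "y"))
    if (grepl("([sxz]|ch|sh)es$", w) && n > 4) return(substr(w, 1, n - 2))
    if (grepl("[^sui]s$", w) && n > 3) return(substr(w, 1, n - 1))
    return(w)
  }
  w
}

#' Lemmatize all tokens in tagged sentences
#'
#' @param sentences Tagged sentences from [pos_tag()].
#' @return Sentences with a `lemma` column on each token data frame.
#' @export
lemmatize_sentences <- function(sentences) {
  lapply(sentences, function(sent) {
    sent$tokens$lemma <- mapply(lemmatize, sent$tokens$surface,
                                sent$tokens$pos, USE.NAMES = FALSE)
    sent
  })
}

# ---- chunker -------------------------------------------------------------

#' Chunk a sentence into noun and verb phrases
#'
#' Builds maximal non-recursive noun phrases (optional determiner, then a
#' run of adjectives/nouns/numerals containing at least one noun; head is
#' the last noun) and verb phrases (adverbs followed by one or more
#' verbs). Every noun token belongs to exactly one noun phrase; chunks
#' never overlap or cross the sentence boundary.
#'
#' @param sentence A tagged sentence.
#' @return Data frame with columns `kind` (`noun_phrase`/`verb_phrase`),
#'   `from`, `to` (1-based inclusive token indices) and `head`.
#' @export
chunk_sentence <- function(sentence) {
  pos <- sentence$tokens$pos
  n <- length(pos)
  out <- data.frame(kind = character(0), from = integer(0), to = integer(0),
                    head = integer(0), stringsAsFactors = FALSE)
  i <- 1L
  while (i <= n) {
    if (pos[i] %in% c("DET", "ADJ", "NOUN", "NUM")) {
      j <- i
      if (pos[j] == "DET") j <- j + 1L
      k <- j
      while (k <= n && pos[k] %in% c("ADJ", "NOUN", "NUM")) k <- k + 1L
      nouns <- which(pos[i:(k - 1L)] == "NOUN")
      if (k > j && length(nouns)) {
        out <- rbind(out, data.frame(kind = "noun_phrase", from = i,
                                     to = k - 1L,
                                     head = i + nouns[length(nouns)] - 1L))
        i <- k
        next
      }
      i <- i + 1L
    } else if (pos[i] == "VERB" ||
               (pos[i] == "ADV" && i < n && pos[i + 1L] %in% c("ADV", "VERB"))) {
      j <- i
      while (j <= n && pos[j] == "ADV") j <- j + 1L
      k <- j
      while (k <= n && pos[k] == "VERB") k <- k + 1L
      if (k > j) {
        out <- rbind(out, data.frame(kind = "verb_phrase", from = i,
                                     to = k - 1L, head = k - 1L))
        i <- k
        next
      }
      i <- i + 1L
    } else i <- i + 1L
  }
  out
}

#' Run the full text-processing stack on one section
#'
#' Convenience wrapper: segment, tag, lemmatize.
#'
#' @param section_text Section text.
#' @param section_kind Section kind tag.
#' @param tagger Tagger function (contract of [pos_tag()]).
#' @return List of processed sentences.
#' @export
process_text <- function(section_text, section_kind = "body",
                         tagger = rule_tagger) {
  lemmatize_sentences(pos_tag(segment(section_text, section_kind), tagger))
}
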