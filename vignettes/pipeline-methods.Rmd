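---
title: "Rule-based phenotyping of brain imaging reports: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based phenotyping of brain imaging reports: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radphen)
```

## The problem

Radiologists describe brain CT and MR findings in free text. For
epidemiological research at scale — cohort building, outcome
ascertainment, quality improvement — those findings need to be turned
into structured phenotypes: did this report describe an old deep
infarct, cerebral atrophy, a subdural haematoma? Manual coding of tens
of thousands of reports is impractical, and the prose, while
conventionalized, is full of negation ("No metastases"), hedging
("cannot exclude"), and modifier attachment ("Right frontal chronic
haemorrhage") that defeats naive keyword search.

`radphen` implements a staged, rule-based pipeline that reads a report
and assigns a set of document-level labels drawn from a closed taxonomy
of 24 cerebrovascular and neurological phenotypes
(`phenotype_labels()`), together with the statistical machinery used to
validate such a system and a synthetic report generator that makes the
whole pipeline testable without access to governed clinical text.

## Pipeline stages and their assumptions

Processing order is fixed: zoning, sentence/token segmentation, coarse
part-of-speech tagging, lemmatization, lexicon-driven named entity
recognition, negation detection, chunk-based relation extraction, and
label mapping.

**Zoning** (`zone_report()`) splits a report into request, body and
conclusion sections by matching heading patterns at line start. Heading
conventions vary between departments and are not standardized, so the
pattern set is configuration, not code; the defaults cover the common
UK forms (clinical details/history/indication; report/findings;
conclusion/impression/comment/opinion). Text before any heading is
treated as body. Zoning is lossless: every character belongs to exactly
one section span or to a heading line. Labels are only ever assigned
from body and conclusion evidence; request-section mentions ("?stroke")
are recognized but ineligible, since the clinical question is not a
finding.

**Segmentation** splits on terminal punctuation and blank lines, with a
configurable protected-abbreviation list because radiology prose is
abbreviation-dense ("e.g.", "vs.", measurement units). A query marker
glued to a word ("?stroke") is not sentence-terminal. Hyphenated terms
stay single tokens so that "intra-cranial" and "long-standing" survive
as lexical units.

**Tagging** uses a deliberately coarse 10-tag set (NOUN, VERB, ADJ,
ADV, DET, PREP, CONJ, NUM, PUNCT, OTHER). The downstream rules consult
only broad word classes — noun-phrase boundaries, copulas, determiners
— so nothing finer is needed, and a lexicon-plus-suffix rule tagger
(`rule_tagger()`) carries no model dependency. The tagger is a
*contract*: any function mapping token surfaces to an equal-length
vector of tags from this set can be injected into `pos_tag()`, so a
statistical tagger can replace the built-in one without touching the
rules.

**Lemmatization** (`lemmatize()`) maps inflected forms to canonical
lemmas — *bleed* for *bled*, *bleeding*, *bleeds*; *metastasis* for
*metastases* — through an irregular-form exception table plus regular
suffix rules with doubled-consonant and silent-e handling. Matching at
the lemma level is what lets single lexicon entries cover plural and
inflected mentions.

**The lexicon** (`default_lexicon()`) holds disease entries for the ten
disease entity types and modifier entries for the five modifier types
(time recent/old, location deep/cortical, aneurysmal). Because no
reference vocabulary for this task is published, the shipped lexicon is
a reconstruction from standard UK neuroradiology usage: infarct /
infarction / ischaemic change; haemorrhage / haematoma / bleed / blood;
lacunar and deep grey-matter anatomy mapping to the deep location; lobe
names and cortex mapping to cortical; acute/recent/new/fresh versus
old/chronic/mature/established. It is a starting point, fully
overridable by TSV file, and the anatomy-to-location mapping lives in
the lexicon precisely so clinicians can amend it without code changes.
`expand_variants()` generates hyphenation triples
(intracranial / intra-cranial / intra cranial) and ae/e spelling pairs
(haemorrhage/hemorrhage) so near-duplicates need not be listed by hand.
Lookup is longest-match over lemmas with ties broken by file order.

**NER** is a left-to-right longest-match scan; matched tokens are
consumed, so entities never overlap. A small pattern set catches
prepositional paraphrases that a dictionary cannot ("blood in the
subarachnoid spaces" is subarachnoid blood with a prepositional phrase
in the middle); dictionary-only systems are known to miss exactly this
construction, so the patterns are first-class and checked before the
dictionary at each position.

**Negation** is trigger-based with clause scoping. Pre-triggers (no,
without, absence of, exclude, rule out, free of, clear of, no evidence
of, no sign(s) of) negate disease entities that follow them in the same
clause; post-triggers (unlikely, less likely, not seen, not identified,
is/are excluded) negate entities whose noun phrase precedes them; and
"rather than X" negates disease entities inside the contrasted noun
phrase. Clause boundaries are semicolons, contrastive conjunctions, and
commas followed closely by a finite verb. Hedged possibility — "cannot
exclude X", "query X", "?X" — is deliberately *not* negation: it is
flagged `uncertain`, and the labeller treats such mentions as present
by default, because a hedge asserts possible presence, not absence.
Modifier entities are never negated. The trigger lists and the scoping
conventions are not published anywhere as a standard; the values here
were chosen to handle the negation constructions that recur in
reporting prose, and they are exposed in `rules_config()`.

**Relation extraction** attaches each modifier to at most one disease
entity, in a strict priority order: (a) a disease entity in the same
noun phrase ("Right frontal chronic **haemorrhage**"); (b) the subject
of a copula for predicative modifiers ("the infarct **is old**");
(c) the nearest disease entity within a 5-token window, unless a
contrast cue intervenes. The NP rule dominating proximity is what gets
the hard case right: in "redistribution of the original haematoma
rather than new blood", *new* is NP-bound to *blood* and must never
reach back to *haematoma*, which a pure proximity rule would do. The
5-token window is a convention, not a measurement; it is configurable.
In coordinated phrases ("old frontal and parietal infarcts") the
modifier links only to its single best target — a deliberate
simplification, since the pipeline does not parse sentence structure.

**Label mapping** is a thin, pure function (`assign_labels()`) from
non-negated body/conclusion entities and their relations to the
24-label set. Presence phenotypes (atrophy, small vessel disease,
subdural haematoma, haemorrhagic transformation) need only one
qualifying entity. Stroke labels need both a location and a time
relation to be fully specified; an incomplete pair maps to the
"underspecified" variant of that stroke type, because the taxonomy has
no partially-specified labels. For haemorrhagic stroke and microbleeds
the cortical location is rendered "lobar", following the taxonomy's
naming. Subarachnoid haemorrhage is "aneurysmal" when an aneurysmal
modifier is linked or an aneurysm is mentioned in the same sentence.
Tumour subtype comes from the lexicon entry. Labels form a set:
duplicate evidence yields one label, and when two differently specified
mentions co-occur (an old cortical infarct *and* a bare "infarct"
elsewhere), both the specified and the underspecified labels are
emitted, each with its own provenance — the taxonomy gives no grounds
for suppressing either.

## The evaluation layer

Validation of report-level phenotyping reports, per phenotype,
sensitivity, specificity and positive predictive value with **Wilson
score intervals** (`wilson_ci()`), which remain well behaved at
proportions near 0 and 1 where Wald intervals collapse; F1 as the
harmonic mean of PPV and sensitivity; **Cohen's kappa**
(`cohens_kappa()`) for label agreement between annotators; and
entity-level precision/recall/F1 (`entity_prf()`) with both exact-span
and overlap matching, since published inter-annotator comparisons do
not always state which criterion they used. Metrics with zero
denominators are reported as undefined, never as zero, and the
small-count display suppression is a formatting filter
(`format_metrics_table()`) that never touches the computation.

`min_sample_size()` inverts the Wilson width: the smallest positive
case count whose interval at an anticipated sensitivity is narrower
than a target width, inflated by prevalence and optionally rounded up.
At sensitivity 0.95, prevalence 0.12 and total width 0.10 this gives
83 cases, 692 reports, and 700 after rounding to the next hundred — the
standard design for a validation-set size in this setting.

## The synthetic corpus generator

Clinical text from health-board archives is governance-restricted, so
the generator (`generate_corpus()`) is first-class, tested code, not a
fixture. What it emulates:

* the request / body / conclusion report structure, with the clinical
  question in the request ("?stroke") and a conclusion that either
  restates a finding or closes neutrally;
* per-report label sets sampled from a prevalence profile. The default
  `validation_sample` profile mirrors the label mix of a 700-report random
  validation sample of unselected NHS reports (suppressed counts below
  5 are set to 2, the midpoint of the permitted range); a
  `routine_practice` profile mirrors a whole-archive mix (atrophy-heavy,
  microbleeds rare);
* findings language rich in negation and hedging: negated distractor
  sentences at a configurable rate, plus the hard constructions that
  are documented failure modes of dictionary systems ("rather than new
  blood", "much less likely", "blood in the subarachnoid spaces");
* lexical variation (`variant_rate`) over synonyms, spellings and
  hyphenations, and — as a stress knob — out-of-lexicon paraphrases
  (`paraphrase_rate = q`) under which per-label recall should degrade
  to roughly 1 − q, the signature failure mode of any system facing
  unseen phrasing.

Gold entities, relations and negation flags are placed by the templates
with exact character offsets, and the generator's acceptance gate is
self-consistency: `assign_labels()` on the gold annotations reproduces
the intended label set for every generated report.

What it does **not** emulate: the lexical diversity, typographical
noise, dictation artefacts and discourse structure of real reports, or
inter-annotator disagreement. A pipeline that scores F1 = 1 on
in-lexicon synthetic text has demonstrated internal coherence of rules,
lexicon and labeller — not real-world performance, which in published
validations of comparable systems sits in the 0.8–1.0 range per
phenotype and must be measured against expert-annotated clinical text.

## Numerical and interface choices

* Character offsets are 0-based, half-open, counted after CRLF→LF
  normalization — one unambiguous convention shared with brat standoff
  interchange, where round-tripping is the identity up to identifier
  renumbering.
* Wilson bounds at degenerate counts (k = 0 or k = n) are set exactly
  to 0 or 1 rather than left to floating-point cancellation.
* The sample-size search brackets by doubling and then bisects; Wilson
  width is strictly decreasing in n, so the minimum is exact.
* Ties in lexicon lookup go to file order; ties in proximity
  attachment go to the preceding entity. Degenerate inputs (empty
  sections, punctuation-only sentences, reports without headings) fall
  through cleanly: empty token lists, no chunks, all-body zoning.
* Two-decimal rounding happens only at display time.

## Problem sizes used by the test suite

The suite checks the generator's self-consistency invariant on 10,000
generated reports, end-to-end label recovery (per-phenotype F1 ≥ 0.95)
on a 1,000-report in-lexicon corpus, recall degradation at paraphrase
rate 0.3 on 400 reports, and the Wilson implementation against an
independent numeric inversion of the score test on a 200-point random
grid. These sizes give stable estimates for every phenotype in the
default prevalence profile while keeping a full test run to a few
minutes on one core.

## Known limitations

The pipeline does not parse sentence structure: attachment is
chunk-and-proximity based, and long-range or syntactically inverted
constructions can mislink modifiers. There is no coreference across
sentences, so "this" in a follow-up sentence never inherits an entity.
The shipped lexicon cannot be verified against the (unpublished)
vocabularies of the systems it emulates — around 400 entries in the
original — and must be extended for new departments, modalities or
body parts. Negation scope is clause-bounded and trigger-driven;
double negation and scope ambiguity ("no definite acute change, but…")
are resolved only as well as the trigger lists allow.
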