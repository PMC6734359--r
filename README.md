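# radphen

Rule-based phenotyping of brain imaging radiology reports.

## What it does, and for whom

Brain CT/MR findings live in radiologists' free-text reports. Research
uses of routine imaging — cohort building, stroke outcome
ascertainment, health-care quality work — need those findings as
structured phenotypes, at a scale where manual coding is impossible.
`radphen` is an R implementation of a staged, rule-based clinical NLP
pipeline for exactly this task: it reads a report and assigns a set of
document-level labels from a closed taxonomy of 24 cerebrovascular and
neurological phenotypes (stroke by type, location and age; atrophy;
small vessel disease; subarachnoid haemorrhage; subdural haematoma;
microbleeds; haemorrhagic transformation; tumours by subtype).

The pipeline stages, run in fixed order per report:

1. **Zoning** into request / body / conclusion sections (regex-driven,
   configurable headings);
2. **Segmentation** into sentences and tokens (abbreviation-aware,
   hyphenated terms intact);
3. **Coarse POS tagging** behind a pluggable tagger contract, with a
   dependency-free rule tagger as the default;
4. **Lemmatization** (*bleed* for *bled/bleeding/bleeds*,
   *metastasis* for *metastases*);
5. **Named entity recognition** by longest-match lookup over ~400
   lexicon variant forms, plus paraphrase patterns ("blood in the
   subarachnoid spaces");
6. **Negation detection** with clause-scoped pre/post triggers
   ("Exclude subdural bleed.", "much less likely") and an `uncertain`
   flag for hedges ("cannot exclude");
7. **Relation extraction** attaching time/location modifiers to disease
   entities (noun-phrase first, then predicative, then proximity);
8. **Label mapping** from non-negated body/conclusion entities and
   relations to the 24 phenotype labels.

It also ships the full evaluation layer used to validate such systems,
and a synthetic report generator, so that every stage is testable
without governance-restricted clinical text.

## The statistics

For a phenotype with confusion counts (tp, fp, fn, tn) over reports the
package reports sensitivity tp/(tp+fn), specificity tn/(tn+fp), PPV
tp/(tp+fp), and F1 = 2·PPV·sens/(PPV+sens). Interval estimates use the
Wilson score interval

    ( p̂ + z²/2n  ±  z·√( p̂(1−p̂)/n + z²/4n² ) ) / ( 1 + z²/n )

which stays inside [0, 1] and behaves sensibly at proportions near 0 or
1, where these validations typically operate. Label agreement between
annotators uses Cohen's κ = (p_o − p_e)/(1 − p_e); entity agreement
uses precision/recall/F1 with exact or overlap span matching. A
Wilson-width sample-size planner (`min_sample_size()`) inverts the
interval width: at sensitivity 0.95, prevalence 0.12 and a 10-point
target width it returns 700 reports (692 before rounding up to the
hundred).

## Worked example

```r
library(radphen)

ann <- annotate_report(paste0(
  "CLINICAL DETAILS: ?stroke\n",
  "REPORT: There is an old left parietal infarct. ",
  "There is established small vessel disease. No evidence of acute haemorrhage.\n",
  "CONCLUSION: Old cortical infarct and small vessel disease."))
ann
#> <radphen_annotation> report: 5 sentences, 12 entities, 6 relations
#>   labels: Ischaemic stroke, cortical, old; Small vessel disease

ann$entities[c(1, 4, 8), c("id", "type", "surface", "section_kind", "negated")]
#>    id                type     surface section_kind negated
#> 1  T1  stroke_unspecified      stroke      request   FALSE
#> 4  T4    ischaemic_stroke     infarct         body   FALSE
#> 8  T8 haemorrhagic_stroke haemorrhage         body    TRUE

ann$relations
#>   id     kind modifier_id target_id
#> 1 R1     time          T2        T4
#> 2 R2 location          T3        T4
#> 3 R3     time          T5        T6
#> 4 R4     time          T7        T8
#> 5 R5     time          T9       T11
#> 6 R6 location         T10       T11
```

Reading the output: the report gets exactly two labels. The old +
parietal modifiers attach to the body-section infarct (relations R1,
R2), producing *Ischaemic stroke, cortical, old*; the small vessel
disease entity needs no modifiers. The request-section "?stroke"
mention (T1) is recognized but ineligible for labelling, and the
negated haemorrhage (T8) contributes nothing — so no haemorrhagic label
appears despite "haemorrhage" being in the text.

Synthetic corpora with gold annotations:

```r
cfg <- synth_config(700, seed = 1)          # validation-profile label mix
corpus <- generate_corpus(cfg)
tab <- evaluate_labels(
  pred = lapply(corpus, function(sr) {
    a <- annotate_report(sr$report); list(report_id = a$report_id, labels = a$labels)
  }),
  gold = lapply(corpus, function(sr)
    list(report_id = sr$report_id, labels = sr$gold$labels)))
format_metrics_table(tab)
```

A command-line front end (`inst/cli/radphen.R`) wraps the same
functions as `annotate`, `evaluate`, `generate` and `stats`
subcommands.

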