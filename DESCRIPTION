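Package: radphen
Title: Rule-Based Phenotyping of Brain Imaging Radiology Reports
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A staged rule-based natural language processing pipeline that
    reads free-text brain CT/MR radiology reports and assigns 24
    cerebrovascular and neurological phenotype labels per report. Stages
    cover section zoning, sentence and token segmentation, coarse
    part-of-speech tagging, lemmatization, lexicon-driven named entity
    recognition, negation detection, chunk-based time/location relation
    extraction, and document-level label mapping. Also provides the
    evaluation layer used to validate such systems (per-phenotype
    sensitivity, specificity and positive predictive value with Wilson
    score intervals, F1, Cohen's kappa, entity-level precision/recall, and
    Wilson-width sample-size planning), brat standoff annotation
    input/output, and a synthetic report generator with gold annotations
    so the full pipeline is testable without access to governed clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
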