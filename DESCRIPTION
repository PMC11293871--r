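Package: dtirex
Title: Drug-Target Interaction Relation Extraction from Biomedical Text
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reusable pipeline for mining typed drug-target interactions
    from annotated biomedical abstracts. Reads and writes DrugProt-style
    corpus files (abstracts, entity spans, relations, predictions), builds
    entity-marker relation instances restricted to same-sentence
    chemical-gene pairs, augments them with chemical definitions and gene
    summaries keyed by normalized identifiers, computes a 576-dimensional
    protein sequence descriptor vector (amino acid and dipeptide
    composition plus physicochemical indices), trains multi-label
    classifiers over the 13 DrugProt relation types with a focal loss and
    a pluggable text encoder, averages seed-ensemble probabilities with
    per-class decision thresholds, and scores predictions with the
    challenge-style micro-averaged F1 protocol. A seeded synthetic corpus
    generator makes every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
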