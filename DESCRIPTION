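Package: bbrex
Title: Bacteria-Biotope Relation Extraction with Hybrid Sentence and Dependency-Path Attention Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A toolkit for binary entity-pair relation extraction from
    dependency-parsed biomedical text, built around the Bacteria Biotope
    (Lives_In) task. Reads BioNLP-ST standoff annotations and CoNLL-U parses,
    generates intra-sentence candidate instances with entity blinding and
    shortest dependency paths, and classifies them with a hybrid neural model:
    a bidirectional LSTM with additive and entity-oriented attention over the
    full sentence, combined with stacked multi-head self-attention (or a
    multiple-filter-width CNN) over the shortest dependency path. Includes
    relation-level precision/recall/F1 scoring with inter-sentence relations
    counted as false negatives, a multi-seed mean-F1 robustness protocol, a
    precision-recall cut-off sweep, and a synthetic-corpus generator with a
    planted dependency-path rule so the entire pipeline is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
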