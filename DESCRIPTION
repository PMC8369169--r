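Package: charner
Title: Character-Level Clinical Chinese Named Entity Recognition with
    Word-Character Attention Fusion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Character-level named entity recognition for traditional
    Chinese medicine (TCM) text over a five-class entity schema (clinical
    manifestation, syndrome, disease, treatment law, herb) with BIO
    tagging. Implements a word-character integrated attention module that
    fuses word/phrase semantics into per-character representations (a
    bilinear attention form and a masked multi-head self-attention form),
    a BiLSTM encoder and a linear-chain conditional random field trained
    by exact likelihood and decoded by Viterbi, token-level and O-filtered
    identification evaluation protocols plus strict entity-level metrics,
    a seeded generator of TCM-like synthetic corpora, greedy
    maximum-matching word segmentation, CoNLL/JSONL readers and writers,
    and a paired-seed ablation harness.
License: MIT
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
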