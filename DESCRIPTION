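Package: relminer
Title: Document-Level Biomedical Relation Extraction Pipeline
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: An end-to-end pipeline for mining typed relations from biomedical
    abstracts: named entity recognition (BIO token tagging with task-oriented
    dataset tags, and an alternative span-classification head), entity
    normalization against controlled vocabularies with a residual convolutional
    mention encoder and cosine retrieval, document-level bidirectional
    marker-based relation classification with multi-mention max pooling and
    projected-gradient-descent adversarial training, and novelty classification
    of extracted relations with logsumexp pooling. Includes a bit-exact
    PubTator reader and writer, document-level tuple-matching evaluation with
    bootstrap and McNemar significance tests, and seeded synthetic-corpus
    generators with a tiny pluggable contextual encoder so every stage trains
    and evaluates on one CPU.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
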