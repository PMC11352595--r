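# Shared fixtures, built in code.

# A small hand-crafted document with exact offsets:
# full text: "TP53 studies TP53 binds MDM2 . benign tumor was seen ."
fix_doc <- function() {
  document(
    "900001", "TP53 studies", "TP53 binds MDM2 . benign tumor was seen .",
    mentions = mention_table(
      start = c(0L, 13L, 24L, 31L),
      end = c(4L, 17L, 28L, 43L),
      surface = c("TP53", "TP53", "MDM2", "benign tumor"),
      type = c("Gene", "Gene", "Gene", "Disease"),
      ids = list("G1", "G1", "G2", "D1")),
    relations = relation_table("Bind", "G1", "G2", "Novel"))
}

# Small generator settings for fast module tests (the default spec is the
# full study condition used in the acceptance suite).
small_spec <- function(...) {
  synthetic_spec(n_docs = 30,
                 n_entities = c(Gene = 8, Disease = 10, Chemical = 8,
                                Species = 2, Variant = 3, CellLine = 2),
                 ...)
}

small_rescnn_config <- function(...) {
  do.call(rescnn_config, utils::modifyList(
    list(pooling = "max", learning_rate = 3e-3, n_encoder_blocks = 2,
         feature_size = 48, dropout = 0.1, n_filters = 32,
         epochs = 10, eval_every = 5), list(...)))
}

micro_prf <- function(gold_corpus, pred_corpus, what = c("ner", "relation"),
                      ...) {
  what <- match.arg(what)
  tot <- list(tp = 0, fp = 0, fn = 0)
  for (id in names(gold_corpus)) {
    g <- gold_corpus[[id]]
    p <- pred_corpus[[id]]
    m <- if (what == "ner") match_ner(g$mentions, p$mentions) else
      match_relations(corpus(list(g)), corpus(list(p)), ...)
    tot$tp <- tot$tp + m$tp; tot$fp <- tot$fp + m$fp; tot$fn <- tot$fn + m$fn
  }
  prf_from_counts(tot)
}

predict_corpus_relations <- function(model, docs, nd = NULL) {
  corpus(lapply(docs, function(d) {
    rels <- predict_doc_relations(model, d)
    if (!is.null(nd) && nrow(rels)) rels <- predict_novelty(nd, d, rels)
    document(d$doc_id, d$title, d$abstract, d$mentions, rels)
  }))
}
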