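#' Pipeline configuration
#'
#' The four stages run sequentially -- NER, EL, RE, ND -- each consuming the
#' previous stage's output. Gold-entities mode skips NER and EL and applies
#' RE and ND to the gold mentions and identifiers (the "gold standard
#' entities and IDs" evaluation setting).
#'
#' @param ner a fitted `token_ner` or `span_ner`, or `NULL` in gold-entities
#'   mode.
#' @param el list with `indexes` (named [build_synonym_index()] objects),
#'   optional `external` corpus, `lookup`, `threshold`; or `NULL` in
#'   gold-entities mode.
#' @param re a fitted `re_model`.
#' @param nd a fitted `nd_model`, or `NULL` to skip novelty.
#' @param gold_entities skip NER + EL and use gold mentions/identifiers.
#' @param tag [task_tag()] used at NER prediction time.
#' @param seed seed recorded in the manifest (prediction is deterministic).
#' @return a list of class `pipeline_config`.
#' @export
pipeline_config <- function(ner = NULL, el = NULL, re = NULL, nd = NULL,
                            gold_entities = FALSE, tag = task_tag("ALL"),
                            seed = 0L) {
  structure(list(ner = ner, el = el, re = re, nd = nd,
                 gold_entities = gold_entities, tag = tag, seed = seed),
            class = "pipeline_config")
}

#' Run the end-to-end extraction pipeline
#'
#' Applies NER, entity linking, relation extraction, and novelty detection
#' in sequence to every document, returning a new corpus of predictions
#' (input documents are never mutated). Stage requirements are checked
#' before any stage runs. A run manifest (configs, seed, stage flags) is
#' attached as attribute `"manifest"`.
#'
#' @param corpus_ an `rm_corpus` (text, plus gold annotations in
#'   gold-entities mode).
#' @param cfg a [pipeline_config()].
#' @return an `rm_corpus` of predicted documents.
#' @export
run_pipeline <- function(corpus_, cfg) {
  if (!cfg$gold_entities) {
    if (is.null(cfg$ner)) stop("pipeline requires an NER model (or gold_entities mode)")
    if (is.null(cfg$el)) stop("pipeline requires an EL configuration (or gold_entities mode)")
  }
  if (is.null(cfg$re)) stop("pipeline requires an RE model")
  out <- lapply(corpus_, function(doc) {
    if (cfg$gold_entities) {
      mentions <- doc$mentions
    } else {
      mentions <- if (inherits(cfg$ner, "span_ner")) {
        classify_spans(cfg$ner, doc)
      } else {
        predict_mentions(cfg$ner, doc, cfg$tag)
      }
      mentions <- postprocess_mentions(doc, mentions)
      tmp <- document(doc$doc_id, doc$title, doc$abstract, mentions)
      mentions <- hybrid_link(tmp, cfg$el$external %||% corpus(),
                              cfg$el$indexes %||% list(),
                              cfg$el$lookup, cfg$el$threshold)
    }
    pred <- document(doc$doc_id, doc$title, doc$abstract, mentions)
    rels <- predict_doc_relations(cfg$re, pred)
    if (!is.null(cfg$nd) && nrow(rels)) {
      rels <- predict_novelty(cfg$nd, pred, rels)
    }
    document(doc$doc_id, doc$title, doc$abstract, mentions, rels)
  })
  res <- corpus(out)
  attr(res, "manifest") <- list(
    gold_entities = cfg$gold_entities, tag = cfg$tag$name, seed = cfg$seed,
    stages = c(ner = !cfg$gold_entities, el = !cfg$gold_entities,
               re = TRUE, nd = !is.null(cfg$nd)))
  res
}
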