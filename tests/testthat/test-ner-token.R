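test_that("task tags validate the ALL coverage rule", {
  expect_equal(task_tag("ALL")$covered_types, relminer:::ENTITY_TYPES)
  expect_error(task_tag("ALL", "Gene"), "six entity types")
  expect_error(task_tag("GENE", relminer:::ENTITY_TYPES), "six entity types")
  expect_equal(task_tag("GENE", "Gene")$covered_types, "Gene")
})

test_that("encode_bio labels covered mentions and scopes outside labels", {
  text <- "Germline mutations of the human BRCA2 gene confer susceptibility to breast cancer."
  tokens <- tokenize_text(text)
  mentions <- mention_table(
    start = c(32L, 68L), end = c(37L, 81L),
    surface = c("BRCA2", "breast cancer"),
    type = c("Gene", "Disease"))
  # under the GENE task tag the disease stays unannotated outside
  labels <- encode_bio(tokens, mentions, task_tag("GENE", "Gene"))
  expect_equal(labels[tokens$token == "BRCA2"], "B-Gene")
  expect_equal(labels[tokens$token == "breast"], "O-GENE")
  expect_equal(labels[tokens$token == "cancer"], "O-GENE")
  # under ALL both are labeled
  labels_all <- encode_bio(tokens, mentions, task_tag("ALL"))
  expect_equal(labels_all[tokens$token == "breast"], "B-Disease")
  expect_equal(labels_all[tokens$token == "cancer"], "I-Disease")

  expect_equal(encode_bio(tokens, mention_table(), task_tag("ALL")),
               rep("O-ALL", nrow(tokens)))

  # 3-token mention -> B, I, I
  t3 <- tokenize_text("a b c d")
  m3 <- mention_table(0L, 5L, "a b c", "Chemical")
  expect_equal(encode_bio(t3, m3, task_tag("ALL")),
               c("B-Chemical", "I-Chemical", "I-Chemical", "O-ALL"))
})

test_that("decode_bio inverts encode_bio and repairs ill-formed sequences", {
  # round trip on generated documents
  for (doc in make_corpus(small_spec(), 5, "train")) {
    text <- doc_text(doc)
    tokens <- tokenize_text(text)
    labels <- encode_bio(tokens, doc$mentions, task_tag("ALL"))
    dec <- decode_bio(tokens, labels, text)
    expect_equal(dec$start, doc$mentions$start)
    expect_equal(dec$end, doc$mentions$end)
    expect_equal(dec$surface, doc$mentions$surface)
    expect_equal(dec$type, doc$mentions$type)
  }

  tokens <- tokenize_text("a bb cc d")
  # orphan-I run becomes a mention
  dec <- decode_bio(tokens, c("O-ALL", "I-Disease", "I-Disease", "O-ALL"),
                    "a bb cc d")
  expect_equal(nrow(dec), 1L)
  expect_equal(dec$surface, "bb cc")
  expect_equal(dec$type, "Disease")
  # type change inside a run splits it
  dec2 <- decode_bio(tokenize_text("x y"), c("B-Gene", "I-Disease"), "x y")
  expect_equal(dec2$type, c("Gene", "Disease"))
  expect_equal(dec2$surface, c("x", "y"))
  # decoded mentions never overlap
  set.seed(42)
  labs <- sample(c("B-Gene", "I-Gene", "I-Disease", "O-ALL"), 30, TRUE)
  toks <- tokenize_text(paste(letters[1:30], collapse = " "))
  dd <- decode_bio(toks, labs, paste(letters[1:30], collapse = " "))
  if (nrow(dd) > 1) expect_true(all(dd$start[-1] >= dd$end[-nrow(dd)]))
})

test_that("task-token wrapping is inverted by stripping", {
  tag <- task_tag("ALL")
  w <- wrap_task_tokens(letters[1:5], tag)
  expect_length(w, 7L)
  expect_equal(w[1], "<ALL>")
  expect_equal(w[7], "</ALL>")
  expect_equal(strip_task_tokens(w), letters[1:5])
})

test_that("merge_corpora unifies label spaces and counts instances", {
  cc <- make_corpus(small_spec(), 4, "train")
  gene_docs <- corpus(lapply(cc[1:2], function(d) {
    document(paste0(d$doc_id, "g"), d$title, d$abstract,
             d$mentions[d$mentions$type == "Gene", ], d$relations)
  }))
  merged <- merge_corpora(list(
    list(corpus = cc, tag = task_tag("ALL")),
    list(corpus = gene_docs, tag = task_tag("GENE", "Gene"))))
  expect_true(all(c("O-ALL", "O-GENE") %in% merged$labels))
  # ALL corpus at document granularity: one instance per doc
  n_all <- sum(vapply(merged$instances,
                      function(i) i$tag$name == "ALL", logical(1)))
  expect_equal(n_all, 4L)
  # sentence granularity for the auxiliary corpus: >= 1 per doc
  expect_gte(length(merged$instances) - n_all, 2L)

  single <- merge_corpora(list(list(corpus = cc, tag = task_tag("ALL"))))
  expect_length(single$instances, 4L)
})

test_that("token NER memorizes one document and trains deterministically", {
  cc <- make_corpus(small_spec(), 1, "train")
  enc <- make_tiny_encoder_for(small_spec())
  merged <- merge_corpora(list(list(corpus = cc, tag = task_tag("ALL"))))
  cfg <- token_ner_config(learning_rate = 1e-2, batch_size = 4, epochs = 30)
  m1 <- fit_token_ner(merged, enc, cfg, seed = 5)
  pred <- predict_mentions(m1, cc[[1]])
  res <- match_ner(cc[[1]]$mentions, pred)
  expect_equal(prf_from_counts(res)$f1, 100)

  # identical seeds and inputs give identical loss trajectories
  m2 <- fit_token_ner(merged, enc, cfg, seed = 5)
  expect_identical(m1$loss_history, m2$loss_history)
  expect_identical(m1$W, m2$W)

  # loss non-increasing (after the first epochs) on a single instance
  expect_true(all(diff(m1$loss_history[5:30]) <= 1e-8))
})

test_that("predicted mentions always satisfy the document invariants", {
  spec <- small_spec()
  cc <- make_corpus(spec, 8, "train")
  enc <- make_tiny_encoder_for(spec)
  merged <- merge_corpora(list(list(corpus = cc, tag = task_tag("ALL"))))
  m <- fit_token_ner(merged, enc,
                     token_ner_config(learning_rate = 1e-2, batch_size = 8,
                                      epochs = 5), seed = 6)
  for (doc in make_corpus(spec, 4, "dev")) {
    pm <- predict_mentions(m, doc)
    d2 <- document(doc$doc_id, doc$title, doc$abstract, pm)
    expect_equal(nrow(validate_document(d2)), 0L)
  }
})

test_that("post-processing merges adjacent fragments with the slash exception", {
  # same-type fragments with no separating character
  d <- document("1", "A(1)-adenosine receptor study", "")
  frags <- mention_table(c(0L, 1L), c(1L, 23L),
                         c("A", "(1)-adenosine receptor"),
                         c("Chemical", "Chemical"))
  out <- postprocess_mentions(d, frags)
  expect_equal(out$surface, "A(1)-adenosine receptor")
  expect_equal(nrow(out), 1L)

  # two Disease mentions separated by one non-slash character
  d2 <- document("2", "benign tumor", "")
  frags2 <- mention_table(c(0L, 7L), c(6L, 12L), c("benign", "tumor"),
                          c("Disease", "Disease"))
  out2 <- postprocess_mentions(d2, frags2)
  expect_equal(out2$surface, "benign tumor")

  # slash-separated diseases stay distinct
  d3 <- document("3", "colon/rectal pain", "")
  frags3 <- mention_table(c(0L, 6L), c(5L, 12L), c("colon", "rectal"),
                          c("Disease", "Disease"))
  expect_equal(nrow(postprocess_mentions(d3, frags3)), 2L)

  # different types with a gap stay distinct; merged ids reset
  expect_equal(out$ids[[1]], character(0))

  # idempotence and monotone count
  again <- postprocess_mentions(d2, out2)
  expect_equal(again, out2)
  expect_lte(nrow(out2), nrow(frags2))
})
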