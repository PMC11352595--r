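spec <- small_spec()
vocab <- make_vocabulary(spec)
enc <- make_tiny_encoder_for(spec)
cfg <- small_rescnn_config()
model0 <- rescnn_new(enc, cfg, seed = 21)
index0 <- build_synonym_index(vocab$table, model0)

test_that("mention normalization lowercases and strips outer punctuation", {
  expect_equal(normalize_mention("  Breast   Cancer. "), "breast cancer")
  expect_equal(normalize_mention("(TP53)"), "tp53")
  expect_equal(normalize_mention("a/b"), "a/b")
})

test_that("rescnn_encode is deterministic with a fixed output width", {
  v1 <- rescnn_encode(model0, vocab$table$synonym[1])
  v2 <- rescnn_encode(model0, vocab$table$synonym[1])
  expect_identical(v1, v2)
  for (s in vocab$table$synonym[1:5]) {
    expect_length(rescnn_encode(model0, s), cfg$feature_size)
  }
  expect_error(rescnn_encode(model0, "  ...  "), "empty")
})

test_that("max pooling output equals the max over pre-pool activations", {
  ids <- relminer:::rescnn_ids(model0, vocab$table$synonym[2])
  fw <- relminer:::rescnn_forward(model0, ids)
  expect_equal(fw$v, apply(fw$cache$Xtop, 2, max))
})

test_that("synonym index counts entries and keeps unit-norm vectors", {
  tab <- data.frame(identifier = rep(c("D1", "D2", "D3"), each = 2),
                    synonym = c("alpha pain", "alpha ache", "beta pain",
                                "beta ache", "gamma pain", "gamma ache"))
  idx <- build_synonym_index(tab, model0)
  expect_equal(nrow(idx$entries), 6L)
  # duplicate rows collapse
  idx2 <- build_synonym_index(rbind(tab, tab[1, ]), model0)
  expect_equal(nrow(idx2$entries), 6L)
  norms <- sqrt(rowSums(idx$vectors^2))
  expect_true(all(abs(norms - 1) < 1e-6))
  expect_error(build_synonym_index(tab[0, ], model0), "empty")
})

test_that("retrieval ranks an exact synonym first and matches brute force", {
  q <- vocab$table$synonym[7]
  top <- retrieve_topk(q, index0, 3)
  expect_equal(top$identifier[1],
               vocab$table$identifier[7])
  expect_equal(top$score[1], 1.0, tolerance = 1e-6)
  expect_true(all(diff(top$score) <= 1e-12))

  # brute-force cosine oracle over a 50-entry toy index
  sub <- vocab$table[1:50, ]
  idx <- build_synonym_index(sub, model0)
  for (q in c(sub$synonym[c(3, 17, 42)], "unrelated words")) {
    got <- retrieve_topk(q, idx, 10)
    v <- rescnn_encode(model0, q); v <- v / sqrt(sum(v^2))
    sc <- as.vector(idx$vectors %*% v)
    df <- data.frame(id = idx$entries$identifier, sc = sc)
    df <- df[order(-df$sc, df$id), ]
    df <- df[!duplicated(df$id), ][1:10, ]
    expect_equal(got$identifier, df$id)
    expect_equal(got$score, df$sc, tolerance = 1e-12)
  }

  # k >= number of identifiers returns them all
  all_ids <- unique(index0$entries$identifier)
  expect_equal(sort(retrieve_topk(q, index0, 10000)$identifier),
               sort(all_ids))
})

test_that("index augmentation grows monotonically and helps training mentions", {
  cc <- make_corpus(spec, 20, "train")
  aug <- augment_index_with_training(index0, cc,
                                     types = c("Disease", "Chemical"))
  expect_gte(nrow(aug$entries), nrow(index0$entries))
  expect_true(all(paste(index0$entries$identifier, index0$entries$name) %in%
                    paste(aug$entries$identifier, aug$entries$name)))

  # a linked mention absent from the vocabulary adds exactly one entry
  d <- document("x1", "zuzax syndrome seen", "",
                mention_table(0L, 14L, "zuzax syndrome", "Disease",
                              list("D999")))
  one <- augment_index_with_training(index0, corpus(list(d)))
  expect_equal(nrow(one$entries), nrow(index0$entries) + 1L)
  # unlinked mentions change nothing
  d$mentions$ids[[1]] <- character(0)
  expect_equal(nrow(augment_index_with_training(index0,
                                                corpus(list(d)))$entries),
               nrow(index0$entries))

  # augmentation improves top-1 on the training mentions themselves: build a
  # training corpus whose mention surfaces are ad-hoc strings absent from the
  # vocabulary (as real abstracts routinely contain), so pre-augmentation
  # retrieval must fail on some of them
  ids <- unique(vocab$table$identifier)[1:6]
  words <- c("cohort", "patients", "levels", "samples", "study", "reports")
  oov <- corpus(lapply(seq_along(ids), function(i) {
    surf <- paste(words[i], "finding")
    document(sprintf("oov%d", i), paste(surf, "seen"), "",
             mention_table(0L, nchar(surf), surf, "Disease",
                           ids = list(ids[i])))
  }))
  mset <- data.frame(s = vapply(oov, function(d) d$mentions$surface[1], ""),
                     id = ids)
  acc <- function(ix) mean(vapply(seq_len(nrow(mset)), function(i)
    retrieve_topk(mset$s[i], ix, 1)$identifier[1] == mset$id[i], logical(1)))
  aug_oov <- augment_index_with_training(index0, oov)
  expect_gt(acc(aug_oov), acc(index0))
  expect_equal(acc(aug_oov), 1)
})

test_that("triplet training improves held-out variant linking, 0 epochs is a no-op", {
  pairs <- data.frame(mention = vocab$table$synonym,
                      identifier = vocab$table$identifier)
  m_same <- fit_rescnn(pairs, index0,
                       small_rescnn_config(epochs = 0), seed = 2)
  expect_identical(m_same$params, model0$params)

  expect_warning(
    fit_rescnn(data.frame(mention = "x", identifier = "NOPE"), index0,
               small_rescnn_config(epochs = 0), seed = 2),
    "missing from index")

  trained <- fit_rescnn(pairs, index0, small_rescnn_config(epochs = 10),
                        seed = 22)
  # loss decreases over the early epochs
  lh <- attr(trained, "loss_history")
  expect_lt(mean(lh[4:6]), lh[1])
  top1_held <- function(model) {
    ix <- relminer:::index_refresh(index0, model)
    mean(vapply(seq_len(nrow(vocab$heldout)), function(i)
      retrieve_topk(vocab$heldout$synonym[i], ix, 1)$identifier[1] ==
        vocab$heldout$identifier[i], logical(1)))
  }
  expect_gt(top1_held(trained), top1_held(model0))
})

test_that("hybrid linking follows the retrieval / span-match / lookup order", {
  ext <- corpus(list(document(
    "d1", "ACTA2 level and TGFB studies", "",
    mention_table(c(0L, 16L), c(5L, 20L), c("ACTA2", "TGFB"),
                  c("Gene", "Gene"), ids = list("672", "7040")))))
  doc <- document(
    "d1", "ACTA2 level and TGFB studies", "",
    mention_table(c(2L, 16L), c(5L, 20L), c("TA2", "TGFB"),
                  c("Gene", "Gene")))
  linked <- hybrid_link(doc, ext, indexes = list())
  # partial overlap, same type -> external id; exact match -> its id
  expect_equal(linked$ids[[1]], "672")
  expect_equal(linked$ids[[2]], "7040")
  # spans and types are never altered
  expect_equal(linked$start, doc$mentions$start)
  expect_equal(linked$type, doc$mentions$type)

  # surface equal to a vocabulary synonym resolves through retrieval
  dd <- document("d2", paste(vocab$table$synonym[1], "seen"), "",
                 mention_table(0L, nchar(vocab$table$synonym[1]),
                               vocab$table$synonym[1],
                               vocab$variant_map$type[1]))
  got <- hybrid_link(dd, corpus(),
                     indexes = setNames(list(index0),
                                        vocab$variant_map$type[1]))
  expect_equal(got$ids[[1]], vocab$table$identifier[1])

  # lookup-dictionary fallback for a non-overlapping mention
  d3 <- document("d9", "TGFB again", "",
                 mention_table(0L, 4L, "TGFB", "Gene"))
  got3 <- hybrid_link(d3, ext, indexes = list())
  expect_equal(got3$ids[[1]], "7040")

  # nothing matches -> mention stays unlinked
  d4 <- document("d9", "XYZQ again", "",
                 mention_table(0L, 4L, "XYZQ", "Gene"))
  expect_equal(hybrid_link(d4, ext, indexes = list())$ids[[1]], character(0))
})
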