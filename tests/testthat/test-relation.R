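test_that("candidate generation enumerates allowed unordered pairs", {
  d <- document(
    "1", "a b c d", "",
    mention_table(c(0L, 2L, 4L, 6L), c(1L, 3L, 5L, 7L),
                  c("a", "b", "c", "d"),
                  c("Gene", "Disease", "Chemical", "Gene"),
                  ids = list("G1", "D1", "C1", "G2")),
    relation_table("Association", "G1", "D1"))
  cand <- generate_candidate_pairs(d)
  expect_equal(nrow(cand), 6L)   # C(4, 2)
  expect_equal(cand$label[cand$id1 == "D1" & cand$id2 == "G1"], "Association")
  expect_equal(sum(cand$label == "NoRelation"), 5L)

  # type-pair restriction excludes combinations outside the allowed set
  cand2 <- generate_candidate_pairs(d, allowed = "Disease|Gene")
  expect_equal(nrow(cand2), 2L)
  expect_true(all(cand2$id1 %in% c("D1")))

  d$mentions <- d$mentions[1:2, ]
  expect_equal(nrow(generate_candidate_pairs(d)), 1L)
})

test_that("entity markers wrap every mention and strip back to the original", {
  d <- document("1", "X binds Y", "",
                mention_table(c(0L, 8L), c(1L, 9L), c("X", "Y"),
                              c("Gene", "Gene"), ids = list("G1", "G2")))
  tokens <- tokenize_text(doc_text(d))
  mk <- insert_entity_markers(tokens, d, "G1", "G2")
  expect_equal(mk$tokens,
               c("[E]", "X", "[/E]", "binds", "[E]", "Y", "[/E]"))
  expect_equal(mk$tokens[mk$open1], "[E]")
  # stripping markers restores the original tokens
  expect_equal(mk$tokens[!is.na(mk$orig)], tokens$token)

  # an entity with three mentions gains six markers
  d3 <- document("2", "Q here Q there Q end W", "",
                 mention_table(c(0L, 7L, 15L, 21L), c(1L, 8L, 16L, 22L),
                               c("Q", "Q", "Q", "W"),
                               rep("Gene", 4), ids = list("Q", "Q", "Q", "W")))
  mk3 <- insert_entity_markers(tokenize_text(doc_text(d3)), d3, "Q", "W")
  expect_length(mk3$open1, 3L)
  expect_equal(sum(mk3$tokens == "[E]") + sum(mk3$tokens == "[/E]"), 8L)
})

test_that("mention-pair selection is the brute-force dot-product argmax", {
  set.seed(13)
  for (i in 1:20) {
    M1 <- matrix(rnorm(sample(1:4, 1) * 6), ncol = 6)
    M2 <- matrix(rnorm(sample(1:4, 1) * 6), ncol = 6)
    sel <- select_mention_pair(M1, M2)
    S <- M1 %*% t(M2)
    expect_equal(S[sel$i, sel$j], max(S))
    # positive scaling leaves the selected indices unchanged
    sel2 <- select_mention_pair(3.7 * M1, M2 * 0.25)
    expect_equal(c(sel$i, sel$j), c(sel2$i, sel2$j))
  }
  one <- select_mention_pair(matrix(1:3, 1), matrix(4:6, 1))
  expect_equal(c(one$i, one$j), c(1L, 1L))
})

test_that("directional representations satisfy the block-swap identity", {
  e1 <- rnorm(8); e2 <- rnorm(8)
  dr <- directional_representations(e1, e2)
  expect_length(dr$v_fwd, 24L)
  expect_equal(dr$v_rev[1:8], dr$v_fwd[9:16])
  expect_equal(dr$v_rev[9:16], dr$v_fwd[1:8])
  expect_equal(dr$v_rev[17:24], dr$v_fwd[17:24])
})

test_that("pair logits and loss follow the bidirectional contract", {
  set.seed(3)
  cls <- list(W = matrix(rnorm(24 * 9, sd = 0.3), 24, 9), b = rnorm(9))
  e <- rnorm(8)
  lg <- pair_logits(directional_representations(e, e)$v_fwd,
                    directional_representations(e, e)$v_rev, cls)
  expect_equal(lg$fwd, lg$rev)  # e1 == e2 makes both directions equal
  expect_length(lg$fwd, 9L)
  zero <- list(W = matrix(0, 24, 9), b = 1:9 / 10)
  expect_equal(pair_logits(rnorm(24), rnorm(24), zero)$fwd, 1:9 / 10)

  # uniform logits over 9 labels: loss = 2 ln 9
  u <- rep(0, 9)
  expect_equal(re_loss(u, u, "Association"), 2 * log(9), tolerance = 1e-12)
  # confident correct logits drive the loss toward zero
  conf <- c(50, rep(0, 8))
  expect_lt(re_loss(conf, conf, "Association"), 1e-12)
  # equals an independent recomputation of the two cross-entropy terms
  lf <- rnorm(9); lr <- rnorm(9); y <- 4
  ce <- function(l, y) -log(exp(l[y]) / sum(exp(l)))
  expect_equal(re_loss(lf, lr, y), ce(lf, y) + ce(lr, y), tolerance = 1e-10)
  # symmetric under exchanging the two directional vectors
  expect_equal(re_loss(lf, lr, y), re_loss(lr, lf, y))
})

test_that("prediction is invariant under exchanging entity roles", {
  set.seed(5)
  cls <- list(W = matrix(rnorm(24 * 9, sd = 0.3), 24, 9), b = rnorm(9))
  for (i in 1:50) {
    e1 <- rnorm(8); e2 <- rnorm(8)
    a <- directional_representations(e1, e2)
    b <- directional_representations(e2, e1)
    la <- pair_logits(a$v_fwd, a$v_rev, cls)
    lb <- pair_logits(b$v_fwd, b$v_rev, cls)
    expect_identical(predict_relation(la$fwd, la$rev),
                     predict_relation(lb$fwd, lb$rev))
  }
  expect_equal(predict_relation(c(10, rep(0, 8)), c(10, rep(0, 8))),
               "Association")
  # ties resolve to the lowest label index
  expect_equal(predict_relation(rep(0, 9), rep(0, 9)), "Association")
  # brute-force argmax of the summed vectors
  for (i in 1:20) {
    lf <- rnorm(9); lr <- rnorm(9)
    expect_equal(predict_relation(lf, lr),
                 re_label_set()[which.max(lf + lr)])
  }
})

test_that("PGD steps ascend and never escape the radius ball", {
  cfg <- adversarial_config()
  expect_equal(cfg$n_steps, 3L)
  X <- matrix(0, 4, 6)
  # zero gradient leaves the perturbation at zero
  st <- pgd_step(X, X * 0, cfg, NULL)
  expect_equal(st$delta, X)
  set.seed(8)
  delta <- NULL
  for (k in 1:10) {
    g <- matrix(rnorm(24, sd = 10^runif(1, -3, 3)), 4, 6)
    st <- pgd_step(X, g, cfg, delta)
    delta <- st$delta
    expect_lte(sqrt(sum(delta^2)), cfg$radius + 1e-12)
    expect_equal(st$X_pert, X + delta)
  }
})

test_that("the training loop applies exactly n_steps perturbations per instance", {
  spec <- small_spec()
  cc <- make_corpus(spec, 2, "train")
  enc <- make_tiny_encoder_for(spec)
  calls <- 0L
  local_mocked_bindings(
    pgd_step = function(X, grad, cfg, delta) {
      calls <<- calls + 1L
      if (is.null(delta)) delta <- X * 0
      list(X_pert = X + delta, delta = delta)
    },
    .package = "relminer")
  n_inst <- sum(vapply(cc, function(d) nrow(generate_candidate_pairs(
    d, allowed_type_pairs(cc))), integer(1)))
  fit_re_corpus(cc, enc, re_config(epochs = 1, learning_rate = 1e-3,
                                   batch_size = 64),
                adversarial_config(n_steps = 3), seed = 1)
  expect_equal(calls, 3L * n_inst)
})

test_that("the RE model memorizes a small toy set", {
  spec <- small_spec()
  cc <- make_corpus(spec, 5, "train")
  enc <- make_tiny_encoder_for(spec)
  m <- fit_re_corpus(cc, enc, re_config(epochs = 25, learning_rate = 2e-3,
                                        batch_size = 8),
                     adv = NULL, seed = 31)
  pred <- predict_corpus_relations(m, cc)
  expect_equal(micro_prf(cc, pred, "relation")$f1, 100)
})

test_that("predictions are invariant under permuting each entity's mentions", {
  spec <- small_spec()
  cc <- make_corpus(spec, 5, "train")
  enc <- make_tiny_encoder_for(spec)
  m <- fit_re_corpus(cc, enc, re_config(epochs = 3, learning_rate = 2e-3,
                                        batch_size = 8),
                     adv = NULL, seed = 31)
  for (d in cc[1:3]) {
    base <- predict_doc_relations(m, d)
    perm <- d
    set.seed(4)
    perm$mentions <- perm$mentions[sample.int(nrow(perm$mentions)), ]
    got <- predict_doc_relations(m, perm)
    expect_equal(got[order(got$id1, got$id2), ],
                 base[order(base$id1, base$id2), ], ignore_attr = TRUE)
  }
})
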