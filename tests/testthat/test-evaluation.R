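test_that("micro P/R/F1 follows the counting conventions", {
  r <- prf_from_counts(3, 1, 2)
  expect_equal(round_half_up(r$precision), 75)
  expect_equal(round_half_up(r$recall), 60)
  expect_equal(round_half_up(r$f1), 66.67)
  expect_equal(prf_from_counts(0, 0, 0), list(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf_from_counts(5, 0, 0)$f1, 100)
})

test_that("harmonic F1 reproduces reported overall rows", {
  expect_equal(f1_from_pr(94.05, 93.01), 93.53)
  expect_equal(f1_from_pr(68.60, 62.10), 65.19)
  expect_equal(f1_from_pr(100, 100), 100)
  expect_equal(f1_from_pr(0, 0), 0)
})

test_that("mention matching separates exact, partial, and missed", {
  g <- fix_doc()$mentions
  same <- match_ner(g, g)
  expect_equal(c(same$fp, same$fn), c(0L, 0L))
  expect_equal(same$tp, nrow(g))

  empty <- match_ner(g, mention_table())
  expect_equal(empty$tp, 0L)
  expect_equal(empty$fn, nrow(g))

  # a one-character boundary shift of one mention: partial, not exact
  p <- g[1, ]
  p$start <- p$start + 1L
  shift <- match_ner(g[1, ], p)
  expect_equal(shift$tp, 0L)
  expect_equal(shift$partial, 1L)
  expect_equal(c(shift$fp, shift$fn), c(1L, 1L))
  # per-type counts sum to the micro counts
  expect_equal(sum(same$per_type$tp), same$tp)
})

test_that("entity-linking evaluation uses document-level tuple sets", {
  g <- fix_doc()
  same <- match_el(corpus(list(g)), corpus(list(g)))
  expect_equal(prf_from_counts(same)$precision, 100)
  expect_equal(prf_from_counts(same)$recall, 100)

  # multi-identifier mentions expand to multiple tuples
  p <- fix_doc()
  p$mentions$ids[[4]] <- c("D1", "D2")
  r <- match_el(corpus(list(g)), corpus(list(p)))
  expect_equal(r$fp, 1L)           # D2 is spurious
  expect_equal(r$fn, 0L)

  # repeated identifiers in one document collapse to a single tuple
  expect_equal(nrow(relminer:::el_tuples(corpus(list(g)))), 3L)  # G1, G2, D1
})

test_that("relation matching honors type, novelty, and undirectedness", {
  g <- fix_doc()
  p <- fix_doc()
  p$relations$type <- "Association"
  strict <- match_relations(corpus(list(g)), corpus(list(p)))
  expect_equal(c(strict$tp, strict$fp, strict$fn), c(0L, 1L, 1L))
  lax <- match_relations(corpus(list(g)), corpus(list(p)),
                         require_type = FALSE)
  expect_equal(lax$tp, 1L)

  # reversed identifier order still matches (relations are undirected)
  p2 <- fix_doc()
  p2$relations <- relation_table("Bind", "G2", "G1", "Novel")
  expect_equal(match_relations(corpus(list(g)), corpus(list(p2)))$tp, 1L)

  # the novelty flag tightens the key
  p3 <- fix_doc()
  p3$relations$novelty <- "No"
  expect_equal(match_relations(corpus(list(g)), corpus(list(p3)),
                               require_novelty = TRUE)$tp, 0L)
})

test_that("top-k accuracy is monotone and matches a hand recount", {
  set.seed(23)
  ids <- sprintf("D%02d", 1:40)
  gold <- sample(ids, 30, TRUE)
  cands <- lapply(gold, function(g) {
    ranked <- c(sample(ids, 25))
    if (runif(1) < 0.6) ranked <- c(g, setdiff(ranked, g))
    data.frame(identifier = ranked, score = sort(runif(length(ranked)),
                                                 decreasing = TRUE))
  })
  acc <- topk_accuracy(cands, gold)
  expect_true(all(diff(acc) >= 0))
  for (k in c(1, 5, 10, 20)) {
    manual <- mean(vapply(seq_along(gold), function(i)
      gold[i] %in% cands[[i]]$identifier[seq_len(k)], logical(1)))
    expect_equal(unname(acc[paste0("Acc@", k)]), manual)
  }
  perfect <- lapply(gold, function(g) data.frame(identifier = g, score = 1))
  expect_true(all(topk_accuracy(perfect, gold) == 1))
})

test_that("corpus statistics tally exactly and recover planted counts", {
  spec <- small_spec()
  cc <- make_corpus(spec, 15, "train")
  st <- corpus_stats(cc)
  expect_equal(sum(st$mentions), st$mention_total)
  expect_equal(sum(st$relations), st$relation_total)
  planted <- attr(cc, "planted")
  expect_equal(st$mentions, planted$mentions)
  expect_equal(st$relations, planted$relations)

  # three dominant relation types as a share of the benchmark totals
  expect_equal(prop_pct(6146 + 3517 + 2342, 12539), 95.74)
})

test_that("bootstrap F1 differences are seeded and match an oracle", {
  spec <- small_spec()
  gold <- make_corpus(spec, 10, "train")
  enc <- make_tiny_encoder_for(spec)
  degrade <- function(cc, drop) {
    corpus(lapply(cc, function(d) {
      keep <- seq_len(nrow(d$mentions))
      keep <- keep[keep %% drop != 0]
      document(d$doc_id, d$title, d$abstract, d$mentions[keep, ], d$relations)
    }))
  }
  pa <- degrade(gold, 5)
  pb <- degrade(gold, 3)
  same <- bootstrap_f1_diff(gold, pa, pa, n_samples = 50, sample_size = 8,
                            seed = 9)
  expect_equal(same$mean_diff, 0)
  expect_equal(c(same$ci_low, same$ci_high), c(0, 0))

  b1 <- bootstrap_f1_diff(gold, pa, pb, n_samples = 100, sample_size = 8,
                          seed = 9)
  b2 <- bootstrap_f1_diff(gold, pa, pb, n_samples = 100, sample_size = 8,
                          seed = 9)
  expect_identical(b1, b2)
  expect_lte(b1$ci_low, b1$ci_high)

  # independent re-implementation with the same seed stream
  counts <- function(pred) t(vapply(names(gold), function(id) {
    m <- match_ner(gold[[id]]$mentions, pred[[id]]$mentions)
    c(m$tp, m$fp, m$fn)
  }, numeric(3)))
  ca <- counts(pa); cb <- counts(pb)
  oracle <- relminer:::with_seed(9, vapply(1:100, function(s) {
    idx <- sample.int(10, 8, replace = TRUE)
    f <- function(cm) prf_from_counts(sum(cm[idx, 1]), sum(cm[idx, 2]),
                                      sum(cm[idx, 3]))$f1
    f(ca) - f(cb)
  }, numeric(1)))
  expect_equal(b1$mean_diff, mean(oracle))
  expect_equal(c(b1$ci_low, b1$ci_high),
               unname(quantile(oracle, c(0.025, 0.975))))
})

test_that("McNemar's exact test matches closed forms", {
  expect_equal(mcnemar_test(3, 1), 0.625)
  expect_equal(mcnemar_test(0, 0), 1.0)
  expect_equal(mcnemar_test(5, 5), 1.0)
  # symmetric counts maximize the p-value at fixed total
  for (n in 2:8) {
    ps <- vapply(0:n, function(k) mcnemar_test(k, n - k), numeric(1))
    expect_equal(max(ps), ps[floor(n / 2) + 1])
  }
  # chi-square variant with continuity correction
  expect_equal(mcnemar_test(10, 25, exact = FALSE),
               pchisq((abs(10 - 25) - 1)^2 / 35, 1, lower.tail = FALSE))
})

test_that("relation error breakdown partitions fp and fn", {
  g <- fix_doc()
  g$relations <- relation_table(c("Bind", "Association"),
                                c("G1", "G1"), c("G2", "D1"),
                                c("Novel", "No"))
  p <- fix_doc()
  # one type-confused prediction (right pair, wrong type) + one spurious pair
  p$mentions$ids[[4]] <- "D9"
  p$relations <- relation_table(c("Association", "Association"),
                                c("G1", "G2"), c("G2", "D9"))
  eb <- re_error_breakdown(corpus(list(g)), corpus(list(p)))
  expect_equal(eb$fp$type_confusion, 0.5)
  expect_equal(eb$fp$non_related, 0.5)
  expect_equal(eb$fp$type_confusion + eb$fp$non_related, 1)
  expect_equal(eb$fn$n, 2L)

  clean <- re_error_breakdown(corpus(list(g)), corpus(list(g)))
  expect_equal(clean$fp$n, 0L)
  expect_equal(clean$fp$type_confusion, 0)
})
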