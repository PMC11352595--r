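#' Micro precision/recall/F1 from match counts
#'
#' Percent scale, full precision internally, conventionally reported at two
#' decimals. By convention each component is 0 when its denominator is 0.
#'
#' @param tp,fp,fn non-negative counts (or a list with those fields as first
#'   argument).
#' @return list with `precision`, `recall`, `f1` (percent).
#' @export
prf_from_counts <- function(tp, fp = NULL, fn = NULL) {
  if (is.list(tp)) { fp <- tp$fp; fn <- tp$fn; tp <- tp$tp }
  p <- if (tp + fp > 0) 100 * tp / (tp + fp) else 0
  r <- if (tp + fn > 0) 100 * tp / (tp + fn) else 0
  list(precision = p, recall = r, f1 = if (p + r > 0) 2 * p * r / (p + r) else 0)
}

#' Harmonic-mean F1 from precision and recall (percent scale)
#'
#' @param p,r precision and recall in `[0, 100]`.
#' @param digits decimals for reporting (half-up); `NULL` for full precision.
#' @return the F1 score.
#' @export
f1_from_pr <- function(p, r, digits = 2) {
  f <- ifelse(p + r > 0, 2 * p * r / (p + r), 0)
  if (!is.null(digits)) f <- round_half_up(f, digits)
  f
}

#' Percentage share of a part in a total
#'
#' @param part,total counts.
#' @param digits decimals (half-up).
#' @return `100 * part / total`, rounded.
#' @export
prop_pct <- function(part, total, digits = 2) {
  round_half_up(100 * part / total, digits)
}

mention_key <- function(m) paste(m$start, m$end, m$type)

#' Match predicted against gold mentions
#'
#' True positives are exact matches (boundaries and entity type); partially
#' matching predictions (span-overlapping, same type, boundaries not exact)
#' are reported separately but still count as errors for precision/recall.
#'
#' @param gold,pred [mention_table()]s for one document.
#' @return list with `tp`, `fp`, `fn`, `partial`, and `per_type` (a
#'   `data.frame` of counts by entity type).
#' @export
match_ner <- function(gold, pred) {
  gk <- mention_key(gold); pk <- mention_key(pred)
  gused <- rep(FALSE, nrow(gold)); pok <- rep(FALSE, nrow(pred))
  for (i in seq_len(nrow(pred))) {
    j <- which(!gused & gk == pk[i])
    if (length(j)) { gused[j[1]] <- TRUE; pok[i] <- TRUE }
  }
  partial <- 0L
  pmiss <- which(!pok)
  gmiss <- which(!gused)
  gpart <- rep(FALSE, nrow(gold))
  for (i in pmiss) {
    j <- gmiss[!gpart[gmiss] &
                 gold$type[gmiss] == pred$type[i] &
                 gold$end[gmiss] > pred$start[i] &
                 gold$start[gmiss] < pred$end[i]]
    if (length(j)) { gpart[j[1]] <- TRUE; partial <- partial + 1L }
  }
  per_type <- do.call(rbind, lapply(ENTITY_TYPES, function(ty) {
    data.frame(type = ty,
               tp = sum(pok & pred$type == ty),
               fp = sum(!pok & pred$type == ty),
               fn = sum(!gused & gold$type == ty))
  }))
  list(tp = sum(pok), fp = sum(!pok), fn = sum(!gused), partial = partial,
       per_type = per_type)
}

el_tuples <- function(corpus_) {
  out <- list()
  for (doc in corpus_) {
    m <- doc$mentions
    for (i in seq_len(nrow(m))) {
      for (id in m$ids[[i]]) {
        out[[length(out) + 1L]] <- data.frame(
          doc_id = doc$doc_id, type = m$type[i], identifier = id,
          stringsAsFactors = FALSE)
      }
    }
  }
  unique(do.call(rbind, out) %||%
           data.frame(doc_id = character(0), type = character(0),
                      identifier = character(0)))
}

#' Document-level entity-linking evaluation
#'
#' Both corpora are expanded to sets of (PMID, entity type, identifier)
#' tuples -- a mention mapped to multiple identifiers yields multiple tuples,
#' and repeated identifiers within a document collapse to one tuple -- and
#' compared as sets.
#'
#' @param gold,pred `rm_corpus` objects.
#' @return list with overall `tp`, `fp`, `fn` and `per_type` counts.
#' @export
match_el <- function(gold, pred) {
  g <- el_tuples(gold); p <- el_tuples(pred)
  gk <- paste(g$doc_id, g$type, g$identifier, sep = "\t")
  pk <- paste(p$doc_id, p$type, p$identifier, sep = "\t")
  per_type <- do.call(rbind, lapply(ENTITY_TYPES, function(ty) {
    gt <- gk[g$type == ty]; pt <- pk[p$type == ty]
    data.frame(type = ty, tp = sum(pt %in% gt), fp = sum(!(pt %in% gt)),
               fn = sum(!(gt %in% pt)))
  }))
  list(tp = sum(pk %in% gk), fp = sum(!(pk %in% gk)), fn = sum(!(gk %in% pk)),
       per_type = per_type)
}

relation_keys <- function(corpus_, require_type, require_novelty) {
  out <- character(0)
  for (doc in corpus_) {
    r <- doc$relations
    if (!nrow(r)) next
    key <- paste(doc$doc_id, pmin(r$id1, r$id2), pmax(r$id1, r$id2), sep = "\t")
    if (require_type) key <- paste(key, r$type, sep = "\t")
    if (require_novelty) key <- paste(key, r$novelty, sep = "\t")
    out <- c(out, unique(key))
  }
  out
}

#' Document-level relation evaluation
#'
#' Relations are undirected: pairs are canonicalized by sorting identifiers.
#' The match key is (PMID, pair), extended with the relation type and/or the
#' novelty label on request ("RE" vs "RE + ND" settings; dropping the type
#' gives binary relation classification).
#'
#' @param gold,pred `rm_corpus` objects.
#' @param require_type include the relation type in the match key.
#' @param require_novelty include the novelty label in the match key.
#' @return list with `tp`, `fp`, `fn`.
#' @export
match_relations <- function(gold, pred, require_type = TRUE,
                            require_novelty = FALSE) {
  gk <- relation_keys(gold, require_type, require_novelty)
  pk <- relation_keys(pred, require_type, require_novelty)
  list(tp = sum(pk %in% gk), fp = sum(!(pk %in% gk)), fn = sum(!(gk %in% pk)))
}

#' Top-k retrieval accuracy
#'
#' Fraction of mentions whose gold identifier appears among the k
#' highest-scoring candidates; non-decreasing in k.
#'
#' @param candidates list of [retrieve_topk()]-style data.frames, one per
#'   mention.
#' @param gold character vector of gold identifiers, parallel to
#'   `candidates`.
#' @param ks accuracy cutoffs (default 1, 5, 10, 20).
#' @return named numeric vector `Acc@k`.
#' @export
topk_accuracy <- function(candidates, gold, ks = c(1, 5, 10, 20)) {
  stopifnot(length(candidates) == length(gold))
  vapply(ks, function(k) {
    mean(mapply(function(cand, g) {
      g %in% utils::head(cand$identifier, k)
    }, candidates, gold))
  }, numeric(1)) |> stats::setNames(paste0("Acc@", ks))
}

#' Corpus composition statistics
#'
#' Mention counts per entity type, relation counts per relation type,
#' unique-entity counts per type (distinct identifiers), and the percentage
#' share of each relation type, at two decimals.
#'
#' @param corpus_ an `rm_corpus`.
#' @return list with `mentions`, `relations`, `unique_entities` (named
#'   counts), `relation_share_pct`, and totals.
#' @export
corpus_stats <- function(corpus_) {
  mcount <- stats::setNames(numeric(length(ENTITY_TYPES)), ENTITY_TYPES)
  rcount <- stats::setNames(numeric(length(RELATION_TYPES)), RELATION_TYPES)
  ids_by_type <- stats::setNames(vector("list", length(ENTITY_TYPES)), ENTITY_TYPES)
  for (doc in corpus_) {
    m <- doc$mentions
    for (ty in ENTITY_TYPES) {
      sel <- m$type == ty
      mcount[ty] <- mcount[ty] + sum(sel)
      ids_by_type[[ty]] <- union(ids_by_type[[ty]], unlist(m$ids[sel]))
    }
    r <- doc$relations
    for (ty in RELATION_TYPES) rcount[ty] <- rcount[ty] + sum(r$type == ty)
  }
  uniq <- vapply(ids_by_type, length, integer(1))
  total_r <- sum(rcount)
  list(mentions = mcount, mention_total = sum(mcount),
       relations = rcount, relation_total = total_r,
       unique_entities = uniq,
       relation_share_pct = if (total_r > 0) prop_pct(rcount, total_r) else
         rcount * 0)
}

# Per-document (tp, fp, fn) under a given task matcher, for resampling.
doc_counts <- function(gold, pred, task = c("ner", "relation")) {
  task <- match.arg(task)
  t(vapply(names(gold), function(id) {
    g <- gold[[id]]
    p <- if (id %in% names(pred)) pred[[id]] else
      document(id, g$title, g$abstract)
    c_ <- if (task == "ner") match_ner(g$mentions, p$mentions) else
      match_relations(corpus(list(g)), corpus(list(p)))
    c(tp = c_$tp, fp = c_$fp, fn = c_$fn)
  }, numeric(3)))
}

#' Bootstrap the F1 difference between two systems
#'
#' Draws `sample_size` documents with replacement `n_samples` times,
#' computes each system's overall F1 on every sample, and reports the mean
#' difference (system A minus system B) with a 2.5/97.5 percentile
#' confidence interval. Seeded and reproducible.
#'
#' @param gold gold `rm_corpus`.
#' @param pred_a,pred_b predicted corpora sharing `gold`'s doc ids.
#' @param n_samples number of bootstrap samples (default 1000).
#' @param sample_size documents per sample (default 100).
#' @param seed integer seed.
#' @param task `"ner"` (mention matching) or `"relation"`.
#' @return list with `mean_diff`, `ci_low`, `ci_high`, `n_samples`,
#'   `sample_size`, `seed`.
#' @export
bootstrap_f1_diff <- function(gold, pred_a, pred_b, n_samples = 1000,
                              sample_size = 100, seed = 1, task = "ner") {
  ca <- doc_counts(gold, pred_a, task)
  cb <- doc_counts(gold, pred_b, task)
  n <- length(gold)
  diffs <- with_seed(seed, {
    vapply(seq_len(n_samples), function(s) {
      idx <- sample.int(n, sample_size, replace = TRUE)
      fa <- prf_from_counts(sum(ca[idx, "tp"]), sum(ca[idx, "fp"]),
                            sum(ca[idx, "fn"]))$f1
      fb <- prf_from_counts(sum(cb[idx, "tp"]), sum(cb[idx, "fp"]),
                            sum(cb[idx, "fn"]))$f1
      fa - fb
    }, numeric(1))
  })
  ci <- unname(stats::quantile(diffs, c(0.025, 0.975), type = 7))
  list(mean_diff = mean(diffs), ci_low = ci[1], ci_high = ci[2],
       n_samples = n_samples, sample_size = sample_size, seed = seed)
}

#' McNemar's test on discordant pairs
#'
#' Exact two-sided binomial test by default (`2 * P(X <= min)` under
#' `Binomial(n01 + n10, 1/2)`, capped at 1); the chi-square variant with
#' continuity correction is available by flag. With no discordant pairs the
#' p-value is 1.
#'
#' @param n01,n10 discordant counts (system A wrong / B right, and vice
#'   versa).
#' @param exact use the exact binomial test (default) or chi-square.
#' @return the two-sided p-value.
#' @export
mcnemar_test <- function(n01, n10, exact = TRUE) {
  stopifnot(n01 >= 0, n10 >= 0)
  n <- n01 + n10
  if (n == 0) return(1.0)
  if (exact) {
    min(1, 2 * stats::pbinom(min(n01, n10), n, 0.5))
  } else {
    stat <- (abs(n01 - n10) - 1)^2 / n
    stats::pchisq(stat, df = 1, lower.tail = FALSE)
  }
}

#' Breakdown of relation-extraction errors
#'
#' Splits false positives into type confusion (the pair matches a gold pair
#' but with a different relation type) versus non-related pairs, and false
#' negatives analogously (gold relations whose pair was predicted with the
#' wrong type versus missed entirely). Fractions per side sum to 1 whenever
#' errors exist, 0 otherwise.
#'
#' @param gold,pred `rm_corpus` objects.
#' @return list with `fp` and `fn`, each holding `type_confusion` and
#'   `non_related` fractions plus the error count `n`.
#' @export
re_error_breakdown <- function(gold, pred) {
  gk_t <- relation_keys(gold, TRUE, FALSE)
  pk_t <- relation_keys(pred, TRUE, FALSE)
  gk_p <- relation_keys(gold, FALSE, FALSE)
  pk_p <- relation_keys(pred, FALSE, FALSE)
  strip_type <- function(k) sub("\t[^\t]+$", "", k)
  fp_keys <- pk_t[!(pk_t %in% gk_t)]
  fn_keys <- gk_t[!(gk_t %in% pk_t)]
  side <- function(keys, other_pairs) {
    n <- length(keys)
    if (!n) {
      return(list(type_confusion = 0, non_related = 0, n = 0L))
    }
    conf <- sum(strip_type(keys) %in% other_pairs)
    list(type_confusion = conf / n, non_related = (n - conf) / n, n = n)
  }
  list(fp = side(fp_keys, gk_p), fn = side(fn_keys, pk_p))
}
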