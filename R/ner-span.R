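#' Enumerate candidate token spans
#'
#' All contiguous token spans up to a maximum width; the count is the
#' truncated triangular number `sum_{w=1..min(L,n)} (n - w + 1)`.
#'
#' @param n_tokens number of tokens in the sequence.
#' @param max_span_len maximum span width (default 30, the maximum entity
#'   span length observed in the reference training data).
#' @return `data.frame` with 1-based inclusive columns `start`, `end`,
#'   `width`.
#' @export
enumerate_spans <- function(n_tokens, max_span_len = 30) {
  stopifnot(n_tokens >= 1)
  widths <- seq_len(min(max_span_len, n_tokens))
  starts <- unlist(lapply(widths, function(w) seq_len(n_tokens - w + 1L)))
  width <- rep(widths, times = n_tokens - widths + 1L)
  data.frame(start = starts, end = starts + width - 1L, width = width)
}

#' Configuration for the span-classification NER model
#'
#' Defaults follow the reference tuning (learning rate 1e-5, 39 epochs,
#' batch size 32, maximum span length 30).
#'
#' @param learning_rate,epochs,batch_size training hyperparameters.
#' @param max_span_len maximum candidate span width in tokens.
#' @param width_embedding_dim size of the learned span-width embedding.
#' @param neg_ratio negatives kept per positive span during training
#'   (candidate spans grow quadratically, so negatives are subsampled).
#' @return a list of class `span_ner_config`.
#' @export
span_ner_config <- function(learning_rate = 1e-5, epochs = 39, batch_size = 32,
                            max_span_len = 30, width_embedding_dim = 8,
                            neg_ratio = 4) {
  structure(list(learning_rate = learning_rate, epochs = epochs,
                 batch_size = batch_size, max_span_len = max_span_len,
                 width_embedding_dim = width_embedding_dim,
                 neg_ratio = neg_ratio),
            class = "span_ner_config")
}

#' Span representation from encoder outputs
#'
#' The representation of a candidate span is the concatenation of its start
#' token's contextual vector, its end token's contextual vector, and a
#' learned width embedding.
#'
#' @param H encoder output matrix (`n x dim`).
#' @param span one row of [enumerate_spans()] (or a list with `start`, `end`,
#'   `width`).
#' @param width_emb width-embedding matrix (`max_span_len x w_dim`).
#' @return numeric vector of length `2 * dim + w_dim`.
#' @export
span_representation <- function(H, span, width_emb) {
  c(H[span$start, ], H[span$end, ], width_emb[span$width, ])
}

# Matrix of representations for many spans at once.
span_rep_matrix <- function(H, spans, width_emb) {
  cbind(H[spans$start, , drop = FALSE],
        H[spans$end, , drop = FALSE],
        width_emb[spans$width, , drop = FALSE])
}

# Gold class index per span: entity type when the span equals a mention's
# token range, else the "none" class (K + 1).
span_gold_classes <- function(spans, tokens, mentions) {
  cls <- rep(length(ENTITY_TYPES) + 1L, nrow(spans))
  for (i in seq_len(nrow(mentions))) {
    idx <- tokens_in_span(tokens, mentions$start[i], mentions$end[i])
    if (!length(idx)) next
    hit <- which(spans$start == idx[1] & spans$end == idx[length(idx)])
    if (length(hit)) cls[hit] <- match(mentions$type[i], ENTITY_TYPES)
  }
  cls
}

#' Fit the span-classification NER model
#'
#' Candidate spans are scored over the six entity types plus a "none" class
#' by a two-layer feed-forward network on [span_representation()]s; the
#' encoder is fine-tuned jointly. Negative spans are subsampled per instance
#' (seeded) to keep the quadratic candidate set tractable.
#'
#' @param corpus_ an `rm_corpus` of training documents with gold mentions.
#' @param encoder a `tiny_encoder`.
#' @param cfg a [span_ner_config()].
#' @param seed integer seed.
#' @param hidden width of the feed-forward hidden layer.
#' @return an object of class `span_ner`.
#' @export
fit_span_ner <- function(corpus_, encoder, cfg = span_ner_config(), seed = 1,
                         hidden = 64) {
  K <- length(ENTITY_TYPES) + 1L
  d <- encoder$dim
  in_dim <- 2 * d + cfg$width_embedding_dim
  params <- with_seed(seed + 1L, c(encoder$params, list(
    Wd = ginit(cfg$max_span_len, cfg$width_embedding_dim,
               fan_in = cfg$width_embedding_dim),
    Ws1 = ginit(in_dim, hidden), bs1 = numeric(hidden),
    Ws2 = ginit(hidden, K), bs2 = numeric(K))))
  opt <- adam_init(params)
  docs <- lapply(corpus_, function(doc) {
    tokens <- tokenize_text(doc_text(doc))
    tokens <- tokens[seq_len(min(nrow(tokens), encoder$max_len)), , drop = FALSE]
    spans <- enumerate_spans(nrow(tokens), cfg$max_span_len)
    list(ids = encoder_token_ids(encoder, tokens$token), tokens = tokens,
         spans = spans, cls = span_gold_classes(spans, tokens, doc$mentions))
  })
  loss_history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ep_loss <- 0; ep_n <- 0L
      for (dd in docs[sample.int(length(docs))]) {
        pos <- which(dd$cls != K)
        neg <- which(dd$cls == K)
        if (length(neg) > cfg$neg_ratio * max(length(pos), 1L)) {
          neg <- sample(neg, cfg$neg_ratio * max(length(pos), 1L))
        }
        keep <- c(pos, neg)
        if (!length(keep)) next
        spans <- dd$spans[keep, , drop = FALSE]
        y <- dd$cls[keep]
        encoder$params <- params[names(encoder$params)]
        X <- encoder_embed(encoder, dd$ids)
        fwd <- encoder_forward(encoder, X)
        R <- span_rep_matrix(fwd$H, spans, params$Wd)
        Z <- pmax(R %*% params$Ws1 + rep(params$bs1, each = nrow(R)), 0)
        logits <- Z %*% params$Ws2 + rep(params$bs2, each = nrow(Z))
        P <- softmax_rows(logits)
        m <- nrow(R)
        ep_loss <- ep_loss - sum(log(pmax(P[cbind(seq_len(m), y)], 1e-12)))
        ep_n <- ep_n + m
        dlog <- P; dlog[cbind(seq_len(m), y)] <- dlog[cbind(seq_len(m), y)] - 1
        dlog <- dlog / m
        grads <- lapply(params, function(p) p * 0)
        grads$Ws2 <- crossprod(Z, dlog)
        grads$bs2 <- colSums(dlog)
        dZ <- (dlog %*% t(params$Ws2)) * (Z > 0)
        grads$Ws1 <- crossprod(R, dZ)
        grads$bs1 <- colSums(dZ)
        dR <- dZ %*% t(params$Ws1)
        dH <- matrix(0, nrow(fwd$H), d)
        dstart <- dR[, 1:d, drop = FALSE]
        dend <- dR[, (d + 1):(2 * d), drop = FALSE]
        dwidth <- dR[, (2 * d + 1):ncol(dR), drop = FALSE]
        dH <- dH + rowsum_into(dstart, spans$start, nrow(dH))
        dH <- dH + rowsum_into(dend, spans$end, nrow(dH))
        grads$Wd <- grads$Wd + rowsum_into(dwidth, spans$width, cfg$max_span_len)
        bk <- encoder_backward(encoder, fwd$cache, dH)
        for (nm in names(bk$grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
        grads$E <- accumulate_embedding_grad(grads$E, dd$ids, bk$dX)
        st <- adam_step(opt, params, grads, cfg$learning_rate)
        opt <- st$opt; params <- st$params
      }
      loss_history <- c(loss_history, ep_loss / max(ep_n, 1L))
    }
  })
  encoder$params <- params[names(encoder$params)]
  structure(list(encoder = encoder,
                 Wd = params$Wd, Ws1 = params$Ws1, bs1 = params$bs1,
                 Ws2 = params$Ws2, bs2 = params$bs2, cfg = cfg, seed = seed,
                 loss_history = loss_history),
            class = "span_ner")
}

# Sum rows of `m` into a `nout x ncol(m)` matrix by index.
rowsum_into <- function(m, idx, nout) {
  agg <- rowsum(m, group = idx)
  out <- matrix(0, nout, ncol(m))
  out[as.integer(rownames(agg)), ] <- agg
  out
}

#' Classify candidate spans of a document into mentions
#'
#' Scores all spans, drops those whose argmax is the "none" class, then
#' resolves overlaps greedily by descending classifier confidence so the
#' output mentions never overlap.
#'
#' @param model a fitted `span_ner`.
#' @param doc an `rm_document`.
#' @return a [mention_table()] of predicted, unlinked mentions.
#' @export
classify_spans <- function(model, doc) {
  text <- doc_text(doc)
  tokens <- tokenize_text(text)
  if (!nrow(tokens)) return(mention_table())
  tokens <- tokens[seq_len(min(nrow(tokens), model$encoder$max_len)), , drop = FALSE]
  spans <- enumerate_spans(nrow(tokens), model$cfg$max_span_len)
  ids <- encoder_token_ids(model$encoder, tokens$token)
  H <- encoder_forward(model$encoder, encoder_embed(model$encoder, ids))$H
  R <- span_rep_matrix(H, spans, model$Wd)
  Z <- pmax(R %*% model$Ws1 + rep(model$bs1, each = nrow(R)), 0)
  P <- softmax_rows(Z %*% model$Ws2 + rep(model$bs2, each = nrow(Z)))
  cls <- max.col(P, ties.method = "first")
  conf <- P[cbind(seq_len(nrow(P)), cls)]
  keep <- which(cls != length(ENTITY_TYPES) + 1L)
  keep <- keep[order(-conf[keep])]
  taken <- rep(FALSE, nrow(tokens))
  sel <- integer(0)
  for (i in keep) {
    rng <- spans$start[i]:spans$end[i]
    if (any(taken[rng])) next
    taken[rng] <- TRUE
    sel <- c(sel, i)
  }
  if (!length(sel)) return(mention_table())
  sel <- sel[order(spans$start[sel])]
  starts <- tokens$start[spans$start[sel]]
  ends <- tokens$end[spans$end[sel]]
  mention_table(starts, ends, substring(text, starts + 1L, ends),
                ENTITY_TYPES[cls[sel]])
}
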