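#' Normalize mention or synonym text
#'
#' Lowercases, collapses internal whitespace, and strips outer punctuation;
#' applied to every string before indexing or encoding so that trivial
#' surface variation does not reach the encoder.
#'
#' @param x character vector.
#' @return normalized character vector.
#' @export
normalize_mention <- function(x) {
  x <- tolower(trimws(x))
  x <- gsub("[[:space:]]+", " ", x)
  x <- gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)
  trimws(x)
}

#' Configuration for the ResCNN mention encoder
#'
#' The architecture follows the residual convolutional entity-linking
#' encoder: frozen token embeddings from a contextual model, `n_encoder_blocks`
#' blocks of a multi-width convolution bank (300 filters by default),
#' a position-wise feed-forward layer and a residual connection, then a
#' pooling layer. Tuned optima for the two vocabularies are exposed as
#' [rescnn_config_disease()] (attention pooling, 4 blocks) and
#' [rescnn_config_chemical()] (max pooling, 3 blocks); both use learning rate
#' 1e-3, feature size 256, dropout 0.25.
#'
#' @param pooling `"max"`, `"mean"`, or `"attention"`.
#' @param learning_rate Adam learning rate.
#' @param n_encoder_blocks number of residual conv blocks.
#' @param feature_size output (and per-block) feature dimension.
#' @param dropout dropout rate on the convolution bank during training.
#' @param n_filters convolution filters per width.
#' @param epochs,eval_every training schedule.
#' @param widths convolution filter widths (odd).
#' @param margin triplet-loss margin on cosine similarity.
#' @return a list of class `rescnn_config`.
#' @export
rescnn_config <- function(pooling = c("max", "mean", "attention"),
                          learning_rate = 1e-3, n_encoder_blocks = 3,
                          feature_size = 256, dropout = 0.25, n_filters = 300,
                          epochs = 100, eval_every = 5, widths = c(1, 3, 5),
                          margin = 0.2) {
  structure(list(pooling = match.arg(pooling), learning_rate = learning_rate,
                 n_encoder_blocks = n_encoder_blocks,
                 feature_size = feature_size, dropout = dropout,
                 n_filters = n_filters, epochs = epochs,
                 eval_every = eval_every, widths = widths, margin = margin),
            class = "rescnn_config")
}

#' @rdname rescnn_config
#' @param ... overrides passed through to [rescnn_config()].
#' @export
rescnn_config_disease <- function(...) {
  do.call(rescnn_config, utils::modifyList(
    list(pooling = "attention", learning_rate = 1e-3, n_encoder_blocks = 4,
         feature_size = 256, dropout = 0.25), list(...)))
}

#' @rdname rescnn_config
#' @export
rescnn_config_chemical <- function(...) {
  do.call(rescnn_config, utils::modifyList(
    list(pooling = "max", learning_rate = 1e-3, n_encoder_blocks = 3,
         feature_size = 256, dropout = 0.25), list(...)))
}

# Shift rows of X by k positions (row t of the result holds X[t + k], zeros
# outside). The adjoint of shift_k is shift_{-k}.
shift_k <- function(X, k) {
  n <- nrow(X)
  if (k == 0 || n == 0) return(X)
  if (abs(k) >= n) return(matrix(0, n, ncol(X)))
  if (k > 0) rbind(X[-seq_len(k), , drop = FALSE], matrix(0, k, ncol(X)))
  else rbind(matrix(0, -k, ncol(X)), X[seq_len(n + k), , drop = FALSE])
}

window_mat <- function(X, w) {
  hw <- (w - 1L) / 2L
  do.call(cbind, lapply(seq(-hw, hw), function(k) shift_k(X, k)))
}

#' Initialize a ResCNN mention encoder
#'
#' @param embedder a `tiny_encoder` whose embedding table supplies the frozen
#'   token embeddings.
#' @param cfg a [rescnn_config()].
#' @param seed integer seed for weight initialization.
#' @return an object of class `rescnn`.
#' @export
rescnn_new <- function(embedder, cfg = rescnn_config(), seed = 1) {
  d_e <- embedder$dim
  F_ <- cfg$feature_size
  nf <- cfg$n_filters
  with_seed(seed, {
    params <- list(Win = ginit(d_e, F_))
    for (b in seq_len(cfg$n_encoder_blocks)) {
      for (w in cfg$widths) {
        params[[sprintf("Wc%d_%d", b, w)]] <- ginit(w * F_, nf)
        params[[sprintf("bc%d_%d", b, w)]] <- numeric(nf)
      }
      params[[sprintf("Wf%d", b)]] <- ginit(length(cfg$widths) * nf, F_)
      params[[sprintf("bf%d", b)]] <- numeric(F_)
    }
    if (cfg$pooling == "attention") params$a <- stats::rnorm(F_, sd = 1 / sqrt(F_))
    structure(list(vocab = embedder$vocab, E = embedder$params$E,
                   d_e = d_e, cfg = cfg, params = params, seed = seed),
              class = "rescnn")
  })
}

#' @export
print.rescnn <- function(x, ...) {
  cat(sprintf("<rescnn: %d blocks, %d filters x widths {%s}, feature %d, %s pooling>\n",
              x$cfg$n_encoder_blocks, x$cfg$n_filters,
              paste(x$cfg$widths, collapse = ","),
              x$cfg$feature_size, x$cfg$pooling))
  invisible(x)
}

rescnn_ids <- function(model, text) {
  norm <- normalize_mention(text)
  toks <- tokenize_text(norm)$token
  if (!length(toks)) stop("mention text empty after normalization: ", dQuote(text))
  idx <- model$vocab[toks]
  idx[is.na(idx)] <- model$vocab[["[UNK]"]]
  unname(idx)
}

rescnn_forward <- function(model, ids, train = FALSE) {
  cfg <- model$cfg
  p <- model$params
  X <- model$E[ids, , drop = FALSE] %*% p$Win
  cache <- list(X0 = model$E[ids, , drop = FALSE], blocks = list())
  for (b in seq_len(cfg$n_encoder_blocks)) {
    blk <- list(Xin = X)
    Zs <- list()
    for (w in cfg$widths) {
      C <- window_mat(X, w)
      A <- C %*% p[[sprintf("Wc%d_%d", b, w)]] +
        rep(p[[sprintf("bc%d_%d", b, w)]], each = nrow(X))
      blk[[paste0("C", w)]] <- C
      blk[[paste0("A", w)]] <- A
      Zs[[as.character(w)]] <- pmax(A, 0)
    }
    Zcat <- do.call(cbind, Zs)
    if (train && cfg$dropout > 0) {
      mask <- matrix(stats::rbinom(length(Zcat), 1, 1 - cfg$dropout),
                     nrow(Zcat)) / (1 - cfg$dropout)
      Zcat <- Zcat * mask
      blk$mask <- mask
    }
    blk$Zcat <- Zcat
    X <- X + (Zcat %*% p[[sprintf("Wf%d", b)]] +
                rep(p[[sprintf("bf%d", b)]], each = nrow(X)))
    cache$blocks[[b]] <- blk
  }
  cache$Xtop <- X
  if (cfg$pooling == "max") {
    v <- apply(X, 2, max)
    cache$argmax <- max.col(t(X), ties.method = "first")
  } else if (cfg$pooling == "mean") {
    v <- colMeans(X)
  } else {
    s <- as.vector(X %*% p$a)
    wgt <- softmax_vec(s)
    v <- as.vector(crossprod(X, wgt))
    cache$att_w <- wgt
  }
  list(v = v, cache = cache)
}

rescnn_backward <- function(model, cache, dv) {
  cfg <- model$cfg
  p <- model$params
  X <- cache$Xtop
  n <- nrow(X)
  grads <- lapply(p, function(q) q * 0)
  if (cfg$pooling == "max") {
    dX <- matrix(0, n, ncol(X))
    dX[cbind(cache$argmax, seq_len(ncol(X)))] <- dv
  } else if (cfg$pooling == "mean") {
    dX <- matrix(dv / n, n, ncol(X), byrow = TRUE)
  } else {
    wgt <- cache$att_w
    dX <- outer(wgt, dv)
    dwgt <- as.vector(X %*% dv)
    ds <- wgt * (dwgt - sum(wgt * dwgt))
    grads$a <- as.vector(crossprod(X, ds))
    dX <- dX + outer(ds, p$a)
  }
  for (b in rev(seq_len(cfg$n_encoder_blocks))) {
    blk <- cache$blocks[[b]]
    dF <- dX  # residual: gradient flows both into the FFN branch and Xin
    grads[[sprintf("Wf%d", b)]] <- crossprod(blk$Zcat, dF)
    grads[[sprintf("bf%d", b)]] <- colSums(dF)
    dZcat <- dF %*% t(p[[sprintf("Wf%d", b)]])
    if (!is.null(blk$mask)) dZcat <- dZcat * blk$mask
    nf <- cfg$n_filters
    dXin <- dX
    for (wi in seq_along(cfg$widths)) {
      w <- cfg$widths[wi]
      cols <- ((wi - 1) * nf + 1):(wi * nf)
      dZ <- dZcat[, cols, drop = FALSE] * (blk[[paste0("A", w)]] > 0)
      grads[[sprintf("Wc%d_%d", b, w)]] <- crossprod(blk[[paste0("C", w)]], dZ)
      grads[[sprintf("bc%d_%d", b, w)]] <- colSums(dZ)
      dC <- dZ %*% t(p[[sprintf("Wc%d_%d", b, w)]])
      hw <- (w - 1L) / 2L
      F_ <- cfg$feature_size
      for (ki in seq_along(seq(-hw, hw))) {
        k <- seq(-hw, hw)[ki]
        dXin <- dXin + shift_k(dC[, ((ki - 1) * F_ + 1):(ki * F_), drop = FALSE], -k)
      }
    }
    dX <- dXin
  }
  grads$Win <- crossprod(cache$X0, dX)
  grads
}

#' Encode a mention string into the retrieval embedding space
#'
#' Deterministic in evaluation mode: identical strings always map to
#' identical vectors.
#'
#' @param model a `rescnn`.
#' @param text mention text (non-empty after normalization).
#' @return numeric vector of length `cfg$feature_size`.
#' @export
rescnn_encode <- function(model, text) {
  rescnn_forward(model, rescnn_ids(model, text))$v
}

#' Build a synonym index from a vocabulary table
#'
#' One entry per distinct (identifier, normalized synonym) pair; every entry
#' is embedded with the mention encoder and unit-normalized for cosine
#' retrieval.
#'
#' @param vocab `data.frame` with columns `identifier` and `synonym` (the
#'   layout of MEDIC / CTD chemical exports reduced to two columns).
#' @param model a `rescnn` mention encoder.
#' @param source tag recorded on entries (default `"vocabulary"`).
#' @return an object of class `synonym_index` with `entries`, unit-norm
#'   `vectors`, and the encoder reference `model`.
#' @export
build_synonym_index <- function(vocab, model, source = "vocabulary") {
  if (!nrow(vocab)) stop("empty vocabulary table")
  entries <- data.frame(identifier = as.character(vocab$identifier),
                        name = normalize_mention(vocab$synonym),
                        source = source, stringsAsFactors = FALSE)
  entries <- entries[entries$name != "", , drop = FALSE]
  entries <- unique(entries[, c("identifier", "name", "source")])
  rownames(entries) <- NULL
  idx <- structure(list(entries = entries, model = model), class = "synonym_index")
  index_embed(idx, seq_len(nrow(entries)))
}

# (Re-)embed entries at rows `rows`, keeping others.
index_embed <- function(index, rows) {
  V <- index$vectors
  if (is.null(V)) V <- matrix(0, 0, index$model$cfg$feature_size)
  if (nrow(V) < nrow(index$entries)) {
    V <- rbind(V, matrix(0, nrow(index$entries) - nrow(V), ncol(V)))
  }
  for (i in rows) {
    v <- rescnn_encode(index$model, index$entries$name[i])
    V[i, ] <- v / max(l2norm(v), 1e-12)
  }
  index$vectors <- V
  index
}

# Re-embed the whole index with a (newly trained) encoder.
index_refresh <- function(index, model = index$model) {
  index$model <- model
  index_embed(index, seq_len(nrow(index$entries)))
}

#' @export
print.synonym_index <- function(x, ...) {
  cat(sprintf("<synonym_index: %d entries, %d identifiers>\n",
              nrow(x$entries), length(unique(x$entries$identifier))))
  invisible(x)
}

#' Augment a synonym index with corpus training mentions
#'
#' Appends every (identifier, mention surface) pair found on linked mentions
#' of the corpus as additional index entries (source `"corpus"`). Growth is
#' monotone: no existing entry is removed.
#'
#' @param index a `synonym_index`.
#' @param corpus_ an `rm_corpus` with gold identifiers.
#' @param types restrict to these entity types (default: all).
#' @return the augmented index.
#' @export
augment_index_with_training <- function(index, corpus_, types = NULL) {
  rows <- list()
  for (doc in corpus_) {
    m <- doc$mentions
    for (i in seq_len(nrow(m))) {
      if (!is.null(types) && !(m$type[i] %in% types)) next
      for (id in m$ids[[i]]) {
        rows[[length(rows) + 1L]] <- data.frame(
          identifier = id, name = normalize_mention(m$surface[i]),
          source = "corpus", stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) return(index)
  new <- unique(do.call(rbind, rows))
  new <- new[new$name != "", , drop = FALSE]
  key <- paste(index$entries$identifier, index$entries$name)
  new <- new[!(paste(new$identifier, new$name) %in% key), , drop = FALSE]
  if (!nrow(new)) return(index)
  first_new <- nrow(index$entries) + 1L
  index$entries <- rbind(index$entries, new)
  rownames(index$entries) <- NULL
  index_embed(index, first_new:nrow(index$entries))
}

#' Retrieve the top-k candidate identifiers for a mention
#'
#' Cosine similarity between the encoded mention and all index entries;
#' candidates are deduplicated at the identifier level (each identifier keeps
#' its best-scoring synonym) and ties are broken by (score descending,
#' identifier ascending).
#'
#' @param text mention text.
#' @param index a `synonym_index`.
#' @param k number of candidates.
#' @return `data.frame` with columns `identifier`, `score` (descending).
#' @export
retrieve_topk <- function(text, index, k = 1) {
  stopifnot(k >= 1)
  v <- rescnn_encode(index$model, text)
  v <- v / max(l2norm(v), 1e-12)
  scores <- as.vector(index$vectors %*% v)
  ord <- order(-scores, index$entries$identifier)
  best <- ord[!duplicated(index$entries$identifier[ord])]
  best <- best[seq_len(min(k, length(best)))]
  data.frame(identifier = index$entries$identifier[best],
             score = scores[best], stringsAsFactors = FALSE)
}

# d cos(a,b) / d a
dcos_da <- function(a, b) {
  na <- max(l2norm(a), 1e-12); nb <- max(l2norm(b), 1e-12)
  cs <- sum(a * b) / (na * nb)
  b / (na * nb) - cs * a / (na * na)
}

#' Train the ResCNN mention encoder against a synonym index
#'
#' Online hard-negative triplet loss on cosine similarity (margin
#' `cfg$margin`): each training mention is pulled toward the best-matching
#' synonym of its gold identifier and pushed away from the highest-scoring
#' synonym of any other identifier, with hard negatives mined from the
#' current index. Pairs whose identifier is absent from the index are
#' skipped with a warning. Training with 0 epochs returns the initial
#' encoder unchanged.
#'
#' @param pairs `data.frame` with columns `mention`, `identifier`.
#' @param index a `synonym_index` (its `model` supplies the initial weights).
#' @param cfg a [rescnn_config()].
#' @param seed integer seed.
#' @return a trained `rescnn` with attributes `loss_history` and
#'   `eval_history` (top-1 accuracy on the training pairs every
#'   `eval_every` epochs).
#' @export
fit_rescnn <- function(pairs, index, cfg = index$model$cfg, seed = 1) {
  model <- index$model
  model$cfg <- cfg
  known <- unique(index$entries$identifier)
  miss <- !(pairs$identifier %in% known)
  if (any(miss)) {
    warning(sum(miss), " training pair(s) with identifier missing from index; skipped")
    pairs <- pairs[!miss, , drop = FALSE]
  }
  if (!nrow(pairs) || cfg$epochs == 0) return(model)
  opt <- adam_init(model$params)
  loss_history <- numeric(0)
  eval_history <- data.frame(epoch = integer(0), top1 = numeric(0))
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      index <- index_refresh(index, model)
      ep_loss <- 0
      for (i in sample.int(nrow(pairs))) {
        ids_a <- rescnn_ids(model, pairs$mention[i])
        fa <- rescnn_forward(model, ids_a, train = TRUE)
        va <- fa$v / max(l2norm(fa$v), 1e-12)
        scores <- as.vector(index$vectors %*% va)
        gold <- index$entries$identifier == pairs$identifier[i]
        pi_ <- which(gold)[which.max(scores[gold])]
        ni_ <- which(!gold)[which.max(scores[!gold])]
        fp <- rescnn_forward(model, rescnn_ids(model, index$entries$name[pi_]),
                             train = TRUE)
        fn_ <- rescnn_forward(model, rescnn_ids(model, index$entries$name[ni_]),
                              train = TRUE)
        cs <- function(x, y) sum(x * y) / (max(l2norm(x), 1e-12) * max(l2norm(y), 1e-12))
        loss <- max(0, cfg$margin - cs(fa$v, fp$v) + cs(fa$v, fn_$v))
        ep_loss <- ep_loss + loss
        if (loss <= 0) next
        da <- -dcos_da(fa$v, fp$v) + dcos_da(fa$v, fn_$v)
        dp <- -dcos_da(fp$v, fa$v)
        dn <- dcos_da(fn_$v, fa$v)
        g1 <- rescnn_backward(model, fa$cache, da)
        g2 <- rescnn_backward(model, fp$cache, dp)
        g3 <- rescnn_backward(model, fn_$cache, dn)
        grads <- Map(function(a, b, c) a + b + c, g1, g2, g3)
        st <- adam_step(opt, model$params, grads, cfg$learning_rate)
        opt <- st$opt; model$params <- st$params
      }
      loss_history <- c(loss_history, ep_loss / nrow(pairs))
      if (ep %% cfg$eval_every == 0 || ep == cfg$epochs) {
        idx_eval <- index_refresh(index, model)
        hit <- vapply(seq_len(nrow(pairs)), function(i) {
          retrieve_topk(pairs$mention[i], idx_eval, 1)$identifier[1] ==
            pairs$identifier[i]
        }, logical(1))
        eval_history <- rbind(eval_history,
                              data.frame(epoch = ep, top1 = mean(hit)))
      }
    }
  })
  attr(model, "loss_history") <- loss_history
  attr(model, "eval_history") <- eval_history
  model
}

#' Build an exact-surface lookup dictionary from external predictions
#'
#' Maps (entity type, normalized surface) to the most frequent identifier
#' assigned by the external linker; used as a fallback for mentions the
#' retrieval and span-matching routes cannot resolve.
#'
#' @param external an `rm_corpus` of external-linker predictions.
#' @return named character vector keyed by `"<type>\t<surface>"`.
#' @export
build_surface_lookup <- function(external) {
  tab <- list()
  for (doc in external) {
    m <- doc$mentions
    for (i in seq_len(nrow(m))) {
      for (id in m$ids[[i]]) {
        key <- paste(m$type[i], normalize_mention(m$surface[i]), sep = "\t")
        tab[[key]] <- c(tab[[key]], id)
      }
    }
  }
  vapply(tab, function(ids) names(sort(table(ids), decreasing = TRUE))[1],
         character(1))
}

#' Hybrid entity linking
#'
#' Disease and Chemical mentions are linked by top-1 cosine retrieval against
#' their synonym indexes (optionally gated by a similarity floor). All other
#' types are linked by span-matching against an external linker's
#' predictions: an exact (start, end, type) match first, then partial overlap
#' of the same type (at least one shared character; largest overlap, then
#' leftmost, wins). Mentions still unlinked fall back to the exact-surface
#' lookup dictionary. Spans and types are never altered, only identifiers.
#'
#' @param doc an `rm_document` whose mentions are to be linked.
#' @param external `rm_corpus` of external predictions covering `doc$doc_id`.
#' @param indexes named list of `synonym_index` objects keyed by entity type
#'   (typically `Disease` and `Chemical`).
#' @param lookup optional result of [build_surface_lookup()]; built from
#'   `external` when `NULL`.
#' @param threshold optional cosine floor below which retrieval results are
#'   discarded (default: none; the top-1 candidate is always taken).
#' @return the mention table of `doc` with `ids` filled where resolved.
#' @export
hybrid_link <- function(doc, external = corpus(), indexes = list(),
                        lookup = NULL, threshold = NULL) {
  if (is.null(lookup)) lookup <- build_surface_lookup(external)
  m <- doc$mentions
  ext <- if (doc$doc_id %in% names(external)) external[[doc$doc_id]]$mentions else
    mention_table()
  for (i in seq_len(nrow(m))) {
    ty <- m$type[i]
    linked <- character(0)
    if (ty %in% names(indexes)) {
      cand <- tryCatch(retrieve_topk(m$surface[i], indexes[[ty]], 1),
                       error = function(e) NULL)
      if (!is.null(cand) && nrow(cand) &&
          (is.null(threshold) || cand$score[1] >= threshold)) {
        linked <- cand$identifier[1]
      }
    } else if (nrow(ext)) {
      same <- which(ext$type == ty)
      exact <- same[ext$start[same] == m$start[i] & ext$end[same] == m$end[i]]
      if (length(exact)) {
        linked <- ext$ids[[exact[1]]]
      } else {
        ov <- pmin(ext$end[same], m$end[i]) - pmax(ext$start[same], m$start[i])
        hit <- same[ov > 0]
        if (length(hit)) {
          ovh <- ov[ov > 0]
          best <- hit[order(-ovh, ext$start[hit])][1]
          linked <- ext$ids[[best]]
        }
      }
    }
    if (!length(linked)) {
      key <- paste(ty, normalize_mention(m$surface[i]), sep = "\t")
      if (key %in% names(lookup)) linked <- unname(lookup[[key]])
    }
    m$ids[[i]] <- linked
  }
  m
}
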