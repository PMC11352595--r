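#' Relation label set
#'
#' The eight relation types plus `NoRelation`; `NoRelation` is kept last so
#' deterministic tie-breaking ("lowest label index") can never invent a
#' relation over a real type tie.
#'
#' @return character vector of length 9.
#' @export
re_label_set <- function() c(RELATION_TYPES, "NoRelation")

#' Allowed entity-type pairs for candidate generation
#'
#' The set of unordered entity-type combinations that carry at least one gold
#' relation in a training corpus; recomputed at training time and stored with
#' the model.
#'
#' @param corpus_ an `rm_corpus` with gold relations and linked mentions.
#' @return character vector of keys `"TypeA|TypeB"` (types sorted).
#' @export
allowed_type_pairs <- function(corpus_) {
  keys <- character(0)
  for (doc in corpus_) {
    ty <- entity_types_of(doc)
    r <- doc$relations
    for (i in seq_len(nrow(r))) {
      t1 <- ty[r$id1[i]]; t2 <- ty[r$id2[i]]
      if (is.na(t1) || is.na(t2)) next
      keys <- c(keys, type_pair_key(t1, t2))
    }
  }
  sort(unique(keys), method = "radix")
}

type_pair_key <- function(t1, t2) {
  paste(sort(c(t1, t2), method = "radix"), collapse = "|")
}

# identifier -> entity type map for a document (first mention's type wins).
entity_types_of <- function(doc) {
  groups <- group_mentions_by_entity(doc)
  vapply(groups, function(g) g$type[1], character(1))
}

#' Generate candidate entity pairs for a document
#'
#' One candidate per unordered pair of distinct linked entity identifiers
#' whose type combination is allowed; the gold relation type is attached when
#' one exists, else `NoRelation`.
#'
#' @param doc an `rm_document` with linked mentions.
#' @param allowed character vector from [allowed_type_pairs()]; `NULL` allows
#'   all combinations.
#' @return `data.frame` with columns `id1`, `id2` (sorted), `label`.
#' @export
generate_candidate_pairs <- function(doc, allowed = NULL) {
  ty <- entity_types_of(doc)
  ids <- sort(names(ty), method = "radix")
  out <- list()
  r <- doc$relations
  rkey <- paste(r$id1, r$id2)
  if (length(ids) >= 2) {
    for (i in seq_len(length(ids) - 1L)) {
      for (j in (i + 1L):length(ids)) {
        key <- type_pair_key(ty[ids[i]], ty[ids[j]])
        if (!is.null(allowed) && !(key %in% allowed)) next
        hit <- match(paste(ids[i], ids[j]), rkey)
        out[[length(out) + 1L]] <- data.frame(
          id1 = ids[i], id2 = ids[j],
          label = if (!is.na(hit)) r$type[hit] else "NoRelation",
          stringsAsFactors = FALSE)
      }
    }
  }
  do.call(rbind, out) %||%
    data.frame(id1 = character(0), id2 = character(0), label = character(0))
}

RE_OPEN <- "[E]"
RE_CLOSE <- "[/E]"

#' Insert entity markers around a candidate pair's mentions
#'
#' Every mention of both entities is enclosed in the single untyped marker
#' pair `[E]` ... `[/E]` (entity-type information in markers was found
#' unhelpful, and subject/object designations are dropped since relations are
#' undirected). Each mention keeps its own marker pair; nested mentions yield
#' nested markers. Stripping all markers recovers the original sequence.
#'
#' @param tokens token table of the document (from [tokenize_text()]).
#' @param doc the `rm_document` (for mention lookup).
#' @param id1,id2 the two entity identifiers (sorted order is the caller's
#'   contract).
#' @return list with `tokens` (character vector including markers),
#'   `open1`, `open2` (positions of the open markers of each entity's
#'   mentions), and `orig` (for each output token its source row in `tokens`,
#'   `NA` for markers).
#' @export
insert_entity_markers <- function(tokens, doc, id1, id2) {
  groups <- group_mentions_by_entity(doc)
  span_rows <- function(id) {
    g <- groups[[id]]
    if (is.null(g)) stop("entity ", id, " has no tagged mentions")
    lapply(seq_len(nrow(g)), function(i) {
      idx <- tokens_in_span(tokens, g$start[i], g$end[i])
      if (!length(idx)) NULL else c(min(idx), max(idx))
    })
  }
  sp1 <- Filter(Negate(is.null), span_rows(id1))
  sp2 <- Filter(Negate(is.null), span_rows(id2))
  if (!length(sp1)) stop("entity ", id1, " has no tagged mentions")
  if (!length(sp2)) stop("entity ", id2, " has no tagged mentions")
  ents <- c(rep(1L, length(sp1)), rep(2L, length(sp2)))
  spans <- c(sp1, sp2)
  n <- nrow(tokens)
  # opens[t]: marker openings before token t (outermost = longest span first)
  opens <- lapply(seq_len(n), function(t) integer(0))
  closes <- lapply(seq_len(n), function(t) integer(0))
  for (k in seq_along(spans)) {
    opens[[spans[[k]][1]]] <- c(opens[[spans[[k]][1]]], k)
    closes[[spans[[k]][2]]] <- c(closes[[spans[[k]][2]]], k)
  }
  out <- character(0); orig <- integer(0)
  open_pos <- integer(length(spans))
  for (t in seq_len(n)) {
    ks <- opens[[t]]
    ks <- ks[order(-vapply(ks, function(k) spans[[k]][2], numeric(1)))]
    for (k in ks) {
      out <- c(out, RE_OPEN); orig <- c(orig, NA_integer_)
      open_pos[k] <- length(out)
    }
    out <- c(out, tokens$token[t]); orig <- c(orig, t)
    ks <- closes[[t]]
    ks <- ks[order(vapply(ks, function(k) spans[[k]][1], numeric(1)))]
    for (k in rev(ks)) {
      out <- c(out, RE_CLOSE); orig <- c(orig, NA_integer_)
    }
  }
  list(tokens = out, open1 = open_pos[ents == 1L], open2 = open_pos[ents == 2L],
       orig = orig)
}

#' Select the mention pair with maximal dot product
#'
#' With multiple mentions per entity, the mention pair whose marker
#' embeddings have the highest dot product is taken as the relation
#' representation (max pooling over mention pairs); the dot product acts as
#' the importance of the pair for classifying the relation.
#'
#' @param M1,M2 matrices of marker embeddings (`k x dim`), one row per
#'   mention of each entity.
#' @return list with indices `i`, `j` and vectors `e1`, `e2`.
#' @export
select_mention_pair <- function(M1, M2) {
  stopifnot(nrow(M1) >= 1, nrow(M2) >= 1)
  S <- M1 %*% t(M2)
  best <- arrayInd(which.max(S), dim(S))
  list(i = best[1], j = best[2],
       e1 = M1[best[1], ], e2 = M2[best[2], ])
}

#' Directional pair representations
#'
#' The forward representation is `[e1; e2; e1*e2]` and the reverse
#' `[e2; e1; e2*e1]` (elementwise product); the reverse is the forward with
#' its first two blocks swapped and an identical product block.
#'
#' @param e1,e2 mention marker embeddings.
#' @return list with `v_fwd`, `v_rev` (each of length `3 * dim`).
#' @export
directional_representations <- function(e1, e2) {
  list(v_fwd = c(e1, e2, e1 * e2), v_rev = c(e2, e1, e2 * e1))
}

#' Logits of both directional representations
#'
#' @param v_fwd,v_rev directional representations.
#' @param classifier list with `W` (`3*dim x 9`) and `b` (length 9).
#' @return list with `fwd` and `rev` logit vectors over the 9 labels.
#' @export
pair_logits <- function(v_fwd, v_rev, classifier) {
  list(fwd = as.vector(v_fwd %*% classifier$W) + classifier$b,
       rev = as.vector(v_rev %*% classifier$W) + classifier$b)
}

#' Bidirectional relation loss
#'
#' Sum of the cross-entropy losses of the two directional representations.
#'
#' @param logits_fwd,logits_rev logit vectors.
#' @param gold gold label (string in [re_label_set()] or integer index).
#' @return scalar loss.
#' @export
re_loss <- function(logits_fwd, logits_rev, gold) {
  y <- if (is.character(gold)) match(gold, re_label_set()) else gold
  ce_loss(logits_fwd, y) + ce_loss(logits_rev, y)
}

#' Predict a relation label from bidirectional logits
#'
#' The two directional logit vectors are summed and the argmax taken, making
#' the prediction invariant under exchanging the entity roles. Ties resolve
#' to the lowest label index (`NoRelation` is last).
#'
#' @param logits_fwd,logits_rev logit vectors.
#' @return the predicted label string.
#' @export
predict_relation <- function(logits_fwd, logits_rev) {
  s <- logits_fwd + logits_rev
  re_label_set()[which.max(s)]
}

#' Adversarial-training configuration
#'
#' Projected gradient descent on the input token embeddings: `n_steps`
#' ascent steps (3, per the training recipe) of size `step_size` along the
#' normalized loss gradient, with the accumulated perturbation projected onto
#' an L2 ball of radius `radius`.
#'
#' @param n_steps,step_size,radius,norm PGD parameters.
#' @return a list of class `adversarial_config`.
#' @export
adversarial_config <- function(n_steps = 3, step_size = 0.3, radius = 1.0,
                               norm = "l2") {
  structure(list(n_steps = n_steps, step_size = step_size, radius = radius,
                 norm = norm), class = "adversarial_config")
}

#' One projected-gradient-descent step on input embeddings
#'
#' Ascends along the (Frobenius-normalized) loss gradient and projects the
#' accumulated perturbation back onto the radius ball; a zero gradient leaves
#' the perturbation unchanged.
#'
#' @param X original input embedding matrix.
#' @param grad gradient of the loss w.r.t. the perturbed embeddings.
#' @param cfg an [adversarial_config()].
#' @param delta accumulated perturbation so far (matrix like `X`, or `NULL`).
#' @return list with `X_pert` (perturbed embeddings) and `delta`.
#' @export
pgd_step <- function(X, grad, cfg = adversarial_config(), delta = NULL) {
  if (is.null(delta)) delta <- X * 0
  gn <- sqrt(sum(grad * grad))
  if (gn > 0) delta <- delta + cfg$step_size * grad / gn
  dn <- sqrt(sum(delta * delta))
  if (dn > cfg$radius) delta <- delta * (cfg$radius / dn)
  list(X_pert = X + delta, delta = delta)
}

#' Configuration for the relation-extraction model
#'
#' Defaults are the tuned recipe: 5 epochs, learning rate 3e-5, batch size
#' 32, Adam.
#'
#' @param epochs,learning_rate,batch_size,optimizer training hyperparameters.
#' @return a list of class `re_config`.
#' @export
re_config <- function(epochs = 5, learning_rate = 3e-5, batch_size = 32,
                      optimizer = "adam", pair_temperature = 1.0) {
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, optimizer = optimizer,
                 pair_temperature = pair_temperature),
            class = "re_config")
}

# Build per-pair training/prediction instances for one document.
re_doc_instances <- function(doc, allowed, encoder) {
  tokens <- tokenize_text(doc_text(doc))
  cands <- generate_candidate_pairs(doc, allowed)
  lapply(seq_len(nrow(cands)), function(i) {
    mk <- insert_entity_markers(tokens, doc, cands$id1[i], cands$id2[i])
    toks <- mk$tokens
    open1 <- mk$open1; open2 <- mk$open2
    if (length(toks) > encoder$max_len) {
      warning(sprintf("marked sequence of %d tokens truncated to %d",
                      length(toks), encoder$max_len))
      keep1 <- open1[open1 <= encoder$max_len]
      keep2 <- open2[open2 <= encoder$max_len]
      if (!length(keep1) || !length(keep2)) return(NULL)
      toks <- toks[seq_len(encoder$max_len)]
      open1 <- keep1; open2 <- keep2
    }
    list(doc_id = doc$doc_id, id1 = cands$id1[i], id2 = cands$id2[i],
         ids = encoder_token_ids(encoder, toks),
         open1 = open1, open2 = open2,
         y = match(cands$label[i], re_label_set()))
  })
}

# Forward + backward for one RE instance given an input embedding matrix X.
# Training uses a softmax over mention-pair dot products (temperature tau) as
# a smooth relaxation of the max-dot pair selection, so the pair ranking
# itself receives gradient; prediction takes the hard argmax pair.
# Returns loss, weight grads (encoder layers + classifier), and dX.
re_instance_grad <- function(encoder, params, inst, X, tau = 1.0) {
  d <- encoder$dim
  encoder$params <- params[names(encoder$params)]
  fwd <- encoder_forward(encoder, X)
  M1 <- fwd$H[inst$open1, , drop = FALSE]
  M2 <- fwd$H[inst$open2, , drop = FALSE]
  S <- M1 %*% t(M2)
  A <- S / tau
  A <- A - max(A)
  w <- exp(A); w <- w / sum(w)
  wk <- rowSums(w); wl <- colSums(w)
  P3 <- w %*% M2            # row k: sum_l w_kl m2_l
  Q3 <- t(w) %*% M1         # row l: sum_k w_kl m1_k
  block1 <- as.vector(t(M1) %*% wk)
  block2 <- as.vector(t(M2) %*% wl)
  block3 <- colSums(M1 * P3)
  v_fwd <- c(block1, block2, block3)
  v_rev <- c(block2, block1, block3)
  cls <- list(W = params$Wre, b = params$bre)
  lg <- pair_logits(v_fwd, v_rev, cls)
  loss <- re_loss(lg$fwd, lg$rev, inst$y)
  pf <- softmax_vec(lg$fwd); pr <- softmax_vec(lg$rev)
  dlf <- pf; dlf[inst$y] <- dlf[inst$y] - 1
  dlr <- pr; dlr[inst$y] <- dlr[inst$y] - 1
  dW <- outer(v_fwd, dlf) + outer(v_rev, dlr)
  db <- dlf + dlr
  dvf <- as.vector(params$Wre %*% dlf)
  dvr <- as.vector(params$Wre %*% dlr)
  b1 <- 1:d; b2 <- (d + 1):(2 * d); b3 <- (2 * d + 1):(3 * d)
  u1 <- dvf[b1] + dvr[b2]
  u2 <- dvf[b2] + dvr[b1]
  u3 <- dvf[b3] + dvr[b3]
  dM1 <- outer(wk, u1) + sweep(P3, 2, u3, `*`)
  dM2 <- outer(wl, u2) + sweep(Q3, 2, u3, `*`)
  Dw <- outer(as.vector(M1 %*% u1), rep(1, nrow(M2))) +
    outer(rep(1, nrow(M1)), as.vector(M2 %*% u2)) +
    sweep(M1, 2, u3, `*`) %*% t(M2)
  dS <- w * (Dw - sum(w * Dw)) / tau
  dM1 <- dM1 + dS %*% M2
  dM2 <- dM2 + t(dS) %*% M1
  dH <- matrix(0, nrow(fwd$H), d)
  for (r_ in seq_along(inst$open1)) {
    dH[inst$open1[r_], ] <- dH[inst$open1[r_], ] + dM1[r_, ]
  }
  for (r_ in seq_along(inst$open2)) {
    dH[inst$open2[r_], ] <- dH[inst$open2[r_], ] + dM2[r_, ]
  }
  bk <- encoder_backward(encoder, fwd$cache, dH)
  grads <- bk$grads
  grads$Wre <- dW
  grads$bre <- db
  list(loss = loss, grads = grads, dX = bk$dX)
}

#' Fit the document-level relation-extraction model
#'
#' Trains the encoder and a 9-way classifier over the bidirectional pair
#' representations end-to-end with the summed directional cross-entropy
#' loss. After each batch's clean update, the input token embeddings are
#' perturbed `adv$n_steps` times by projected gradient ascent and the model
#' is additionally updated to classify the perturbed inputs correctly.
#'
#' @param instances list of instances from [re_doc_instances()] (or the
#'   convenience path via [fit_re_corpus()]).
#' @param encoder a `tiny_encoder`; the `[E]` / `[/E]` marker tokens are
#'   registered in its vocabulary.
#' @param cfg an [re_config()].
#' @param adv an [adversarial_config()], or `NULL` to disable PGD.
#' @param seed integer seed.
#' @return an object of class `re_model`.
#' @export
fit_re <- function(instances, encoder, cfg = re_config(),
                   adv = adversarial_config(), seed = 1) {
  instances <- Filter(Negate(is.null), instances)
  if (!length(instances)) stop("no training instances")
  d <- encoder$dim
  K <- length(re_label_set())
  params <- with_seed(seed + 1L, c(encoder$params,
                                   list(Wre = ginit(3 * d, K), bre = numeric(K))))
  opt <- adam_init(params)
  loss_history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(instances))
      ep_loss <- 0
      for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        grads <- lapply(params, function(p) p * 0)
        for (ii in batch) {
          inst <- instances[[ii]]
          X <- params$E[inst$ids, , drop = FALSE]
          g <- re_instance_grad(encoder, params, inst, X, cfg$pair_temperature)
          ep_loss <- ep_loss + g$loss
          for (nm in setdiff(names(g$grads), "E")) {
            grads[[nm]] <- grads[[nm]] + g$grads[[nm]] / length(batch)
          }
          grads$E <- accumulate_embedding_grad(grads$E, inst$ids,
                                               g$dX / length(batch))
        }
        st <- adam_step(opt, params, grads, cfg$learning_rate)
        opt <- st$opt; params <- st$params
        if (!is.null(adv) && adv$n_steps > 0) {
          grads <- lapply(params, function(p) p * 0)
          for (ii in batch) {
            inst <- instances[[ii]]
            X0 <- params$E[inst$ids, , drop = FALSE]
            delta <- NULL
            Xp <- X0
            for (k in seq_len(adv$n_steps)) {
              g <- re_instance_grad(encoder, params, inst, Xp, cfg$pair_temperature)
              stp <- pgd_step(X0, g$dX, adv, delta)
              delta <- stp$delta
              Xp <- stp$X_pert
            }
            g <- re_instance_grad(encoder, params, inst, Xp, cfg$pair_temperature)
            for (nm in setdiff(names(g$grads), "E")) {
              grads[[nm]] <- grads[[nm]] + g$grads[[nm]] / length(batch)
            }
            # perturbation is on the looked-up embeddings; their gradient
            # still flows to the embedding table rows
            grads$E <- accumulate_embedding_grad(grads$E, inst$ids,
                                                 g$dX / length(batch))
          }
          st <- adam_step(opt, params, grads, cfg$learning_rate)
          opt <- st$opt; params <- st$params
        }
      }
      loss_history <- c(loss_history, ep_loss / length(instances))
    }
  })
  encoder$params <- params[names(encoder$params)]
  structure(list(encoder = encoder, W = params$Wre, b = params$bre,
                 cfg = cfg, adv = adv, seed = seed,
                 loss_history = loss_history),
            class = "re_model")
}

#' Convenience: fit the RE model from a gold-annotated corpus
#'
#' Computes the allowed type-pair set from the corpus, builds per-document
#' candidate-pair instances, and calls [fit_re()].
#'
#' @param corpus_ an `rm_corpus` with linked mentions and gold relations.
#' @inheritParams fit_re
#' @return an `re_model` with the allowed type pairs stored as `allowed`.
#' @export
fit_re_corpus <- function(corpus_, encoder, cfg = re_config(),
                          adv = adversarial_config(), seed = 1) {
  encoder <- encoder_add_tokens(encoder, c(RE_OPEN, RE_CLOSE))
  allowed <- allowed_type_pairs(corpus_)
  instances <- unlist(lapply(corpus_, re_doc_instances, allowed = allowed,
                             encoder = encoder), recursive = FALSE)
  model <- fit_re(instances, encoder, cfg, adv, seed)
  model$allowed <- allowed
  model
}

#' Predict document-level relations
#'
#' Generates candidate pairs under the model's allowed type-pair set, scores
#' each with summed bidirectional logits, and emits one relation per pair not
#' labeled `NoRelation` (identifiers sorted).
#'
#' @param model a fitted `re_model`.
#' @param doc an `rm_document` with linked mentions.
#' @param allowed override of the allowed type pairs (default: the model's).
#' @return a [relation_table()].
#' @export
predict_doc_relations <- function(model, doc, allowed = model$allowed) {
  insts <- re_doc_instances(doc, allowed, model$encoder)
  insts <- Filter(Negate(is.null), insts)
  out <- list()
  for (inst in insts) {
    H <- encoder_forward(model$encoder,
                         model$encoder$params$E[inst$ids, , drop = FALSE])$H
    sel <- select_mention_pair(H[inst$open1, , drop = FALSE],
                               H[inst$open2, , drop = FALSE])
    dr <- directional_representations(sel$e1, sel$e2)
    lg <- pair_logits(dr$v_fwd, dr$v_rev, list(W = model$W, b = model$b))
    lab <- predict_relation(lg$fwd, lg$rev)
    if (lab != "NoRelation") {
      out[[length(out) + 1L]] <- relation_table(lab, inst$id1, inst$id2)
    }
  }
  res <- do.call(rbind, out) %||% relation_table()
  rownames(res) <- NULL
  res
}
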