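#' Logsumexp pooling of mention embeddings
#'
#' Coordinate-wise `log(sum(exp(x)))` over the rows, computed with a
#' max-shift for numerical stability. A smooth version of max pooling: every
#' mention contributes, weighted by how strongly it activates each
#' coordinate, and the result lies in `[max, max + log n]` coordinate-wise.
#'
#' @param M matrix of mention marker embeddings (`k x dim`, `k >= 1`), or a
#'   single vector.
#' @return numeric vector of length `dim`.
#' @export
logsumexp_pool <- function(M) {
  if (is.vector(M)) M <- matrix(M, nrow = 1)
  if (!nrow(M)) stop("logsumexp_pool over an empty mention set")
  mx <- apply(M, 2, max)
  mx + log(colSums(exp(sweep(M, 2, mx))))
}

#' Novelty relation representation
#'
#' Pools all mention marker embeddings of each entity with
#' [logsumexp_pool()] and concatenates the two entity vectors. The entity
#' order is canonicalized upstream (sorted identifiers) so the
#' representation is well-defined for undirected pairs.
#'
#' @param M1,M2 marker embedding matrices of the two entities.
#' @return numeric vector of length `2 * dim`.
#' @export
nd_representation <- function(M1, M2) {
  c(logsumexp_pool(M1), logsumexp_pool(M2))
}

#' Configuration for the novelty-detection model
#'
#' Defaults are the tuned recipe: 4 epochs, learning rate 2e-5, batch size
#' 32, Adam.
#'
#' @param epochs,learning_rate,batch_size,optimizer training hyperparameters.
#' @return a list of class `nd_config`.
#' @export
nd_config <- function(epochs = 4, learning_rate = 2e-5, batch_size = 32,
                      optimizer = "adam") {
  structure(list(epochs = epochs, learning_rate = learning_rate,
                 batch_size = batch_size, optimizer = optimizer),
            class = "nd_config")
}

# Instances: one per gold relation (no negatives -- input pairs already have
# an identified relation).
nd_doc_instances <- function(doc, encoder) {
  tokens <- tokenize_text(doc_text(doc))
  r <- doc$relations
  out <- list()
  for (i in seq_len(nrow(r))) {
    mk <- insert_entity_markers(tokens, doc, r$id1[i], r$id2[i])
    toks <- mk$tokens
    if (length(toks) > encoder$max_len) {
      keep1 <- mk$open1[mk$open1 <= encoder$max_len]
      keep2 <- mk$open2[mk$open2 <= encoder$max_len]
      if (!length(keep1) || !length(keep2)) next
      toks <- toks[seq_len(encoder$max_len)]
      mk$open1 <- keep1; mk$open2 <- keep2
    }
    out[[length(out) + 1L]] <- list(
      doc_id = doc$doc_id, id1 = r$id1[i], id2 = r$id2[i],
      ids = encoder_token_ids(encoder, toks),
      open1 = mk$open1, open2 = mk$open2,
      y = if (!is.na(r$novelty[i])) match(r$novelty[i], NOVELTY_LABELS)
          else NA_integer_)
  }
  out
}

nd_instance_forward <- function(encoder, params, inst, X = NULL) {
  encoder$params <- params[names(encoder$params)]
  if (is.null(X)) X <- params$E[inst$ids, , drop = FALSE]
  fwd <- encoder_forward(encoder, X)
  M1 <- fwd$H[inst$open1, , drop = FALSE]
  M2 <- fwd$H[inst$open2, , drop = FALSE]
  rep_ <- nd_representation(M1, M2)
  logits <- as.vector(rep_ %*% params$Wnd) + params$bnd
  list(fwd = fwd, M1 = M1, M2 = M2, rep = rep_, logits = logits)
}

#' Fit the novelty-detection model
#'
#' Binary classifier (Novel vs No) over [nd_representation()]s, trained only
#' on pairs that carry a gold relation -- no negative (unrelated) examples
#' are used, since in the pipeline the input pairs already have an identified
#' relation. The novelty model fine-tunes its own encoder, separate from the
#' relation-extraction encoder.
#'
#' @param corpus_ an `rm_corpus` whose relations carry novelty labels.
#' @param encoder a `tiny_encoder`.
#' @param cfg an [nd_config()].
#' @param seed integer seed.
#' @return an object of class `nd_model`.
#' @export
fit_nd <- function(corpus_, encoder, cfg = nd_config(), seed = 1) {
  encoder <- encoder_add_tokens(encoder, c(RE_OPEN, RE_CLOSE))
  instances <- unlist(lapply(corpus_, nd_doc_instances, encoder = encoder),
                      recursive = FALSE)
  instances <- Filter(function(x) !is.na(x$y), instances)
  if (!length(instances)) stop("no labeled relation instances for training")
  d <- encoder$dim
  params <- with_seed(seed + 1L, c(encoder$params,
                                   list(Wnd = ginit(2 * d, 2), bnd = numeric(2))))
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
          fw <- nd_instance_forward(encoder, params, inst)
          P <- softmax_vec(fw$logits)
          ep_loss <- ep_loss + ce_loss(fw$logits, inst$y)
          dlog <- P; dlog[inst$y] <- dlog[inst$y] - 1
          dlog <- dlog / length(batch)
          grads$Wnd <- grads$Wnd + outer(fw$rep, dlog)
          grads$bnd <- grads$bnd + dlog
          drep <- as.vector(params$Wnd %*% dlog)
          dv1 <- drep[1:d]; dv2 <- drep[(d + 1):(2 * d)]
          # logsumexp backward: column-wise softmax weights over mentions
          lse_back <- function(M, pooled, dv) {
            Wgt <- exp(sweep(M, 2, pooled))
            sweep(Wgt, 2, dv, `*`)
          }
          dH <- matrix(0, length(inst$ids), d)
          dM1 <- lse_back(fw$M1, fw$rep[1:d], dv1)
          dM2 <- lse_back(fw$M2, fw$rep[(d + 1):(2 * d)], dv2)
          for (r_ in seq_along(inst$open1)) {
            dH[inst$open1[r_], ] <- dH[inst$open1[r_], ] + dM1[r_, ]
          }
          for (r_ in seq_along(inst$open2)) {
            dH[inst$open2[r_], ] <- dH[inst$open2[r_], ] + dM2[r_, ]
          }
          encoder$params <- params[names(encoder$params)]
          bk <- encoder_backward(encoder, fw$fwd$cache, dH)
          for (nm in names(bk$grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
          grads$E <- accumulate_embedding_grad(grads$E, inst$ids, bk$dX)
        }
        st <- adam_step(opt, params, grads, cfg$learning_rate)
        opt <- st$opt; params <- st$params
      }
      loss_history <- c(loss_history, ep_loss / length(instances))
    }
  })
  encoder$params <- params[names(encoder$params)]
  structure(list(encoder = encoder, W = params$Wnd, b = params$bnd,
                 cfg = cfg, seed = seed, loss_history = loss_history),
            class = "nd_model")
}

#' Predict novelty labels for a document's relations
#'
#' Applied in the pipeline to relations extracted upstream; a relation whose
#' entities have no tagged mentions in the document is an error.
#'
#' @param model a fitted `nd_model`.
#' @param doc an `rm_document` with linked mentions.
#' @param relations a [relation_table()] (default: the document's).
#' @return the relation table with its `novelty` column filled.
#' @export
predict_novelty <- function(model, doc, relations = doc$relations) {
  if (!nrow(relations)) return(relations)
  tmp <- doc
  tmp$relations <- relations
  insts <- nd_doc_instances(tmp, model$encoder)
  if (length(insts) != nrow(relations)) {
    stop("some relations reference entities without tagged mentions")
  }
  params <- c(model$encoder$params, list(Wnd = model$W, bnd = model$b))
  for (i in seq_along(insts)) {
    fw <- nd_instance_forward(model$encoder, params, insts[[i]])
    relations$novelty[i] <- NOVELTY_LABELS[which.max(fw$logits)]
  }
  relations
}
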