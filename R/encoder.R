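#' A tiny contextual token encoder
#'
#' A deliberately small, fully deterministic stand-in for a pretrained
#' contextual language model, satisfying the encoder contract the task models
#' require: a fixed vocabulary with special tokens, per-token final-layer
#' vectors, a 512-token maximum length, and gradients that propagate back to
#' the input token embeddings (needed both for fine-tuning and for adversarial
#' perturbation of the embeddings).
#'
#' Architecture: an embedding table followed by `n_layers` width-3
#' convolutional mixing layers with tanh nonlinearity, so each extra layer
#' widens the receptive field by one token on each side.
#'
#' @param tokens character vector of vocabulary tokens; `"[UNK]"` is added
#'   automatically and absorbs out-of-vocabulary tokens.
#' @param dim embedding width (default 32).
#' @param n_layers number of convolutional mixing layers (default 2).
#' @param seed integer seed for weight initialization.
#' @return an object of class `tiny_encoder`.
#' @export
make_tiny_encoder <- function(tokens, dim = 32, n_layers = 2, seed = 1) {
  vocab <- unique(c("[UNK]", tokens))
  with_seed(seed, {
    params <- list(E = ginit(length(vocab), dim, fan_in = dim))
    for (l in seq_len(n_layers)) {
      params[[paste0("W", l)]] <- ginit(3 * dim, dim)
      params[[paste0("b", l)]] <- numeric(dim)
    }
    structure(list(vocab = stats::setNames(seq_along(vocab), vocab),
                   dim = dim, n_layers = n_layers, max_len = 512L,
                   seed = seed, params = params),
              class = "tiny_encoder")
  })
}

#' @export
print.tiny_encoder <- function(x, ...) {
  cat(sprintf("<tiny_encoder: |V|=%d, dim=%d, %d layers>\n",
              length(x$vocab), x$dim, x$n_layers))
  invisible(x)
}

#' Register additional special tokens in an encoder vocabulary
#'
#' New rows of the embedding table are initialized deterministically from the
#' encoder's stored seed and the token's position, so repeated construction
#' yields identical weights.
#'
#' @param enc a `tiny_encoder`.
#' @param tokens character vector of tokens to add (existing ones are ignored).
#' @return the updated encoder.
#' @export
encoder_add_tokens <- function(enc, tokens) {
  new <- setdiff(tokens, names(enc$vocab))
  for (tok in new) {
    pos <- length(enc$vocab) + 1L
    row <- with_seed(enc$seed + 7919L * pos,
                     matrix(stats::rnorm(enc$dim, sd = 1 / sqrt(enc$dim)), 1))
    enc$params$E <- rbind(enc$params$E, row)
    enc$vocab[[tok]] <- pos
  }
  enc
}

#' Map tokens to vocabulary ids (OOV to [UNK])
#' @param enc a `tiny_encoder`.
#' @param tokens character vector.
#' @return integer vector of vocabulary indices.
#' @export
encoder_token_ids <- function(enc, tokens) {
  idx <- enc$vocab[tokens]
  idx[is.na(idx)] <- enc$vocab[["[UNK]"]]
  unname(idx)
}

# Input embeddings for a sequence of vocabulary ids.
encoder_embed <- function(enc, ids) {
  enc$params$E[ids, , drop = FALSE]
}

# Shift helpers for the width-3 context window (zero-padded).
shift_up <- function(X) rbind(X[-1, , drop = FALSE], 0)    # token t+1 at row t
shift_down <- function(X) rbind(0, X[-nrow(X), , drop = FALSE]) # token t-1

#' Encoder forward pass
#'
#' @param enc a `tiny_encoder`.
#' @param X input embedding matrix (`n x dim`), usually `E[ids, ]` but any
#'   matrix (e.g. adversarially perturbed embeddings) is accepted.
#' @return list with `H` (`n x dim` final-layer vectors) and a `cache` for
#'   [encoder_backward()].
#' @export
encoder_forward <- function(enc, X) {
  cache <- list(X0 = X)
  for (l in seq_len(enc$n_layers)) {
    C <- cbind(shift_down(X), X, shift_up(X))
    H <- tanh(C %*% enc$params[[paste0("W", l)]] +
                rep(enc$params[[paste0("b", l)]], each = nrow(X)))
    cache[[paste0("C", l)]] <- C
    cache[[paste0("H", l)]] <- H
    X <- H
  }
  list(H = X, cache = cache)
}

#' Encoder backward pass
#'
#' Backpropagates a gradient on the final-layer vectors through all mixing
#' layers, returning weight gradients and the gradient with respect to the
#' input embedding matrix.
#'
#' @param enc a `tiny_encoder`.
#' @param cache cache from [encoder_forward()].
#' @param dH gradient on `H` (`n x dim`).
#' @return list with `dX` (gradient on input embeddings) and `grads` (named
#'   list matching `enc$params`, without `E`; embedding-table gradients are
#'   accumulated by the caller via the token ids).
#' @export
encoder_backward <- function(enc, cache, dH) {
  grads <- list()
  for (l in rev(seq_len(enc$n_layers))) {
    H <- cache[[paste0("H", l)]]
    C <- cache[[paste0("C", l)]]
    dA <- dH * (1 - H * H)
    grads[[paste0("W", l)]] <- crossprod(C, dA)
    grads[[paste0("b", l)]] <- colSums(dA)
    dC <- dA %*% t(enc$params[[paste0("W", l)]])
    d <- enc$dim
    dXm1 <- dC[, 1:d, drop = FALSE]
    dXmid <- dC[, (d + 1):(2 * d), drop = FALSE]
    dXp1 <- dC[, (2 * d + 1):(3 * d), drop = FALSE]
    # X[t] fed row t+1 of the t-1 block and row t-1 of the t+1 block
    dH <- dXmid + shift_up(dXm1) + shift_down(dXp1)
  }
  list(dX = dH, grads = grads)
}

# Accumulate an input-embedding gradient into an E-shaped gradient matrix.
accumulate_embedding_grad <- function(dE, ids, dX) {
  agg <- rowsum(dX, group = ids)
  rows <- as.integer(rownames(agg))
  dE[rows, ] <- dE[rows, , drop = FALSE] + agg
  dE
}
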