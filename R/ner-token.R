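#' Task-oriented tags for multi-corpus NER training
#'
#' When several NER corpora with different annotated type inventories are
#' merged into one training set, each instance is wrapped in special task
#' tokens (e.g. `<ALL>` ... `</ALL>`, `<GENE>` ... `</GENE>`) and outside
#' labels carry the task scope (`O-ALL`, `O-GENE`, ...), telling the model
#' which entity types the instance actually annotates. The `ALL` tag is
#' reserved for a corpus annotated with all six entity types.
#'
#' @param name scope label, e.g. `"ALL"`, `"GENE"`, `"CHEMICAL-DISEASE"`.
#' @param covered_types subset of the six entity types annotated under this
#'   tag. `"ALL"` must (and by default does) cover all six.
#' @return an object of class `task_tag`.
#' @export
task_tag <- function(name, covered_types = if (name == "ALL") ENTITY_TYPES) {
  covered_types <- match.arg(covered_types, ENTITY_TYPES, several.ok = TRUE)
  if ((name == "ALL") != setequal(covered_types, ENTITY_TYPES)) {
    stop("tag 'ALL' must cover exactly the six entity types, and vice versa")
  }
  structure(list(name = name, covered_types = covered_types), class = "task_tag")
}

tag_open <- function(tag) paste0("<", tag$name, ">")
tag_close <- function(tag) paste0("</", tag$name, ">")

#' Encode mentions as BIO token labels
#'
#' Each token receives one label: the first token of a mention of a covered
#' type gets `B-<type>`, subsequent tokens `I-<type>`, and every other token
#' the scoped outside label `O-<tag name>`. Mentions of types outside the
#' tag's coverage are ignored (left as outside), reflecting that such
#' entities are simply unannotated in a single-type corpus. A mention
#' boundary that splits a token is aligned to the overlapping tokens with a
#' warning.
#'
#' @param tokens token table from [tokenize_text()].
#' @param mentions a [mention_table()].
#' @param tag a [task_tag()].
#' @return character vector of labels, one per token.
#' @export
encode_bio <- function(tokens, mentions, tag) {
  labels <- rep(paste0("O-", tag$name), nrow(tokens))
  if (!nrow(mentions)) return(labels)
  mentions <- mentions[mentions$type %in% tag$covered_types, , drop = FALSE]
  for (i in seq_len(nrow(mentions))) {
    idx <- tokens_in_span(tokens, mentions$start[i], mentions$end[i])
    if (!length(idx)) next
    if (tokens$start[idx[1]] < mentions$start[i] ||
        tokens$end[idx[length(idx)]] > mentions$end[i]) {
      warning(sprintf("mention boundary splits a token at [%d,%d); aligning to tokens",
                      mentions$start[i], mentions$end[i]))
    }
    labels[idx[1]] <- paste0("B-", mentions$type[i])
    if (length(idx) > 1) labels[idx[-1]] <- paste0("I-", mentions$type[i])
  }
  labels
}

#' Decode BIO token labels into mentions
#'
#' Inverse of [encode_bio()] on well-formed sequences, with deterministic
#' repair of ill-formed ones: an orphan `I-` run (no preceding `B-`) is
#' treated as a mention, and a type change inside a run splits the run.
#' Emitted mentions never overlap.
#'
#' @param tokens token table with character spans.
#' @param labels character vector of BIO labels, one per token.
#' @param text the document text the spans index, used to slice surfaces.
#' @return a [mention_table()] (identifiers empty; linking happens later).
#' @export
decode_bio <- function(tokens, labels, text) {
  stopifnot(nrow(tokens) == length(labels))
  role <- substr(labels, 1, 1)
  etype <- ifelse(role %in% c("B", "I"), substring(labels, 3), NA_character_)
  starts <- integer(0); ends <- integer(0); types <- character(0)
  cur <- NULL
  close_run <- function() {
    if (is.null(cur)) return()
    starts <<- c(starts, tokens$start[cur$first])
    ends <<- c(ends, tokens$end[cur$last])
    types <<- c(types, cur$type)
    cur <<- NULL
  }
  for (t in seq_along(labels)) {
    if (role[t] == "B") {
      close_run()
      cur <- list(first = t, last = t, type = etype[t])
    } else if (role[t] == "I") {
      if (!is.null(cur) && cur$type == etype[t]) {
        cur$last <- t
      } else {
        close_run()  # orphan I or type break: start a fresh mention
        cur <- list(first = t, last = t, type = etype[t])
      }
    } else {
      close_run()
    }
  }
  close_run()
  if (!length(starts)) return(mention_table())
  mention_table(starts, ends,
                surface = substring(text, starts + 1L, ends),
                type = types)
}

#' Wrap a token sequence in task tokens
#'
#' @param tokens character vector of tokens.
#' @param tag a [task_tag()].
#' @return character vector `<TAG> tokens </TAG>`.
#' @export
wrap_task_tokens <- function(tokens, tag) {
  c(tag_open(tag), tokens, tag_close(tag))
}

#' Strip task-token wrappers from a sequence
#' @param x a vector wrapped by [wrap_task_tokens()] (tokens, labels, or
#'   predictions of the same length).
#' @return the vector without its first and last element.
#' @export
strip_task_tokens <- function(x) {
  if (length(x) < 2) stop("sequence too short to be wrapped")
  x[-c(1L, length(x))]
}

#' Merge annotated corpora into one tagged training set
#'
#' Each corpus is paired with the task tag describing which entity types it
#' annotates. Instances from the all-types corpus are whole abstracts;
#' single-type auxiliary corpora are split into sentences (configurable per
#' dataset). The unified label space contains every `B-`/`I-` type plus one
#' `O-<scope>` label per distinct tag name.
#'
#' @param datasets list of `list(corpus =, tag =, granularity =)` entries;
#'   `granularity` is `"document"` (default for tag `ALL`) or `"sentence"`.
#' @return list with `instances` (each carrying `tokens`, `labels`, `tag`,
#'   `doc_id`, `text`) and `labels`, the unified label set.
#' @export
merge_corpora <- function(datasets) {
  instances <- list()
  label_set <- character(0)
  for (ds in datasets) {
    tag <- ds$tag
    gran <- ds$granularity %||% if (tag$name == "ALL") "document" else "sentence"
    label_set <- union(label_set, paste0("O-", tag$name))
    label_set <- union(label_set,
                       c(paste0("B-", tag$covered_types),
                         paste0("I-", tag$covered_types)))
    for (doc in ds$corpus) {
      text <- doc_text(doc)
      tokens <- tokenize_text(text)
      labels <- encode_bio(tokens, doc$mentions, tag)
      units <- if (gran == "sentence") sentence_splits(tokens) else
        list(seq_len(nrow(tokens)))
      for (u in units) {
        instances[[length(instances) + 1L]] <- list(
          tokens = tokens[u, , drop = FALSE],
          labels = labels[u],
          tag = tag, doc_id = doc$doc_id, text = text)
      }
    }
  }
  list(instances = instances, labels = sort(label_set))
}

#' Configuration for the token-classification NER model
#'
#' Defaults are the grid-search optima of the reference setting (learning
#' rate 3e-5, batch size 16, 22 epochs, cross-entropy loss); toy encoders
#' want much larger learning rates, so runs on synthetic corpora pass their
#' own values.
#'
#' @param learning_rate,batch_size,epochs training hyperparameters.
#' @return a list of class `token_ner_config`.
#' @export
token_ner_config <- function(learning_rate = 3e-5, batch_size = 16, epochs = 22) {
  structure(list(learning_rate = learning_rate, batch_size = batch_size,
                 epochs = epochs, loss = "cross-entropy"),
            class = "token_ner_config")
}

# Convert a merged instance to id/label-index form for training.
ner_instance_ids <- function(enc, inst, label_set) {
  toks <- wrap_task_tokens(inst$tokens$token, inst$tag)
  y <- c(NA_integer_, match(inst$labels, label_set), NA_integer_)
  if (length(toks) > enc$max_len) {
    warning(sprintf("instance of %d tokens truncated to max_len=%d",
                    length(toks), enc$max_len))
    toks <- toks[seq_len(enc$max_len)]
    y <- y[seq_len(enc$max_len)]
  }
  list(ids = encoder_token_ids(enc, toks), y = y)
}

#' Fit the token-classification NER model
#'
#' Fine-tunes the encoder with a linear-plus-softmax head over the unified
#' BIO label set, minimizing cross-entropy on labeled tokens. Task-token
#' wrapper positions are masked from the loss. Training is reproducible
#' given `seed` and a fixed encoder.
#'
#' @param merged output of [merge_corpora()].
#' @param encoder a `tiny_encoder` (or any object honoring its contract).
#' @param cfg a [token_ner_config()].
#' @param seed integer seed controlling shuffling and head initialization.
#' @return an object of class `token_ner` with a `loss_history` element
#'   (mean per-token loss per epoch).
#' @export
fit_token_ner <- function(merged, encoder, cfg = token_ner_config(), seed = 1) {
  instances <- merged$instances
  if (!length(instances)) stop("no training instances")
  label_set <- merged$labels
  tags <- unique(lapply(instances, `[[`, "tag"))
  encoder <- encoder_add_tokens(
    encoder, unlist(lapply(tags, function(tg) c(tag_open(tg), tag_close(tg)))))
  K <- length(label_set)
  d <- encoder$dim
  head_ <- with_seed(seed + 1L, list(W = ginit(d, K), b = numeric(K)))
  params <- c(encoder$params, head_)
  opt <- adam_init(params)
  prepped <- lapply(instances, ner_instance_ids, enc = encoder,
                    label_set = label_set)
  loss_history <- numeric(0)
  with_seed(seed, {
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample.int(length(prepped))
      ep_loss <- 0; ep_n <- 0L
      for (batch in split(ord, ceiling(seq_along(ord) / cfg$batch_size))) {
        grads <- lapply(params, function(p) p * 0)
        n_tok <- sum(vapply(prepped[batch],
                            function(pp) sum(!is.na(pp$y)), integer(1)))
        if (n_tok == 0L) next
        for (ii in batch) {
          pp <- prepped[[ii]]
          encoder$params <- params[names(encoder$params)]
          X <- encoder_embed(encoder, pp$ids)
          fwd <- encoder_forward(encoder, X)
          logits <- fwd$H %*% params$W + rep(params$b, each = nrow(fwd$H))
          P <- softmax_rows(logits)
          valid <- which(!is.na(pp$y))
          ep_loss <- ep_loss - sum(log(pmax(
            P[cbind(valid, pp$y[valid])], 1e-12)))
          ep_n <- ep_n + length(valid)
          dlog <- matrix(0, nrow(P), K)
          dlog[valid, ] <- P[valid, , drop = FALSE]
          dlog[cbind(valid, pp$y[valid])] <-
            dlog[cbind(valid, pp$y[valid])] - 1
          dlog <- dlog / n_tok
          grads$W <- grads$W + crossprod(fwd$H, dlog)
          grads$b <- grads$b + colSums(dlog)
          bk <- encoder_backward(encoder, fwd$cache, dlog %*% t(params$W))
          for (nm in names(bk$grads)) grads[[nm]] <- grads[[nm]] + bk$grads[[nm]]
          grads$E <- accumulate_embedding_grad(grads$E, pp$ids, bk$dX)
        }
        st <- adam_step(opt, params, grads, cfg$learning_rate)
        opt <- st$opt; params <- st$params
      }
      loss_history <- c(loss_history, ep_loss / max(ep_n, 1L))
    }
  })
  encoder$params <- params[names(encoder$params)]
  structure(list(encoder = encoder, W = params$W, b = params$b,
                 labels = label_set, cfg = cfg, seed = seed,
                 loss_history = loss_history),
            class = "token_ner")
}

#' Predict mentions in a document with a trained token NER model
#'
#' Wraps the tokenized text in the task tokens, classifies each token by
#' argmax over the label softmax, strips the wrappers, and decodes the BIO
#' sequence into character-offset mentions.
#'
#' @param model a fitted `token_ner`.
#' @param doc an `rm_document`.
#' @param tag a [task_tag()] present in the model's label space.
#' @return a [mention_table()] of predicted, unlinked mentions.
#' @export
predict_mentions <- function(model, doc, tag = task_tag("ALL")) {
  if (!(paste0("O-", tag$name) %in% model$labels)) {
    stop("tag ", tag$name, " not in the model's label space")
  }
  text <- doc_text(doc)
  tokens <- tokenize_text(text)
  if (!nrow(tokens)) return(mention_table())
  toks <- wrap_task_tokens(tokens$token, tag)
  if (length(toks) > model$encoder$max_len) toks <- toks[seq_len(model$encoder$max_len)]
  ids <- encoder_token_ids(model$encoder, toks)
  H <- encoder_forward(model$encoder, encoder_embed(model$encoder, ids))$H
  logits <- H %*% model$W + rep(model$b, each = nrow(H))
  pred <- model$labels[max.col(logits, ties.method = "first")]
  inner <- strip_task_tokens(pred)
  tokens <- tokens[seq_along(inner), , drop = FALSE]
  decode_bio(tokens, inner, text)
}

#' Post-process predicted mentions by merging fragments
#'
#' Two rules, applied repeatedly until a fixpoint: (1) two mentions of the
#' same type appearing consecutively with no characters between them are
#' combined into a single mention (e.g. "A" + "(1)-adenosine receptor");
#' (2) two Disease mentions separated by exactly one character that is not a
#' slash are combined (e.g. "benign" + "tumor" across a space). Merged
#' mentions span both parts and have their identifiers reset (linking happens
#' downstream).
#'
#' @param doc the `rm_document` the mentions index (for surface slicing).
#' @param mentions a [mention_table()] sorted by start.
#' @return the post-processed [mention_table()].
#' @export
postprocess_mentions <- function(doc, mentions) {
  text <- doc_text(doc)
  m <- mentions[order(mentions$start, mentions$end), , drop = FALSE]
  repeat {
    merged <- FALSE
    i <- 1L
    while (i < nrow(m)) {
      gap <- m$start[i + 1L] - m$end[i]
      sep <- if (gap == 1L) substr(text, m$end[i] + 1L, m$end[i] + 1L) else ""
      do_merge <- (gap == 0L && m$type[i] == m$type[i + 1L]) ||
        (gap == 1L && m$type[i] == "Disease" && m$type[i + 1L] == "Disease" &&
           sep != "/")
      if (do_merge) {
        m$end[i] <- m$end[i + 1L]
        m$surface[i] <- substring(text, m$start[i] + 1L, m$end[i])
        m$ids[[i]] <- character(0)
        m <- m[-(i + 1L), , drop = FALSE]
        merged <- TRUE
      } else {
        i <- i + 1L
      }
    }
    if (!merged) break
  }
  rownames(m) <- NULL
  m
}
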