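#' Parse a PubTator-format corpus
#'
#' The PubTator dialect is line-oriented: per document a `PMID|t|<title>` line,
#' a `PMID|a|<abstract>` line, then tab-separated annotation lines -- mention
#' lines `PMID<TAB>start<TAB>end<TAB>surface<TAB>type<TAB>ids` and relation
#' lines `PMID<TAB>rtype<TAB>id1<TAB>id2[<TAB>novelty]` -- with a blank line
#' between documents. Mention offsets index the full text
#' `title + " " + abstract`. An identifier column of `"-"` denotes an unlinked
#' mention; composite mentions carry comma-joined identifiers.
#'
#' @param x path to a file, or a character vector of lines.
#' @param aliases alias table mapping raw entity-type / novelty labels onto
#'   the internal closed sets; see [default_aliases()].
#' @return an `rm_corpus`. Documents whose mention surfaces disagree with
#'   their spans are kept; the violations are attached as attribute
#'   `"violations"` on the corpus (a data.frame with a `doc_id` column).
#' @export
parse_pubtator <- function(x, aliases = default_aliases()) {
  lines <- if (length(x) == 1 && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else x
  docs <- list()
  viol <- list()
  cur <- NULL
  lineno <- 0L
  flush_doc <- function() {
    if (is.null(cur)) return()
    mm <- do.call(rbind, cur$mentions) %||% mention_table()
    rr <- do.call(rbind, cur$relations) %||% relation_table()
    rownames(mm) <- NULL
    rownames(rr) <- NULL
    d <- document(cur$doc_id, cur$title, cur$abstract, mm, rr)
    v <- validate_document(d)
    if (nrow(v)) {
      v$doc_id <- d$doc_id
      viol[[length(viol) + 1L]] <<- v
    }
    docs[[length(docs) + 1L]] <<- d
    cur <<- NULL
  }
  for (line in lines) {
    lineno <- lineno + 1L
    if (line == "") { flush_doc(); next }
    tpipe <- regmatches(line, regexec("^([^|\t]+)\\|t\\|(.*)$", line))[[1]]
    apipe <- regmatches(line, regexec("^([^|\t]+)\\|a\\|(.*)$", line))[[1]]
    if (length(tpipe)) {
      if (!is.null(cur) && !is.null(cur$title)) flush_doc()
      cur <- list(doc_id = tpipe[2], title = tpipe[3], abstract = "",
                  mentions = list(), relations = list())
      next
    }
    if (length(apipe)) {
      if (is.null(cur) || cur$doc_id != apipe[2]) {
        stop(sprintf("line %d: abstract line without matching title", lineno))
      }
      cur$abstract <- apipe[3]
      next
    }
    f <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (is.null(cur)) stop(sprintf("line %d: annotation before any title line", lineno))
    if (length(f) == 6) {
      raw_type <- f[5]
      ctype <- aliases$type[raw_type]
      if (is.na(ctype)) {
        stop(sprintf("line %d: unknown entity type label %s", lineno, dQuote(raw_type)))
      }
      st <- suppressWarnings(as.integer(f[2]))
      en <- suppressWarnings(as.integer(f[3]))
      if (is.na(st) || is.na(en)) {
        stop(sprintf("line %d: non-numeric mention offsets", lineno))
      }
      cur$mentions[[length(cur$mentions) + 1L]] <-
        mention_table(st, en, f[4], unname(ctype), ids = f[6], label = raw_type)
    } else if (length(f) %in% c(4L, 5L)) {
      nov <- if (length(f) == 5) {
        cn <- aliases$novelty[f[5]]
        if (is.na(cn)) stop(sprintf("line %d: unknown novelty label %s", lineno, dQuote(f[5])))
        unname(cn)
      } else NA_character_
      if (!(f[2] %in% RELATION_TYPES)) {
        stop(sprintf("line %d: unknown relation type %s", lineno, dQuote(f[2])))
      }
      cur$relations[[length(cur$relations) + 1L]] <-
        relation_table(f[2], f[3], f[4], nov)
    } else {
      stop(sprintf("line %d: malformed annotation line (%d fields)", lineno, length(f)))
    }
  }
  flush_doc()
  out <- corpus(docs)
  attr(out, "violations") <- do.call(rbind, viol) %||%
    data.frame(kind = character(0), detail = character(0), doc_id = character(0))
  out
}

#' Serialize a corpus to PubTator format
#'
#' Inverse of [parse_pubtator()]: `parse_pubtator(write_pubtator(x))`
#' reproduces `x`. Mention lines are sorted by start offset; unlinked mentions
#' are written with identifier `"-"`; composite identifiers are comma-joined;
#' the novelty column is written whenever present.
#'
#' @param x an `rm_corpus` or a single `rm_document`.
#' @param path optional file path; when given, lines are written there.
#' @return invisibly (if `path` given) or visibly, the character vector of
#'   lines.
#' @export
write_pubtator <- function(x, path = NULL) {
  if (inherits(x, "rm_document")) x <- corpus(list(x))
  blocks <- lapply(x, function(d) {
    m <- d$mentions
    if (nrow(m)) m <- m[order(m$start, m$end), , drop = FALSE]
    mlines <- vapply(seq_len(nrow(m)), function(i) {
      ids <- m$ids[[i]]
      paste(d$doc_id, m$start[i], m$end[i], m$surface[i], m$label[i],
            if (length(ids)) paste(ids, collapse = ",") else "-",
            sep = "\t")
    }, character(1))
    r <- d$relations
    rlines <- vapply(seq_len(nrow(r)), function(i) {
      base <- paste(d$doc_id, r$type[i], r$id1[i], r$id2[i], sep = "\t")
      if (!is.na(r$novelty[i])) paste(base, r$novelty[i], sep = "\t") else base
    }, character(1))
    c(paste0(d$doc_id, "|t|", d$title),
      paste0(d$doc_id, "|a|", d$abstract),
      mlines, rlines)
  })
  lines <- if (length(blocks)) {
    unname(unlist(mapply(
      function(b, last) c(b, if (!last) "" else character(0)),
      blocks, seq_along(blocks) == length(blocks), SIMPLIFY = FALSE)))
  } else character(0)
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
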