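#' @name corpus-model
#' @title Offset-anchored document and annotation model
#'
#' @description
#' Abstracts are modeled as a title and abstract joined by a single space; all
#' mention offsets are 0-based, half-open character positions into that full
#' text (the PubTator convention, where abstract offsets start at
#' `nchar(title) + 1`). Mentions carry one of six entity types (Gene, Disease,
#' Chemical, Species, Variant, CellLine) and zero or more knowledge-base
#' identifiers; relations are undirected typed pairs of identifiers with an
#' optional novelty label.
NULL

ENTITY_TYPES <- c("Gene", "Disease", "Chemical", "Species", "Variant", "CellLine")

RELATION_TYPES <- c("Association", "Positive_Correlation", "Negative_Correlation",
                    "Bind", "Comparison", "Conversion", "Cotreatment",
                    "Drug_Interaction")

NOVELTY_LABELS <- c("Novel", "No")

# Default alias table: corpus releases spell entity-type and novelty labels in
# several ways; all are mapped onto the internal closed sets at parse time.
default_aliases <- function() {
  list(
    type = c(
      Gene = "Gene", GeneOrGeneProduct = "Gene",
      Disease = "Disease", DiseaseOrPhenotypicFeature = "Disease",
      Chemical = "Chemical", ChemicalEntity = "Chemical",
      Species = "Species", OrganismTaxon = "Species",
      Variant = "Variant", SequenceVariant = "Variant", GeneticVariant = "Variant",
      CellLine = "CellLine"
    ),
    novelty = c(Novel = "Novel", No = "No", None = "No")
  )
}

#' Build a mention table
#'
#' @param start,end integer vectors of 0-based half-open character offsets.
#' @param surface character vector of mention surface strings.
#' @param type character vector drawn from the six entity types.
#' @param ids list of character vectors of identifiers (`character(0)` =
#'   unlinked; more than one = composite mention), or a character vector of
#'   comma-joined identifiers.
#' @param label optional character vector of raw type labels as spelled in a
#'   source file (preserved for byte-exact round-tripping); defaults to `type`.
#' @return a `data.frame` with columns `start`, `end`, `surface`, `type`,
#'   `label` and list-column `ids`.
#' @export
mention_table <- function(start = integer(), end = integer(),
                          surface = character(), type = character(),
                          ids = NULL, label = NULL) {
  n <- length(start)
  if (is.null(ids)) ids <- rep(list(character(0)), n)
  if (is.character(ids)) {
    ids <- lapply(ids, function(s) {
      if (is.na(s) || s == "-" || s == "") character(0)
      else strsplit(s, ",", fixed = TRUE)[[1]]
    })
  }
  stopifnot(length(end) == n, length(surface) == n, length(type) == n,
            length(ids) == n)
  bad <- setdiff(unique(type), ENTITY_TYPES)
  if (length(bad)) stop("unknown entity type(s): ", paste(bad, collapse = ", "))
  df <- data.frame(start = as.integer(start), end = as.integer(end),
                   surface = as.character(surface), type = as.character(type),
                   label = as.character(label %||% type),
                   stringsAsFactors = FALSE)
  df$ids <- ids
  df
}

#' Build a relation table
#'
#' Identifier pairs are undirected and stored sorted lexicographically.
#'
#' @param type character vector drawn from the eight relation types.
#' @param id1,id2 character vectors of entity identifiers (distinct per row).
#' @param novelty character vector of `"Novel"`/`"No"`, or `NA` when absent.
#' @return a `data.frame` with columns `type`, `id1`, `id2`, `novelty`.
#' @export
relation_table <- function(type = character(), id1 = character(),
                           id2 = character(), novelty = NA_character_) {
  n <- length(type)
  novelty <- rep_len(as.character(novelty), max(n, 1L))[seq_len(n)]
  bad <- setdiff(unique(type), RELATION_TYPES)
  if (length(bad)) stop("unknown relation type(s): ", paste(bad, collapse = ", "))
  if (any(id1 == id2)) stop("relation pair members must be distinct")
  lo <- pmin(id1, id2)
  hi <- pmax(id1, id2)
  data.frame(type = as.character(type), id1 = lo, id2 = hi,
             novelty = novelty, stringsAsFactors = FALSE)
}

#' Construct a document
#'
#' @param doc_id PMID-style identifier string.
#' @param title,abstract text fields; the full annotated text is
#'   `paste(title, abstract, sep = " ")`.
#' @param mentions a [mention_table()].
#' @param relations a [relation_table()].
#' @return an object of class `rm_document`.
#' @export
document <- function(doc_id, title, abstract = "",
                     mentions = mention_table(),
                     relations = relation_table()) {
  structure(list(doc_id = as.character(doc_id), title = title,
                 abstract = abstract, mentions = mentions,
                 relations = relations),
            class = "rm_document")
}

#' Full annotated text of a document
#' @param doc an `rm_document`.
#' @return a string: title, one separator space, abstract.
#' @export
doc_text <- function(doc) paste(doc$title, doc$abstract, sep = " ")

#' Construct a corpus
#' @param documents list of [document()] objects with unique `doc_id`s.
#' @return an object of class `rm_corpus` (a list of documents, named by id).
#' @export
corpus <- function(documents = list()) {
  ids <- vapply(documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) stop("duplicate doc_ids in corpus")
  names(documents) <- ids
  structure(documents, class = "rm_corpus")
}

#' @export
print.rm_corpus <- function(x, ...) {
  nm <- sum(vapply(x, function(d) nrow(d$mentions), integer(1)))
  nr <- sum(vapply(x, function(d) nrow(d$relations), integer(1)))
  cat(sprintf("<corpus: %d documents, %d mentions, %d relations>\n",
              length(x), nm, nr))
  invisible(x)
}

#' @export
print.rm_document <- function(x, ...) {
  cat(sprintf("<document %s: %d mentions, %d relations>\n  %s\n",
              x$doc_id, nrow(x$mentions), nrow(x$relations),
              substr(x$title, 1, 70)))
  invisible(x)
}

#' Validate a document's annotation invariants
#'
#' Checks are total: every violated invariant yields one record and a valid
#' document yields a zero-row table. Checked invariants: mention spans lie
#' within the full text ("offset overflow"), each surface equals the text
#' substring at its span ("surface mismatch"), and every relation identifier
#' appears among some mention's identifiers ("dangling relation id").
#'
#' @param doc an `rm_document`.
#' @return `data.frame` with columns `kind` and `detail`; zero rows iff valid.
#' @export
validate_document <- function(doc) {
  text <- doc_text(doc)
  n <- nchar(text)
  kind <- character(0)
  detail <- character(0)
  m <- doc$mentions
  for (i in seq_len(nrow(m))) {
    if (!(m$start[i] >= 0 && m$start[i] < m$end[i])) {
      kind <- c(kind, "bad span")
      detail <- c(detail, sprintf("mention %d: start=%d end=%d", i, m$start[i], m$end[i]))
      next
    }
    if (m$end[i] > n) {
      kind <- c(kind, "offset overflow")
      detail <- c(detail, sprintf("mention %d: end=%d > text length %d", i, m$end[i], n))
      next
    }
    sub <- substr(text, m$start[i] + 1L, m$end[i])
    if (!identical(sub, m$surface[i])) {
      kind <- c(kind, "surface mismatch")
      detail <- c(detail, sprintf("mention %d: span text %s != surface %s",
                                  i, dQuote(sub), dQuote(m$surface[i])))
    }
  }
  known <- unique(unlist(m$ids))
  r <- doc$relations
  for (i in seq_len(nrow(r))) {
    for (id in c(r$id1[i], r$id2[i])) {
      if (!(id %in% known)) {
        kind <- c(kind, "dangling relation id")
        detail <- c(detail, sprintf("relation %d: identifier %s not on any mention", i, id))
      }
    }
  }
  data.frame(kind = kind, detail = detail, stringsAsFactors = FALSE)
}

#' Group a document's mentions by entity identifier
#'
#' A mention with k identifiers (a composite mention) contributes to k groups;
#' unlinked mentions are excluded. Multiple mentions of the same entity are
#' common in abstracts, and downstream pair classification consumes all of
#' them per entity.
#'
#' @param doc an `rm_document`.
#' @return named list: identifier -> [mention_table()] of that entity's
#'   mentions (in document order).
#' @export
group_mentions_by_entity <- function(doc) {
  m <- doc$mentions
  out <- list()
  for (i in seq_len(nrow(m))) {
    for (id in m$ids[[i]]) {
      out[[id]] <- c(out[[id]], i)
    }
  }
  lapply(out, function(idx) m[idx, , drop = FALSE])
}
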