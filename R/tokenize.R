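#' Tokenize text with character offsets
#'
#' Whitespace-and-punctuation tokenization: maximal alphanumeric runs are
#' word tokens, every other non-space character is a single-character token.
#' Character spans (0-based, half-open) are tracked so decoded labels can be
#' mapped back to exact document offsets.
#'
#' @param text a string.
#' @return `data.frame` with columns `token`, `start`, `end`.
#' @export
tokenize_text <- function(text) {
  m <- gregexpr("[A-Za-z0-9_]+|[^A-Za-z0-9_[:space:]]", text)[[1]]
  if (length(m) == 1 && m[1] == -1) {
    return(data.frame(token = character(0), start = integer(0), end = integer(0),
                      stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(token = regmatches(text, list(m))[[1]],
             start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             stringsAsFactors = FALSE)
}

# Indices of tokens fully or partially covered by [start, end).
tokens_in_span <- function(tokens, start, end) {
  which(tokens$end > start & tokens$start < end)
}

# Split a token table into sentences at "." tokens (the "." stays with the
# preceding sentence). Returns a list of row-index vectors.
sentence_splits <- function(tokens) {
  if (!nrow(tokens)) return(list())
  ends <- which(tokens$token == ".")
  if (!length(ends) || ends[length(ends)] != nrow(tokens)) {
    ends <- c(ends, nrow(tokens))
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- starts <= ends
  mapply(seq.int, starts[keep], ends[keep], SIMPLIFY = FALSE)
}
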