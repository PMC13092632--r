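# Shared text utilities: tokenization, sentence segmentation, span helpers.
# All character offsets in this package are 0-based, half-open [start, end).

#' Tokenize text on non-alphanumeric boundaries
#'
#' Splits a document into maximal runs of alphanumeric characters, recording
#' the 0-based half-open character span of every token.
#'
#' @param text A single character string.
#' @return A data.frame with columns `start`, `end` (0-based half-open) and
#'   `token`.
#' @export
tokenizeText <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (is.na(text) || nchar(text) == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      token = character(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[[:alnum:]]+", text)[[1]]
  if (m[1] == -1L) {
    return(data.frame(start = integer(0), end = integer(0),
                      token = character(0), stringsAsFactors = FALSE))
  }
  len <- attr(m, "match.length")
  data.frame(start = as.integer(m) - 1L,
             end = as.integer(m) - 1L + len,
             token = substring(text, m, m + len - 1L),
             stringsAsFactors = FALSE)
}

#' Split text into sentences with character offsets
#'
#' A deliberately simple splitter: sentence boundaries are runs of `.`, `!`,
#' `?` or newline characters; the delimiter is attached to the preceding
#' sentence. Offsets are 0-based half-open over the input.
#'
#' @param text A single character string.
#' @return A data.frame with columns `start`, `end`, `text`.
#' @export
splitSentences <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  n <- nchar(text)
  if (n == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  m <- gregexpr("[.!?\n]+", text)[[1]]
  if (m[1] == -1L) {
    ends <- n
  } else {
    ends <- as.integer(m) + attr(m, "match.length") - 1L
    if (ends[length(ends)] < n) ends <- c(ends, n)
  }
  starts <- c(1L, head(ends, -1L) + 1L)
  keep <- starts <= ends
  starts <- starts[keep]; ends <- ends[keep]
  txt <- substring(text, starts, ends)
  nonblank <- grepl("[^[:space:]]", txt)
  data.frame(start = starts[nonblank] - 1L, end = ends[nonblank],
             text = txt[nonblank], stringsAsFactors = FALSE)
}

# Sentence containing a 0-based half-open span; falls back to the whole text.
containingSentence <- function(text, start, end) {
  sents <- splitSentences(text)
  if (nrow(sents) == 0L) return(text)
  hit <- which(sents$start <= start & sents$end > start)
  if (length(hit) == 0L) hit <- nrow(sents)
  trimws(sents$text[hit[1]])
}

# Collapse internal whitespace and trim; shared normalization for matching.
squeezeWhitespace <- function(x) gsub("[[:space:]]+", " ", trimws(x))

# TRUE where spans [s1,e1) and [s2,e2) intersect (vectorized).
spansOverlap <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1
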