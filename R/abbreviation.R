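# Abbreviation detection and zero-shot context-based disambiguation.
#
# Detection is dictionary pattern matching at token boundaries, longest key
# first so nested abbreviations are never expanded prematurely. Each detected
# abbreviation is expanded by comparing its containing sentence against the
# context-sample collections of its candidate expansions; the best-scoring
# expansion is chosen only when its cosine similarity clears a minimum gate
# (default 0.3), otherwise the text is left as-is.

#' Abbreviation dictionary
#'
#' Maps abbreviations to candidate expansions, each expansion carrying up to
#' a configured number of context samples (sentences in which the expansion
#' was observed). An expansion with no context samples is never selectable by
#' context comparison.
#'
#' @slot entries Named list: abbreviation -> list of expansions, each a list
#'   with elements `text` (string) and `samples` (character vector).
#' @export
setClass("AbbreviationDictionary", representation(entries = "list"))

setValidity("AbbreviationDictionary", function(object) {
  nm <- names(object@entries)
  if (length(object@entries) && (is.null(nm) || any(!nzchar(nm))))
    return("every abbreviation must be a non-empty name")
  if (anyDuplicated(nm)) return("abbreviations must be unique")
  for (a in nm) {
    exps <- object@entries[[a]]
    if (length(exps) == 0L)
      return(paste0("abbreviation '", a, "' has no expansions"))
    for (e in exps)
      if (is.null(e$text) || !nzchar(e$text))
        return(paste0("abbreviation '", a, "' has an empty expansion"))
  }
  TRUE
})

setMethod("show", "AbbreviationDictionary", function(object) {
  cat("AbbreviationDictionary:", length(object@entries), "abbreviations,",
      sum(vapply(object@entries, length, integer(1))), "expansions\n")
})

#' Construct an abbreviation dictionary from (abbreviation, expansion) pairs
#'
#' @param pairs data.frame with columns `abbreviation` and `expansion`
#'   (repeated rows per sense).
#' @return An [AbbreviationDictionary-class].
#' @export
abbreviationDictionary <- function(pairs) {
  entries <- list()
  for (i in seq_len(nrow(pairs))) {
    a <- as.character(pairs$abbreviation[i])
    e <- as.character(pairs$expansion[i])
    cur <- entries[[a]]
    if (is.null(cur)) cur <- list()
    if (!e %in% vapply(cur, `[[`, character(1), "text"))
      cur[[length(cur) + 1L]] <- list(text = e, samples = character(0))
    entries[[a]] <- cur
  }
  new("AbbreviationDictionary", entries = entries)
}

#' Read a two-column delimited abbreviation dictionary file
#'
#' @param file Path to a delimited text file with columns `abbreviation`
#'   and `expansion`.
#' @param sep Field separator (default tab).
#' @return An [AbbreviationDictionary-class].
#' @export
readAbbreviationDictionary <- function(file, sep = "\t") {
  tab <- utils::read.delim(file, sep = sep, quote = "",
                           colClasses = "character", stringsAsFactors = FALSE)
  requireColumns(tab, c("abbreviation", "expansion"), file)
  abbreviationDictionary(tab)
}

#' @describeIn abbreviationDictionary Abbreviation keys.
#' @param dictionary An [AbbreviationDictionary-class].
#' @export
abbreviations <- function(dictionary) names(dictionary@entries)

#' @describeIn abbreviationDictionary Expansions of one abbreviation as a
#'   list of `list(text, samples)`.
#' @param abbreviation Abbreviation key.
#' @export
expansionsOf <- function(dictionary, abbreviation) {
  e <- dictionary@entries[[abbreviation]]
  if (is.null(e)) stop("unknown abbreviation: '", abbreviation, "'")
  e
}

#' Harvest abbreviation-expansion pairs from hyphenated terms
#'
#' Emits a pair for every term of the form `"<token> - <phrase>"` (any of
#' `-`, en or em dash) where the letters of the token match, in order and
#' case-insensitively, the first letters of the phrase's words — e.g.
#' `"AP - abdominal pain"` yields `("AP", "abdominal pain")`.
#'
#' @param terms Character vector of candidate terms.
#' @return data.frame with columns `abbreviation`, `expansion`.
#' @export
harvestHyphenPairs <- function(terms) {
  out <- list(); n <- 0L
  for (term in terms) {
    m <- regmatches(term,
                    regexec("^\\s*(\\S+)\\s*[-–—]\\s*(.+?)\\s*$", term))[[1]]
    if (length(m) != 3L) next
    token <- m[2]; phrase <- m[3]
    letters <- strsplit(tolower(token), "")[[1]]
    letters <- letters[grepl("[[:alnum:]]", letters)]
    words <- strsplit(tolower(phrase), "[[:space:]]+")[[1]]
    words <- words[nzchar(words)]
    if (length(letters) == 0L || length(letters) != length(words)) next
    if (!all(letters == substr(words, 1L, 1L))) next
    n <- n + 1L
    out[[n]] <- data.frame(abbreviation = token, expansion = phrase,
                           stringsAsFactors = FALSE)
  }
  if (n == 0L)
    return(data.frame(abbreviation = character(0), expansion = character(0),
                      stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Detect dictionary abbreviations in text
#'
#' Pattern matching at token boundaries. All-uppercase dictionary keys match
#' case-sensitively (so "AP" never fires inside lowercase words); other keys
#' match case-insensitively. Longer keys claim positions first, then leftmost
#' occurrences; retained matches never overlap.
#'
#' @param text Document string.
#' @param dictionary An [AbbreviationDictionary-class] with at least one
#'   entry.
#' @return data.frame of unresolved matches with columns `start`, `end`
#'   (0-based half-open) and `abbreviation`, sorted by `start`.
#' @export
detectAbbreviations <- function(text, dictionary) {
  if (length(dictionary@entries) == 0L)
    stop("state error: dictionary is empty")
  empty <- data.frame(start = integer(0), end = integer(0),
                      abbreviation = character(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  keys <- names(dictionary@entries)
  keys <- keys[order(-nchar(keys), keys)]
  cand <- list(); n <- 0L
  for (key in keys) {
    caseSensitive <- key == toupper(key) && grepl("[[:alpha:]]", key)
    pat <- paste0("(?<![[:alnum:]])",
                  gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", key),
                  "(?![[:alnum:]])")
    m <- gregexpr(pat, text, perl = TRUE, ignore.case = !caseSensitive)[[1]]
    if (m[1] == -1L) next
    len <- attr(m, "match.length")
    n <- n + 1L
    cand[[n]] <- data.frame(start = as.integer(m) - 1L,
                            end = as.integer(m) - 1L + len,
                            abbreviation = key, nch = nchar(key),
                            stringsAsFactors = FALSE)
  }
  if (n == 0L) return(empty)
  cand <- do.call(rbind, cand)
  cand <- cand[order(-cand$nch, cand$start), , drop = FALSE]
  taken <- logical(nchar(text))
  keep <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    idx <- (cand$start[i] + 1L):cand$end[i]
    if (!any(taken[idx])) {
      keep[i] <- TRUE
      taken[idx] <- TRUE
    }
  }
  res <- cand[keep, c("start", "end", "abbreviation"), drop = FALSE]
  res <- res[order(res$start), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Collect context samples for every expansion from a corpus
#'
#' Reverse-substitution style: for each expansion, the first `n` corpus
#' sentences containing the expansion text (case-insensitive substring, in
#' first-encounter order) become its context samples. Expansions that never
#' occur keep zero samples and remain unselectable by context.
#'
#' @param dictionary An [AbbreviationDictionary-class].
#' @param corpus Character vector of documents.
#' @param n Maximum samples per expansion (default 30).
#' @return The enriched [AbbreviationDictionary-class].
#' @export
collectContextSamples <- function(dictionary, corpus, n = 30L) {
  if (n < 1L) stop("input error: n must be >= 1")
  sentences <- unlist(lapply(corpus, function(doc) splitSentences(doc)$text),
                      use.names = FALSE)
  sentences <- trimws(sentences)
  lowSent <- tolower(sentences)
  entries <- dictionary@entries
  for (a in names(entries)) {
    for (j in seq_along(entries[[a]])) {
      expText <- tolower(entries[[a]][[j]]$text)
      hits <- sentences[grepl(expText, lowSent, fixed = TRUE)]
      entries[[a]][[j]]$samples <- utils::head(hits, n)
    }
  }
  new("AbbreviationDictionary", entries = entries)
}

# Resolve one detected abbreviation against its expansion context samples.
# Returns list(expansion = text or NA, score = best similarity or NA).
disambiguateMatch <- function(abbreviation, context, dictionary, provider,
                              minSimilarity) {
  exps <- dictionary@entries[[abbreviation]]
  if (is.null(exps) || length(exps) == 0L)
    stop("state error: no expansions for abbreviation '", abbreviation, "'")
  withSamples <- Filter(function(e) length(e$samples) > 0L, exps)
  if (length(withSamples) == 0L)
    return(list(expansion = NA_character_, score = NA_real_))
  ctxVec <- embedTexts(context, provider)[1, ]
  best <- vapply(withSamples, function(e) {
    sampleEmb <- embedTexts(e$samples, provider)
    max(as.numeric(sampleEmb %*% ctxVec))
  }, numeric(1))
  texts <- vapply(withSamples, `[[`, character(1), "text")
  ord <- order(-best, texts)       # ties: lexicographic expansion text
  score <- best[ord[1]]
  if (score >= minSimilarity)
    list(expansion = texts[ord[1]], score = score)
  else
    list(expansion = NA_character_, score = score)
}

# Match the original casing convention: capitalize the expansion when the
# abbreviation occurrence starts a sentence-like uppercase position.
matchCase <- function(expansion, original) {
  first <- substr(original, 1L, 1L)
  if (first == toupper(first) && first != tolower(first))
    paste0(toupper(substr(expansion, 1L, 1L)), substring(expansion, 2L))
  else expansion
}

#' Detect, disambiguate and expand all abbreviations in a document
#'
#' Runs [detectAbbreviations()], resolves each match against the context of
#' its containing sentence, replaces every resolved match by its expansion,
#' and returns the expanded text together with an offset map translating
#' expanded-text positions back to original positions (so downstream entity
#' links can be reported in original coordinates).
#'
#' @param text Document string.
#' @param dictionary An [AbbreviationDictionary-class].
#' @param provider An [EmbeddingProvider-class].
#' @param minSimilarity Minimum context similarity to expand (default 0.3).
#' @return A list with elements `text` (expanded document), `map` (offset
#'   map data.frame, see [mapToOriginal()]), and `matches` (data.frame with
#'   columns `start`, `end`, `abbreviation`, `expansion`, `score` in
#'   original coordinates; `expansion` is `NA` where the gate rejected all
#'   candidates).
#' @export
expandAbbreviations <- function(text, dictionary, provider,
                                minSimilarity = 0.3) {
  matches <- detectAbbreviations(text, dictionary)
  matches$expansion <- rep(NA_character_, nrow(matches))
  matches$score <- rep(NA_real_, nrow(matches))
  if (nrow(matches) > 0L) {
    for (i in seq_len(nrow(matches))) {
      ctx <- containingSentence(text, matches$start[i], matches$end[i])
      res <- disambiguateMatch(matches$abbreviation[i], ctx, dictionary,
                               provider, minSimilarity)
      matches$expansion[i] <- res$expansion
      matches$score[i] <- res$score
    }
  }
  resolved <- matches[!is.na(matches$expansion), , drop = FALSE]
  segs <- list(); pieces <- character(0)
  cursor <- 0L; newPos <- 0L; k <- 0L
  addSeg <- function(os, oe, ns, ne, repl) {
    k <<- k + 1L
    segs[[k]] <<- data.frame(origStart = os, origEnd = oe, newStart = ns,
                             newEnd = ne, replaced = repl)
  }
  if (nrow(resolved) > 0L) {
    for (i in seq_len(nrow(resolved))) {
      s <- resolved$start[i]; e <- resolved$end[i]
      if (s > cursor) {
        piece <- substr(text, cursor + 1L, s)
        pieces <- c(pieces, piece)
        addSeg(cursor, s, newPos, newPos + nchar(piece), FALSE)
        newPos <- newPos + nchar(piece)
      }
      orig <- substr(text, s + 1L, e)
      repl <- matchCase(resolved$expansion[i], orig)
      pieces <- c(pieces, repl)
      addSeg(s, e, newPos, newPos + nchar(repl), TRUE)
      newPos <- newPos + nchar(repl)
      cursor <- e
    }
  }
  if (cursor < nchar(text) || k == 0L) {
    piece <- substring(text, cursor + 1L)
    pieces <- c(pieces, piece)
    addSeg(cursor, nchar(text), newPos, newPos + nchar(piece), FALSE)
  }
  map <- do.call(rbind, segs)
  list(text = paste(pieces, collapse = ""), map = map, matches = matches)
}

#' Map expanded-text positions back to original coordinates
#'
#' Positions inside an unchanged segment map linearly; positions inside a
#' replacement map onto the replaced original span (its start for position
#' mapping). `originalSpan` maps a 0-based half-open span of the expanded
#' text to the covering span of the original text. `expandedPosition` is the
#' forward map for original positions (inverse of `mapToOriginal` on
#' unchanged segments).
#'
#' @param map Offset map from [expandAbbreviations()].
#' @param pos Integer vector of 0-based positions in the expanded text.
#' @return Integer vector of original positions.
#' @export
mapToOriginal <- function(map, pos) {
  vapply(pos, function(p) {
    i <- which(map$newStart <= p & p < map$newEnd)
    if (length(i) == 0L) {        # end-of-text position
      return(map$origEnd[nrow(map)])
    }
    i <- i[1]
    if (map$replaced[i]) map$origStart[i]
    else map$origStart[i] + (p - map$newStart[i])
  }, integer(1))
}

#' @rdname mapToOriginal
#' @param start,end 0-based half-open span in the expanded text.
#' @export
originalSpan <- function(map, start, end) {
  rows <- which(map$newStart < end & start < map$newEnd)
  if (length(rows) == 0L) return(c(start = start, end = start))
  os <- min(vapply(rows, function(i) {
    if (map$replaced[i]) map$origStart[i]
    else map$origStart[i] + max(0L, start - map$newStart[i])
  }, integer(1)))
  oe <- max(vapply(rows, function(i) {
    if (map$replaced[i]) map$origEnd[i]
    else map$origStart[i] + min(map$newEnd[i], end) - map$newStart[i]
  }, integer(1)))
  c(start = os, end = oe)
}

#' @rdname mapToOriginal
#' @export
expandedPosition <- function(map, pos) {
  vapply(pos, function(p) {
    i <- which(map$origStart <= p & p < map$origEnd)
    if (length(i) == 0L) return(map$newEnd[nrow(map)])
    i <- i[1]
    if (map$replaced[i]) map$newStart[i]
    else map$newStart[i] + (p - map$origStart[i])
  }, integer(1))
}
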