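# Semantic entity linking: two-phase algorithm.
#
# Candidate identification (high recall): (1) build an abbreviation table
# over the document (longest-first pattern matching + context
# disambiguation); (2) tokenize on non-alphanumeric boundaries and form all
# n-grams of 1..max_ngram_len tokens; (3) drop n-grams containing a
# prohibited infix (a full stop or hyphen followed by whitespace, which
# signal sentence/bullet boundaries), then expand abbreviations inside the
# surviving n-grams while keeping the original character spans; (4) retrieve
# the top-k most similar terminology descriptions for every n-gram.
#
# Candidate selection (precision): (1) threshold filter, (2) concept
# pinpointing within overlapping spans, (3) positive/negative context
# collection filter with online learning, (4) nesting minimization.

#' Linker configuration
#'
#' @slot maxNgramLen Maximum n-gram token length (default 30).
#' @slot topK Number of description hits per n-gram (default 10).
#' @slot selectionThreshold Minimum cosine similarity for a candidate to
#'   survive selection (default 0.95; the method is intended for high
#'   thresholds, typically 0.9-0.99).
#' @slot prohibitedInfixes Substrings that disqualify an n-gram (default
#'   `". "` and `"- "`).
#' @slot abbrevGate Minimum context similarity to expand an abbreviation
#'   (default 0.3).
#' @export
setClass("LinkerConfig",
         representation(maxNgramLen = "integer", topK = "integer",
                        selectionThreshold = "numeric",
                        prohibitedInfixes = "character",
                        abbrevGate = "numeric"))

setValidity("LinkerConfig", function(object) {
  if (object@maxNgramLen < 1L) return("maxNgramLen must be >= 1")
  if (object@topK < 1L) return("topK must be >= 1")
  if (object@selectionThreshold < 0 || object@selectionThreshold > 1)
    return("selectionThreshold must be in [0, 1]")
  if (object@abbrevGate < 0 || object@abbrevGate > 1)
    return("abbrevGate must be in [0, 1]")
  TRUE
})

setMethod("show", "LinkerConfig", function(object) {
  cat("LinkerConfig: maxNgramLen =", object@maxNgramLen,
      ", topK =", object@topK,
      ", selectionThreshold =", object@selectionThreshold,
      ", abbrevGate =", object@abbrevGate, "\n")
})

#' Construct a linker configuration
#'
#' @param maxNgramLen,topK,selectionThreshold,prohibitedInfixes,abbrevGate
#'   See [LinkerConfig-class].
#' @return A [LinkerConfig-class].
#' @export
linkerConfig <- function(maxNgramLen = 30L, topK = 10L,
                         selectionThreshold = 0.95,
                         prohibitedInfixes = c(". ", "- "),
                         abbrevGate = 0.3) {
  new("LinkerConfig", maxNgramLen = as.integer(maxNgramLen),
      topK = as.integer(topK), selectionThreshold = selectionThreshold,
      prohibitedInfixes = prohibitedInfixes, abbrevGate = abbrevGate)
}

#' Per-concept context collections for online learning
#'
#' Positive samples come from curated context for ambiguous descriptions and
#' from ground-truth-confirmed links; negative samples from links the ground
#' truth rejected. A concept with only negative samples is blacklisted.
#'
#' @slot positive Named list: concept_id -> character vector of samples.
#' @slot negative Named list: concept_id -> character vector of samples.
#' @export
setClass("ContextCollection",
         representation(positive = "list", negative = "list"))

setMethod("show", "ContextCollection", function(object) {
  cat("ContextCollection:", length(object@positive), "concepts with positive,",
      length(object@negative), "with negative samples\n")
})

#' Construct an (optionally pre-seeded) context collection
#'
#' @param positive,negative Named lists of character vectors keyed by
#'   concept id.
#' @return A [ContextCollection-class].
#' @export
contextCollection <- function(positive = list(), negative = list()) {
  new("ContextCollection", positive = positive, negative = negative)
}

#' @describeIn contextCollection Positive samples of one concept.
#' @param collection A [ContextCollection-class].
#' @param conceptId Concept identifier.
#' @export
positiveSamples <- function(collection, conceptId) {
  s <- collection@positive[[conceptId]]
  if (is.null(s)) character(0) else s
}

#' @describeIn contextCollection Negative samples of one concept.
#' @export
negativeSamples <- function(collection, conceptId) {
  s <- collection@negative[[conceptId]]
  if (is.null(s)) character(0) else s
}

#' @describeIn contextCollection Append a positive sample.
#' @param sample Context sentence to add.
#' @export
addPositiveSample <- function(collection, conceptId, sample) {
  collection@positive[[conceptId]] <-
    c(positiveSamples(collection, conceptId), sample)
  collection
}

#' @describeIn contextCollection Append a negative sample.
#' @export
addNegativeSample <- function(collection, conceptId, sample) {
  collection@negative[[conceptId]] <-
    c(negativeSamples(collection, conceptId), sample)
  collection
}

emptyCandidates <- function() {
  data.frame(start = integer(0), end = integer(0), text = character(0),
             description_id = character(0), concept_id = character(0),
             similarity = numeric(0), stringsAsFactors = FALSE)
}

#' Identify entity link candidates in a document
#'
#' The four-step high-recall phase: abbreviation table, n-gram formation,
#' prohibited-infix filtering plus in-n-gram abbreviation expansion (original
#' character spans are preserved from the pre-expansion text), and top-k
#' retrieval of similar terminology descriptions. A hit on an ambiguous
#' description yields one candidate per associated concept.
#'
#' @param text Document string (original, pre-expansion coordinates).
#' @param index An embedded [TerminologyIndex-class].
#' @param dictionary An [AbbreviationDictionary-class] or `NULL`.
#' @param provider An [EmbeddingProvider-class].
#' @param config A [LinkerConfig-class].
#' @param withAbbrev Run abbreviation disambiguation (default `TRUE` when a
#'   dictionary is supplied).
#' @return data.frame of candidates: `start`, `end` (0-based half-open,
#'   original coordinates), `text` (after in-n-gram expansion),
#'   `description_id`, `concept_id`, `similarity`.
#' @export
identifyCandidates <- function(text, index, dictionary = NULL, provider,
                               config = linkerConfig(),
                               withAbbrev = !is.null(dictionary)) {
  if (nrow(index@embeddings) == 0L)
    stop("state error: terminology index has no embeddings")
  if (!nzchar(trimws(text))) return(emptyCandidates())

  # step 1: abbreviation overview table (spans + chosen expansions)
  abbrevTab <- NULL
  if (withAbbrev && !is.null(dictionary)) {
    matches <- detectAbbreviations(text, dictionary)
    if (nrow(matches) > 0L) {
      matches$expansion <- NA_character_
      for (i in seq_len(nrow(matches))) {
        ctx <- containingSentence(text, matches$start[i], matches$end[i])
        res <- disambiguateMatch(matches$abbreviation[i], ctx, dictionary,
                                 provider, config@abbrevGate)
        matches$expansion[i] <- res$expansion
      }
      abbrevTab <- matches[!is.na(matches$expansion), , drop = FALSE]
    }
  }

  # step 2: n-grams over non-alphanumeric token boundaries
  toks <- tokenizeText(text)
  nTok <- nrow(toks)
  if (nTok == 0L) return(emptyCandidates())
  maxLen <- min(config@maxNgramLen, nTok)
  starts <- integer(0); ends <- integer(0)
  for (n in seq_len(maxLen)) {
    i <- seq_len(nTok - n + 1L)
    starts <- c(starts, toks$start[i])
    ends <- c(ends, toks$end[i + n - 1L])
  }
  ngramText <- substring(text, starts + 1L, ends)

  # step 3: drop prohibited infixes, then expand abbreviations inside
  bad <- rep(FALSE, length(ngramText))
  for (infix in config@prohibitedInfixes)
    bad <- bad | grepl(infix, ngramText, fixed = TRUE)
  starts <- starts[!bad]; ends <- ends[!bad]; ngramText <- ngramText[!bad]
  if (length(ngramText) == 0L) return(emptyCandidates())
  if (!is.null(abbrevTab) && nrow(abbrevTab) > 0L) {
    for (g in seq_along(ngramText)) {
      inside <- abbrevTab[abbrevTab$start >= starts[g] &
                          abbrevTab$end <= ends[g], , drop = FALSE]
      if (nrow(inside) == 0L) next
      inside <- inside[order(-inside$start), , drop = FALSE]
      s <- ngramText[g]
      for (j in seq_len(nrow(inside))) {
        rs <- inside$start[j] - starts[g]   # 0-based within n-gram
        re <- inside$end[j] - starts[g]
        repl <- matchCase(inside$expansion[j], substr(s, rs + 1L, re))
        s <- paste0(substr(s, 1L, rs), repl, substring(s, re + 1L))
      }
      ngramText[g] <- s
    }
  }

  # step 4: top-k description retrieval per n-gram
  uniq <- unique(ngramText)
  qEmb <- embedTexts(uniq, provider)
  rownames(qEmb) <- uniq
  out <- vector("list", length(ngramText))
  for (g in seq_along(ngramText)) {
    hits <- topKHits(index@embeddings, qEmb[ngramText[g], ], config@topK)
    cids <- index@descConcepts[hits$description_id]
    reps <- lengths(cids)
    out[[g]] <- data.frame(start = rep.int(starts[g], sum(reps)),
                           end = rep.int(ends[g], sum(reps)),
                           text = rep.int(ngramText[g], sum(reps)),
                           description_id = rep(hits$description_id, reps),
                           concept_id = unlist(cids, use.names = FALSE),
                           similarity = rep(hits$score, reps),
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- res[order(res$start, res$end, -res$similarity, res$description_id,
                   res$concept_id), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Selection step 1: similarity threshold filter
#'
#' @param candidates Candidate data.frame from [identifyCandidates()].
#' @param threshold Minimum similarity; candidates below it are discarded.
#' @return The filtered candidate data.frame.
#' @export
thresholdFilter <- function(candidates, threshold) {
  res <- candidates[candidates$similarity >= threshold, , drop = FALSE]
  rownames(res) <- NULL
  res
}

# Connected components of the span-overlap graph among rows (by index).
overlapComponents <- function(start, end) {
  n <- length(start)
  comp <- integer(n)
  cur <- 0L
  for (i in seq_len(n)) {
    if (comp[i] != 0L) next
    cur <- cur + 1L
    queue <- i
    comp[i] <- cur
    while (length(queue)) {
      a <- queue[1]; queue <- queue[-1]
      nb <- which(comp == 0L & spansOverlap(start[a], end[a], start, end))
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  comp
}

#' Selection step 2: concept pinpointing
#'
#' When several overlapping n-grams link to the same concept, only the most
#' representative one — the maximum-similarity candidate within each
#' overlap-connected component — is kept (ties: shorter span, then leftmost,
#' then ascending description id). Non-overlapping repeats of a concept
#' elsewhere in the document all survive.
#'
#' @param candidates Candidate data.frame.
#' @return The pinpointed candidate data.frame.
#' @export
pinpointCandidates <- function(candidates) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- logical(nrow(candidates))
  for (cid in unique(candidates$concept_id)) {
    rows <- which(candidates$concept_id == cid)
    comp <- overlapComponents(candidates$start[rows], candidates$end[rows])
    for (cc in unique(comp)) {
      grp <- rows[comp == cc]
      ord <- order(-candidates$similarity[grp],
                   candidates$end[grp] - candidates$start[grp],
                   candidates$start[grp],
                   candidates$description_id[grp])
      keep[grp[ord[1]]] <- TRUE
    }
  }
  res <- candidates[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Selection step 3: context-collection filter
#'
#' A candidate is dropped when its concept has only negative context samples
#' (blacklist), or when it has both kinds and the highest negative-sample
#' similarity to the candidate's sentence exceeds the highest positive-sample
#' similarity. Concepts with no samples pass through.
#'
#' @param candidates Candidate data.frame.
#' @param collections A [ContextCollection-class].
#' @param text The document (for sentence contexts).
#' @param provider An [EmbeddingProvider-class].
#' @return The filtered candidate data.frame.
#' @export
contextFilter <- function(candidates, collections, text, provider) {
  if (nrow(candidates) == 0L) return(candidates)
  keep <- logical(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    cid <- candidates$concept_id[i]
    pos <- positiveSamples(collections, cid)
    neg <- negativeSamples(collections, cid)
    if (length(pos) == 0L && length(neg) == 0L) { keep[i] <- TRUE; next }
    if (length(pos) == 0L) next                       # only negative: drop
    if (length(neg) == 0L) { keep[i] <- TRUE; next }
    ctx <- containingSentence(text, candidates$start[i], candidates$end[i])
    ctxVec <- embedTexts(ctx, provider)[1, ]
    maxPos <- max(as.numeric(embedTexts(pos, provider) %*% ctxVec))
    maxNeg <- max(as.numeric(embedTexts(neg, provider) %*% ctxVec))
    keep[i] <- maxNeg <= maxPos
  }
  res <- candidates[keep, , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Selection step 4: nesting minimization
#'
#' For every candidate whose span lies strictly inside another candidate's
#' span, the outer n-gram is re-scored against its matched description with
#' the inner text removed. A drop in similarity means the inner text was
#' semantically nested information already carried by the outer link, so the
#' inner candidate is dismissed; an increase (or no change) means the inner
#' link carries new information and both are kept.
#'
#' @param candidates Candidate data.frame (post steps 1-3).
#' @param provider An [EmbeddingProvider-class].
#' @param index The embedded [TerminologyIndex-class].
#' @return data.frame of entity links with a `provenance` column.
#' @export
minimizeNesting <- function(candidates, provider, index) {
  n <- nrow(candidates)
  if (n == 0L) {
    candidates$provenance <- character(0)
    return(candidates)
  }
  dismissed <- logical(n)
  for (i in seq_len(n)) {       # i: inner
    if (dismissed[i]) next
    for (o in seq_len(n)) {     # o: outer
      if (o == i || dismissed[o]) next
      strictly <- candidates$start[o] <= candidates$start[i] &&
        candidates$end[i] <= candidates$end[o] &&
        (candidates$start[o] < candidates$start[i] ||
         candidates$end[i] < candidates$end[o])
      if (!strictly) next
      rs <- candidates$start[i] - candidates$start[o]
      re <- candidates$end[i] - candidates$start[o]
      outerText <- candidates$text[o]
      reduced <- squeezeWhitespace(paste(substr(outerText, 1L, rs),
                                         substring(outerText, re + 1L)))
      descRow <- match(candidates$description_id[o],
                       index@descriptions$description_id)
      newSim <- if (!nzchar(reduced)) -Inf else
        sum(embedTexts(reduced, provider)[1, ] * index@embeddings[descRow, ])
      if (newSim < candidates$similarity[o]) {
        dismissed[i] <- TRUE
        break
      }
    }
  }
  res <- candidates[!dismissed, , drop = FALSE]
  res$provenance <- "threshold+pinpoint+context+nesting"
  rownames(res) <- NULL
  res
}

#' Online-learning update of context collections
#'
#' After a document has been linked, gold-linked concepts gain the sentence
#' surrounding their mention as a positive sample, and every pipeline link
#' absent from the gold set gains its sentence as a negative sample for its
#' concept. Call this only after the document's own linking has completed.
#'
#' @param links Pipeline links for the document (`start`, `end`,
#'   `concept_id`).
#' @param gold Gold annotations for the same document, same coordinate
#'   system (`start`, `end`, `concept_id`).
#' @param collections A [ContextCollection-class].
#' @param text The document.
#' @return The updated [ContextCollection-class].
#' @export
updateCollections <- function(links, gold, collections, text) {
  n <- nchar(text)
  if (nrow(gold) > 0L && (any(gold$start < 0L) || any(gold$end > n)))
    stop("input error: gold span outside document")
  for (i in seq_len(nrow(gold))) {
    ctx <- containingSentence(text, gold$start[i], gold$end[i])
    collections <- addPositiveSample(collections, gold$concept_id[i], ctx)
  }
  goldKey <- paste(gold$start, gold$end, gold$concept_id)
  for (i in seq_len(nrow(links))) {
    key <- paste(links$start[i], links$end[i], links$concept_id[i])
    if (!key %in% goldKey) {
      ctx <- containingSentence(text, links$start[i], links$end[i])
      collections <- addNegativeSample(collections, links$concept_id[i], ctx)
    }
  }
  collections
}

#' Link one document end to end
#'
#' Composes candidate identification with the four selection steps and
#' reports spans in original-document coordinates. Deterministic for fixed
#' inputs.
#'
#' @inheritParams identifyCandidates
#' @param collections A [ContextCollection-class] (empty by default).
#' @return data.frame of entity links: `start`, `end`, `text`, `concept_id`,
#'   `description_id`, `similarity`, `provenance`.
#' @export
linkDocument <- function(text, index, dictionary = NULL,
                         collections = contextCollection(), provider,
                         config = linkerConfig(),
                         withAbbrev = !is.null(dictionary)) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("[", name, "] ", conditionMessage(e), call. = FALSE))
  }
  cand <- stage("identify", identifyCandidates(text, index, dictionary,
                                               provider, config, withAbbrev))
  cand <- stage("threshold", thresholdFilter(cand, config@selectionThreshold))
  cand <- stage("pinpoint", pinpointCandidates(cand))
  cand <- stage("context", contextFilter(cand, collections, text, provider))
  stage("nesting", minimizeNesting(cand, provider, index))
}
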