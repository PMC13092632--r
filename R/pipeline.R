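# Pipeline orchestration: batch wrappers over the four stages (abbreviation
# disambiguation, optional translation hook, entity linking, classification),
# threshold-sweep evaluation, and provenance stamping of every artifact.

#' Pipeline configuration
#'
#' Extends [LinkerConfig-class] with the pipeline-level knobs: the context
#' sample budget per abbreviation sense, the random seed, the embedding
#' provider name, and the external translation command (empty = identity
#' hook).
#'
#' @slot contextSamplesPerSense Context samples collected per expansion
#'   (default 30).
#' @slot seed Random seed (default 2026).
#' @slot providerName Embedding provider configuration name (default
#'   `"hashing-256"`).
#' @slot translationCommand External translation command, or empty for the
#'   identity hook.
#' @export
setClass("PipelineConfig", contains = "LinkerConfig",
         representation(contextSamplesPerSense = "integer", seed = "integer",
                        providerName = "character",
                        translationCommand = "character"))

#' Construct a pipeline configuration
#'
#' Defaults follow the method's standard operating point: abbreviation gate
#' 0.3, selection threshold 0.95, top-10 candidates, n-grams of 1-30 tokens,
#' 30 context samples per sense, seed 2026.
#'
#' @inheritParams linkerConfig
#' @param contextSamplesPerSense,seed,providerName,translationCommand See
#'   [PipelineConfig-class].
#' @return A [PipelineConfig-class].
#' @export
pipelineConfig <- function(abbrevGate = 0.3, selectionThreshold = 0.95,
                           topK = 10L, maxNgramLen = 30L,
                           prohibitedInfixes = c(". ", "- "),
                           contextSamplesPerSense = 30L, seed = 2026L,
                           providerName = "hashing-256",
                           translationCommand = character(0)) {
  new("PipelineConfig", maxNgramLen = as.integer(maxNgramLen),
      topK = as.integer(topK), selectionThreshold = selectionThreshold,
      prohibitedInfixes = prohibitedInfixes, abbrevGate = abbrevGate,
      contextSamplesPerSense = as.integer(contextSamplesPerSense),
      seed = as.integer(seed), providerName = providerName,
      translationCommand = translationCommand)
}

configAsList <- function(config) {
  out <- list()
  for (nm in slotNames(class(config)))
    out[[nm]] <- slot(config, nm)
  out
}

stampProvenance <- function(x, config) {
  attr(x, "provenance") <- list(
    config = configAsList(config),
    package = "clinlink",
    version = as.character(utils::packageVersion("clinlink")))
  x
}

#' Retrieve the provenance record of a pipeline result
#'
#' @param x A result returned by [runDisambiguate()], [runLink()] or
#'   [runClassify()].
#' @return The provenance list (resolved config, package version).
#' @export
provenanceOf <- function(x) attr(x, "provenance")

#' Stage 1 batch wrapper: disambiguate abbreviations in a corpus
#'
#' @param docs Named character vector of documents.
#' @param dictionary An [AbbreviationDictionary-class] (with context
#'   samples).
#' @param provider An [EmbeddingProvider-class]; resolved from the config
#'   when `NULL`.
#' @param config A [PipelineConfig-class].
#' @return List with `texts` (expanded documents), `maps` (offset maps) and
#'   `matches` (one data.frame with a `doc_id` column); carries provenance.
#' @export
runDisambiguate <- function(docs, dictionary, provider = NULL,
                            config = pipelineConfig()) {
  if (is.null(provider)) provider <- resolveProvider(config@providerName)
  if (is.null(names(docs))) names(docs) <- sprintf("doc%03d", seq_along(docs))
  texts <- character(0); maps <- list(); matches <- list()
  for (id in names(docs)) {
    res <- expandAbbreviations(docs[[id]], dictionary, provider,
                               minSimilarity = config@abbrevGate)
    texts[id] <- res$text
    maps[[id]] <- res$map
    if (nrow(res$matches) > 0L)
      matches[[id]] <- cbind(doc_id = id, res$matches)
    message(sprintf("[disambiguate] %s: %d match(es)", id,
                    nrow(res$matches)))
  }
  matchTab <- if (length(matches)) do.call(rbind, matches) else
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               abbreviation = character(0), expansion = character(0),
               score = numeric(0), stringsAsFactors = FALSE)
  rownames(matchTab) <- NULL
  stampProvenance(list(texts = texts, maps = maps, matches = matchTab),
                  config)
}

#' Translation hook (identity by default)
#'
#' When a command is configured, each document is split into chunks at
#' sentence boundaries under a character budget, each chunk is piped through
#' the external command, and the outputs are reassembled. No quality claims
#' are made for any external command; the default is the identity.
#'
#' @param docs Named character vector.
#' @param command External shell command reading a chunk on stdin and
#'   writing the translation to stdout, or `NULL`/empty for identity.
#' @param maxChars Chunk budget in characters (default 2000).
#' @return Named character vector of (possibly translated) documents.
#' @export
translateDocs <- function(docs, command = NULL, maxChars = 2000L) {
  if (is.null(command) || length(command) == 0L || !nzchar(command[1]))
    return(docs)
  vapply(docs, function(doc) {
    sents <- splitSentences(doc)$text
    if (length(sents) == 0L) sents <- doc
    chunks <- character(0); cur <- ""
    for (s in sents) {
      if (nzchar(cur) && nchar(cur) + nchar(s) + 1L > maxChars) {
        chunks <- c(chunks, cur); cur <- s
      } else cur <- if (nzchar(cur)) paste(cur, s) else s
    }
    chunks <- c(chunks, cur)
    out <- vapply(chunks, function(ch)
      paste(system(command, intern = TRUE, input = ch), collapse = " "),
      character(1))
    paste(out, collapse = " ")
  }, character(1))
}

#' Stage 3 batch wrapper: link a corpus, optionally sweeping thresholds
#'
#' Candidates are identified once per document; the four selection steps are
#' re-run for every requested threshold. When gold annotations are supplied,
#' micro-averaged precision/recall/F1 are reported per threshold and the
#' context collections are updated in online-learning fashion (after each
#' document's own linking, at the configured threshold).
#'
#' @param docs Named character vector of documents.
#' @param index An embedded [TerminologyIndex-class].
#' @param dictionary Optional [AbbreviationDictionary-class].
#' @param collections A [ContextCollection-class].
#' @param provider An [EmbeddingProvider-class]; resolved from the config
#'   when `NULL`.
#' @param config A [PipelineConfig-class].
#' @param withAbbrev Run abbreviation disambiguation first.
#' @param gold Optional gold data.frame (`doc_id`, `start`, `end`,
#'   `concept_id`).
#' @param thresholds Optional numeric vector for a sweep (e.g.
#'   `seq(0.90, 0.99, 0.01)`); `NULL` uses the configured threshold only.
#' @return List with `links` (data.frame incl. `doc_id`, at the configured
#'   threshold), `metrics` (one row per threshold, or `NULL` without gold)
#'   and `collections` (updated when gold was given); carries provenance.
#' @export
runLink <- function(docs, index, dictionary = NULL,
                    collections = contextCollection(), provider = NULL,
                    config = pipelineConfig(),
                    withAbbrev = !is.null(dictionary), gold = NULL,
                    thresholds = NULL) {
  if (nrow(index@embeddings) == 0L)
    stop("state error: terminology index has no embeddings")
  if (is.null(provider)) provider <- resolveProvider(config@providerName)
  if (is.null(names(docs))) names(docs) <- sprintf("doc%03d", seq_along(docs))
  ts <- if (is.null(thresholds)) config@selectionThreshold else thresholds

  select <- function(cand, t, text, coll) {
    cand <- thresholdFilter(cand, t)
    cand <- pinpointCandidates(cand)
    cand <- contextFilter(cand, coll, text, provider)
    minimizeNesting(cand, provider, index)
  }

  linksPerT <- stats::setNames(vector("list", length(ts)), as.character(ts))
  for (id in names(docs)) {
    cand <- identifyCandidates(docs[[id]], index, dictionary, provider,
                               config, withAbbrev)
    for (t in ts) {
      lk <- select(cand, t, docs[[id]], collections)
      if (nrow(lk) > 0L) lk <- cbind(doc_id = id, lk)
      linksPerT[[as.character(t)]] <-
        rbind(linksPerT[[as.character(t)]], lk)
    }
    if (!is.null(gold)) {
      atConf <- select(cand, config@selectionThreshold, docs[[id]],
                       collections)
      collections <- updateCollections(
        atConf, gold[gold$doc_id == id, , drop = FALSE], collections,
        docs[[id]])
    }
    message(sprintf("[link] %s processed", id))
  }

  metrics <- NULL
  if (!is.null(gold)) {
    metrics <- do.call(rbind, lapply(ts, function(t) {
      lk <- linksPerT[[as.character(t)]]
      if (is.null(lk)) lk <- data.frame(doc_id = character(0),
                                        start = integer(0), end = integer(0),
                                        concept_id = character(0))
      sc <- scoreLinks(lk, gold)
      data.frame(threshold = t, tp = sc$counts["tp"], fp = sc$counts["fp"],
                 fn = sc$counts["fn"], precision = sc$precision,
                 recall = sc$recall, f1 = sc$f1, row.names = NULL)
    }))
  }
  links <- linksPerT[[as.character(config@selectionThreshold)]]
  if (is.null(links))
    links <- linksPerT[[length(linksPerT)]]
  stampProvenance(list(links = links, metrics = metrics,
                       collections = collections), config)
}

#' Stage 4 batch wrapper: classify a cohort under one or more feature modes
#'
#' Wraps [crossValidate()] so that the EHR-only, concepts-only and combined
#' feature modes can be compared in a single invocation.
#'
#' @param cohort List with `concepts`, `ehr`, `labels` (as produced by
#'   [makeCohort()] or [readCohortCSV()]).
#' @param index A [TerminologyIndex-class] (for ancestor expansion) or
#'   `NULL`.
#' @param config A [PipelineConfig-class]; its seed drives the fold split.
#' @param featureModes Modes to evaluate.
#' @param folds Number of folds (default 5).
#' @return List with `comparison` (one row per mode: precision, recall, f1,
#'   macro_f1) and `results` (full [crossValidate()] output per mode);
#'   carries provenance.
#' @export
runClassify <- function(cohort, index = NULL, config = pipelineConfig(),
                        featureModes = c("ehr_only", "concepts_only",
                                         "combined"),
                        folds = 5L) {
  results <- list()
  rows <- list()
  for (mode in featureModes) {
    cv <- crossValidate(cohort$concepts, cohort$ehr, cohort$labels, index,
                        featureMode = mode, folds = folds,
                        seed = config@seed)
    results[[mode]] <- cv
    rows[[mode]] <- data.frame(mode = mode, precision = cv$precision,
                               recall = cv$recall, f1 = cv$f1,
                               macro_f1 = cv$macro_f1)
    message(sprintf("[classify] %s: F1 = %s", mode, formatPercent(cv$f1)))
  }
  comparison <- do.call(rbind, rows)
  rownames(comparison) <- NULL
  stampProvenance(list(comparison = comparison, results = results), config)
}
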