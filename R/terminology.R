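# Terminology store: concepts, descriptions, is-a hierarchy with memoized
# ancestor closure, and an embedded description index for top-k retrieval.
# Readers ingest SNOMED-CT RF2 snapshot tables and UMLS RRF tables; the
# same container also backs the small fixture dialect used in tests.

RF2_ISA <- "116680003"          # the "is a" relationship type
RF2_FSN <- "900000000000003001" # fully specified name description type

#' Terminology index
#'
#' Queryable store over a clinical terminology: uniquely identified concepts
#' with an acyclic is-a hierarchy, descriptions (synonyms and names, possibly
#' shared between concepts — then the description is ambiguous), and, once
#' built, a matrix of description embeddings for similarity retrieval.
#'
#' @slot concepts data.frame with columns `concept_id`, `preferred_name`,
#'   `category` (one row per active concept).
#' @slot parents Named list: concept_id -> character vector of is-a parents.
#' @slot descriptions data.frame with columns `description_id`, `text`.
#' @slot descConcepts Named list: description_id -> character vector of the
#'   concept ids that share this description text.
#' @slot embeddings Numeric matrix of unit description vectors (0 rows until
#'   [buildDescriptionIndex()] is called); rownames are description ids.
#' @slot provider The [EmbeddingProvider-class] used, or `NULL`.
#' @slot cache Environment memoizing ancestor closures.
#' @export
setClass("TerminologyIndex",
         representation(concepts = "data.frame", parents = "list",
                        descriptions = "data.frame", descConcepts = "list",
                        embeddings = "matrix", provider = "ANY",
                        cache = "environment"))

setValidity("TerminologyIndex", function(object) {
  cids <- object@concepts$concept_id
  if (anyDuplicated(cids)) return("duplicate concept ids")
  if (!setequal(names(object@parents), cids))
    return("'parents' must have exactly one entry per concept")
  for (id in names(object@parents)) {
    p <- object@parents[[id]]
    if (id %in% p) return(paste0("concept ", id, " is its own parent"))
    if (!all(p %in% cids))
      return(paste0("dangling parent reference for concept ", id))
  }
  if (isCyclic(object@parents)) return("is-a graph contains a cycle")
  dids <- object@descriptions$description_id
  if (anyDuplicated(dids)) return("duplicate description ids")
  if (!setequal(names(object@descConcepts), dids))
    return("'descConcepts' must have exactly one entry per description")
  ref <- unique(unlist(object@descConcepts, use.names = FALSE))
  if (length(ref) && !all(ref %in% cids))
    return("description references unknown concept ids")
  if (nrow(object@embeddings) > 0L &&
      nrow(object@embeddings) != nrow(object@descriptions))
    return("embedding row count must equal description count")
  TRUE
})

# DFS cycle check over the child -> parents adjacency list.
isCyclic <- function(parents) {
  state <- new.env(parent = emptyenv()) # 1 = in stack, 2 = done
  visit <- function(id) {
    st <- mget(id, envir = state, ifnotfound = 0L)[[1]]
    if (st == 1L) return(TRUE)
    if (st == 2L) return(FALSE)
    assign(id, 1L, envir = state)
    for (p in parents[[id]]) if (visit(p)) return(TRUE)
    assign(id, 2L, envir = state)
    FALSE
  }
  for (id in names(parents)) if (visit(id)) return(TRUE)
  FALSE
}

setMethod("show", "TerminologyIndex", function(object) {
  cat("TerminologyIndex with", nrow(object@concepts), "concepts and",
      nrow(object@descriptions), "descriptions\n")
  cat("  embedded:",
      if (nrow(object@embeddings) > 0L)
        paste0("yes (", object@provider@name, ")") else "no", "\n")
})

#' @describeIn TerminologyIndex Concept table accessor.
#' @param index A `TerminologyIndex`.
#' @export
conceptTable <- function(index) index@concepts

#' @describeIn TerminologyIndex Description table accessor (with a
#'   `concept_ids` list-column).
#' @export
descriptionTable <- function(index) {
  d <- index@descriptions
  d$concept_ids <- unname(index@descConcepts[d$description_id])
  d
}

#' @describeIn TerminologyIndex Description embedding matrix accessor.
#' @export
descriptionEmbeddings <- function(index) index@embeddings

#' @describeIn TerminologyIndex Number of concepts.
#' @export
nConcepts <- function(index) nrow(index@concepts)

#' Construct a terminology index from tidy tables
#'
#' The general-purpose constructor behind all readers. Description texts are
#' deduplicated case-insensitively per concept, and identical (normalized)
#' texts under several concepts merge into one ambiguous description whose
#' id is the smallest contributing description id.
#'
#' @param concepts data.frame with columns `concept_id`, `preferred_name`,
#'   `category`.
#' @param relationships data.frame with columns `child`, `parent` (is-a
#'   edges), or `NULL` for a flat terminology.
#' @param descriptions data.frame with columns `concept_id`, `text` and
#'   optionally `description_id`.
#' @return A [TerminologyIndex-class].
#' @export
terminologyIndex <- function(concepts, relationships = NULL, descriptions) {
  concepts <- data.frame(concept_id = as.character(concepts$concept_id),
                         preferred_name = as.character(concepts$preferred_name),
                         category = as.character(concepts$category),
                         stringsAsFactors = FALSE)
  parents <- stats::setNames(vector("list", nrow(concepts)), concepts$concept_id)
  parents[] <- list(character(0))
  if (!is.null(relationships) && nrow(relationships) > 0L) {
    for (i in seq_len(nrow(relationships))) {
      ch <- as.character(relationships$child[i])
      pa <- as.character(relationships$parent[i])
      parents[[ch]] <- union(parents[[ch]], pa)
    }
  }
  if (is.null(descriptions$description_id))
    descriptions$description_id <- sprintf("D%06d", seq_len(nrow(descriptions)))
  descriptions$description_id <- as.character(descriptions$description_id)
  descriptions$concept_id <- as.character(descriptions$concept_id)
  descriptions$text <- as.character(descriptions$text)
  # case-insensitive dedup per concept, keep first representative casing
  key <- paste(descriptions$concept_id, tolower(squeezeWhitespace(descriptions$text)))
  descriptions <- descriptions[!duplicated(key), , drop = FALSE]
  # merge identical normalized texts across concepts into one description
  norm <- tolower(squeezeWhitespace(descriptions$text))
  descTab <- data.frame(description_id = character(0), text = character(0),
                        stringsAsFactors = FALSE)
  descConcepts <- list()
  for (u in unique(norm)) {
    rows <- descriptions[norm == u, , drop = FALSE]
    did <- sort(rows$description_id)[1]
    descTab <- rbind(descTab, data.frame(description_id = did,
                                         text = rows$text[1],
                                         stringsAsFactors = FALSE))
    descConcepts[[did]] <- sort(unique(rows$concept_id))
  }
  new("TerminologyIndex", concepts = concepts, parents = parents,
      descriptions = descTab, descConcepts = descConcepts,
      embeddings = matrix(numeric(0), 0, 0), provider = NULL,
      cache = new.env(parent = emptyenv()))
}

# -- readers -------------------------------------------------------------------

readTsv <- function(file) {
  utils::read.delim(file, sep = "\t", quote = "", colClasses = "character",
                    check.names = FALSE, stringsAsFactors = FALSE)
}

requireColumns <- function(tab, cols, file) {
  missing <- setdiff(cols, names(tab))
  if (length(missing))
    stop("format error: file '", file, "' is missing column(s): ",
         paste(missing, collapse = ", "))
}

#' Load a SNOMED-CT RF2 snapshot
#'
#' Reads the concept, description and relationship snapshot tables
#' (tab-delimited, standard RF2 headers). Only active rows are retained;
#' only "is a" relationships define the hierarchy; the concept category is
#' taken from the semantic tag of the fully specified name, and the
#' preferred name is the FSN with the tag stripped (falling back to the
#' first active description).
#'
#' @param conceptFile,descriptionFile,relationshipFile Paths to the three
#'   snapshot TSVs.
#' @return A [TerminologyIndex-class].
#' @export
loadRF2 <- function(conceptFile, descriptionFile, relationshipFile) {
  con <- readTsv(conceptFile)
  requireColumns(con, c("id", "active"), conceptFile)
  des <- readTsv(descriptionFile)
  requireColumns(des, c("id", "active", "conceptId", "typeId", "term"),
                 descriptionFile)
  rel <- readTsv(relationshipFile)
  requireColumns(rel, c("active", "sourceId", "destinationId", "typeId"),
                 relationshipFile)

  allConceptIds <- con$id
  active <- con[con$active == "1", , drop = FALSE]
  activeIds <- active$id

  dangling <- setdiff(des$conceptId, allConceptIds)
  if (length(dangling))
    stop("format error: descriptions reference unknown concept ids: ",
         paste(sort(unique(dangling)), collapse = ", "))
  relIds <- c(rel$sourceId, rel$destinationId)
  dangling <- setdiff(relIds, allConceptIds)
  if (length(dangling))
    stop("format error: relationships reference unknown concept ids: ",
         paste(sort(unique(dangling)), collapse = ", "))

  des <- des[des$active == "1" & des$conceptId %in% activeIds, , drop = FALSE]
  isa <- rel[rel$active == "1" & rel$typeId == RF2_ISA &
             rel$sourceId %in% activeIds & rel$destinationId %in% activeIds,
             , drop = FALSE]

  fsn <- des[des$typeId == RF2_FSN, , drop = FALSE]
  prefName <- character(length(activeIds)); category <- character(length(activeIds))
  names(prefName) <- names(category) <- activeIds
  for (cid in activeIds) {
    f <- fsn$term[fsn$conceptId == cid]
    if (length(f)) {
      tag <- regmatches(f[1], regexpr("\\(([^()]*)\\)\\s*$", f[1]))
      category[cid] <- if (length(tag)) gsub("[()]|\\s+$", "", tag) else ""
      prefName[cid] <- trimws(sub("\\s*\\([^()]*\\)\\s*$", "", f[1]))
    } else {
      d <- des$term[des$conceptId == cid]
      prefName[cid] <- if (length(d)) d[1] else cid
      category[cid] <- ""
    }
  }
  concepts <- data.frame(concept_id = activeIds, preferred_name = prefName,
                         category = category, stringsAsFactors = FALSE)
  relationships <- if (nrow(isa))
    data.frame(child = isa$sourceId, parent = isa$destinationId,
               stringsAsFactors = FALSE) else NULL
  descriptions <- data.frame(description_id = des$id, concept_id = des$conceptId,
                             text = des$term, stringsAsFactors = FALSE)
  terminologyIndex(concepts, relationships, descriptions)
}

#' Load UMLS RRF concept-name and semantic-type tables
#'
#' Reads pipe-delimited MRCONSO/MRSTY-layout files (standard column order, no
#' header). Every non-suppressed name becomes a description; identical names
#' under several CUIs become one ambiguous description. UMLS carries no is-a
#' edges here, so every concept gets an empty ancestor set.
#'
#' @param consoFile Path to an MRCONSO-layout file (18 pipe-delimited columns;
#'   CUI in column 1, string in column 15, suppress flag in column 17).
#' @param semanticTypeFile Path to an MRSTY-layout file (CUI in column 1,
#'   semantic type name in column 4), or `NULL`.
#' @return A [TerminologyIndex-class].
#' @export
loadRRF <- function(consoFile, semanticTypeFile = NULL) {
  lines <- readLines(consoFile, warn = FALSE)
  if (length(lines) == 0L) stop("format error: '", consoFile, "' is empty")
  parts <- strsplit(lines, "|", fixed = TRUE)
  ncols <- vapply(parts, length, integer(1))
  if (any(ncols < 17L))
    stop("format error: file '", consoFile,
         "' is missing column(s): expected >= 17 pipe-delimited fields")
  cui <- vapply(parts, `[`, character(1), 1L)
  ispref <- vapply(parts, `[`, character(1), 7L)
  str <- vapply(parts, `[`, character(1), 15L)
  suppress <- vapply(parts, `[`, character(1), 17L)
  keep <- suppress %in% c("N", "")
  cui <- cui[keep]; ispref <- ispref[keep]; str <- str[keep]

  sty <- list()
  if (!is.null(semanticTypeFile)) {
    sl <- readLines(semanticTypeFile, warn = FALSE)
    sp <- strsplit(sl, "|", fixed = TRUE)
    if (length(sp) && any(vapply(sp, length, integer(1)) < 4L))
      stop("format error: file '", semanticTypeFile,
           "' is missing column(s): expected >= 4 pipe-delimited fields")
    for (row in sp)
      if (is.null(sty[[row[1]]])) sty[[row[1]]] <- row[4]
  }

  cuis <- unique(cui)
  pref <- vapply(cuis, function(id) {
    s <- str[cui == id]; p <- ispref[cui == id]
    if (any(p == "Y")) s[p == "Y"][1] else s[1]
  }, character(1))
  cat2 <- vapply(cuis, function(id)
    if (!is.null(sty[[id]])) sty[[id]] else "", character(1))
  concepts <- data.frame(concept_id = cuis, preferred_name = unname(pref),
                         category = unname(cat2), stringsAsFactors = FALSE)
  descriptions <- data.frame(concept_id = cui, text = str,
                             stringsAsFactors = FALSE)
  terminologyIndex(concepts, NULL, descriptions)
}

# -- queries -------------------------------------------------------------------

#' Ancestor closure of a concept
#'
#' Transitive closure over is-a edges, excluding the concept itself.
#' Memoized per index.
#'
#' @param index A [TerminologyIndex-class].
#' @param conceptId Concept identifier.
#' @return Character vector of ancestor concept ids (sorted).
#' @export
conceptAncestors <- function(index, conceptId) {
  if (!conceptId %in% index@concepts$concept_id)
    stop("lookup error: unknown concept id '", conceptId, "'")
  memo <- index@cache
  rec <- function(id) {
    hit <- mget(id, envir = memo, ifnotfound = list(NULL))[[1]]
    if (!is.null(hit)) return(hit)
    ps <- index@parents[[id]]
    anc <- ps
    for (p in ps) anc <- union(anc, rec(p))
    anc <- sort(anc)
    assign(id, anc, envir = memo)
    anc
  }
  rec(conceptId)
}

#' Find ambiguous descriptions
#'
#' Descriptions whose identical text is shared by two or more concepts.
#'
#' @param index A [TerminologyIndex-class].
#' @return data.frame with columns `description_id`, `text`, `concept_ids`
#'   (list-column); zero rows when no description is shared.
#' @export
findAmbiguousDescriptions <- function(index) {
  d <- descriptionTable(index)
  d[lengths(d$concept_ids) >= 2L, , drop = FALSE]
}

#' Embed all description texts into the index
#'
#' Embeds every description with the given provider (repeated calls hit the
#' provider cache and reproduce the identical matrix).
#'
#' @param index A [TerminologyIndex-class].
#' @param provider An [EmbeddingProvider-class].
#' @return The index with its `embeddings` slot populated.
#' @export
buildDescriptionIndex <- function(index, provider) {
  if (nrow(index@descriptions) == 0L)
    stop("state error: terminology has no descriptions to embed")
  emb <- tryCatch(embedTexts(index@descriptions$text, provider),
                  error = function(e)
                    stop("embedding descriptions failed: ", conditionMessage(e)))
  rownames(emb) <- index@descriptions$description_id
  index@embeddings <- emb
  index@provider <- provider
  index
}

#' Top-k most similar descriptions for a query text
#'
#' @param index An embedded [TerminologyIndex-class].
#' @param query Query text (embedded with the index provider) or a numeric
#'   unit vector.
#' @param k Number of hits.
#' @return data.frame with columns `description_id`, `score`, `text` and
#'   `concept_ids` (list-column), sorted by non-increasing score with ties
#'   broken by ascending description id.
#' @export
topKDescriptions <- function(index, query, k = 10L) {
  if (nrow(index@embeddings) == 0L)
    stop("state error: call buildDescriptionIndex() first")
  if (is.character(query))
    query <- as.numeric(embedTexts(query, index@provider)[1, ])
  hits <- topKHits(index@embeddings, query, k)
  pos <- match(hits$description_id, index@descriptions$description_id)
  hits$text <- index@descriptions$text[pos]
  hits$concept_ids <- unname(index@descConcepts[hits$description_id])
  hits
}

# -- fixture round-trip --------------------------------------------------------

#' Write an index back out in the RF2 snapshot dialect
#'
#' Emits minimal concept/description/relationship snapshot tables that
#' [loadRF2()] reads back into an equal index. Used by the fixture
#' generators and the round-trip tests.
#'
#' @param index A [TerminologyIndex-class].
#' @param dir Output directory (created if needed).
#' @return Named character vector of the three file paths.
#' @export
writeRF2Fixture <- function(index, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cids <- index@concepts$concept_id
  conceptTab <- data.frame(id = cids, effectiveTime = "20230531", active = "1",
                           moduleId = "0", definitionStatusId = "0",
                           stringsAsFactors = FALSE)
  descRows <- list(); n <- 0L
  for (i in seq_len(nrow(index@concepts))) {
    n <- n + 1L
    descRows[[n]] <- data.frame(
      id = sprintf("F%06d", n), effectiveTime = "20230531", active = "1",
      moduleId = "0", conceptId = cids[i], languageCode = "en",
      typeId = RF2_FSN,
      term = paste0(index@concepts$preferred_name[i], " (",
                    ifelse(nzchar(index@concepts$category[i]),
                           index@concepts$category[i], "finding"), ")"),
      caseSignificanceId = "0", stringsAsFactors = FALSE)
  }
  d <- descriptionTable(index)
  for (i in seq_len(nrow(d))) {
    for (cid in d$concept_ids[[i]]) {
      n <- n + 1L
      descRows[[n]] <- data.frame(
        id = sprintf("S%06d", n), effectiveTime = "20230531", active = "1",
        moduleId = "0", conceptId = cid, languageCode = "en",
        typeId = "900000000000013009", term = d$text[i],
        caseSignificanceId = "0", stringsAsFactors = FALSE)
    }
  }
  descTab <- do.call(rbind, descRows)
  relRows <- list(); n <- 0L
  for (id in names(index@parents)) {
    for (p in index@parents[[id]]) {
      n <- n + 1L
      relRows[[n]] <- data.frame(
        id = sprintf("R%06d", n), effectiveTime = "20230531", active = "1",
        moduleId = "0", sourceId = id, destinationId = p,
        relationshipGroup = "0", typeId = RF2_ISA,
        characteristicTypeId = "0", modifierId = "0", stringsAsFactors = FALSE)
    }
  }
  relTab <- if (n > 0L) do.call(rbind, relRows) else
    data.frame(id = character(0), effectiveTime = character(0),
               active = character(0), moduleId = character(0),
               sourceId = character(0), destinationId = character(0),
               relationshipGroup = character(0), typeId = character(0),
               characteristicTypeId = character(0), modifierId = character(0),
               stringsAsFactors = FALSE)
  paths <- c(concept = file.path(dir, "sct2_Concept_Snapshot.txt"),
             description = file.path(dir, "sct2_Description_Snapshot.txt"),
             relationship = file.path(dir, "sct2_Relationship_Snapshot.txt"))
  utils::write.table(conceptTab, paths["concept"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(descTab, paths["description"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(relTab, paths["relationship"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths
}
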