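# Seeded synthetic-fixture generators. They emulate, with planted ground
# truth, every input the method is normally run on: an is-a terminology with
# synonyms and ambiguous descriptions (SNOMED-CT RF2 dialect), abbreviation
# dictionaries with context corpora and gold-labeled snippets, annotated
# documents with standoff entity links (including nested mentions), and a
# class-conditional four-class patient cohort with EHR features.
#
# Every generator is a pure function of (spec, seed): each draws from its own
# pseudo-random stream seeded by (master seed, generator name), so adding or
# rerunning one generator never shifts another.

# Mix a master seed with a generator name into an independent 31-bit seed.
generatorSeed <- function(seed, name) {
  h <- 0
  for (cp in utf8ToInt(name)) h <- (h * 31 + cp) %% 1048573
  as.integer((as.numeric(seed) * 2654435 + h) %% 2147483647)
}

wordPool <- function() {
  pre <- c("cardio", "nephro", "hepato", "dermato", "gastro", "pulmo",
           "angio", "osteo", "neuro", "hemato", "broncho", "arthro",
           "cysto", "entero", "phlebo", "myelo", "rhino", "thoraco",
           "spleno", "adeno", "chondro", "fibro", "lipo", "masto")
  suf <- c("pathy", "sclerosis", "stenosis", "megaly", "plasty", "ectomy",
           "graphy", "trophy", "lysis", "ptosis", "genesis", "rrhaphy")
  as.vector(outer(pre, suf, paste0))
}

fillerPool <- function() {
  c("meanwhile", "reported", "observed", "yesterday", "routine", "general",
    "without", "complaint", "remained", "overnight", "tolerated", "examined",
    "discussed", "monitored", "afterwards", "gradually", "improving",
    "consistent", "unremarkable", "throughout", "otherwise", "currently",
    "substantially", "presenting", "documented", "following")
}

discriminativePool <- function() {
  pre <- c("zam", "bor", "fen", "tul", "rik", "vos", "mun", "gax", "pel",
           "dor", "quil", "sarn", "teb", "wix", "yol")
  suf <- c("arine", "ovious", "ethal", "union", "ictive")
  as.vector(outer(pre, suf, paste0))
}

#' Default fixture specification
#'
#' Bundles the knobs of all four generators. Identical spec and seed yield
#' byte-identical fixtures.
#'
#' @param seed Master seed (default 2026).
#' @param n_concepts Number of base concepts in the toy terminology.
#' @param hierarchy_depth Maximum is-a depth.
#' @param synonyms_per_concept Synonym descriptions per concept (besides the
#'   fully specified name).
#' @param ambiguity_rate Fraction of synonym descriptions additionally
#'   attached to a second concept.
#' @param n_composites Number of "history of X" companion concepts used to
#'   plant nested mentions.
#' @param n_abbrevs,senses_per_abbrev,snippets_per_abbrev,samples_per_sense
#'   Abbreviation-corpus shape.
#' @param n_docs,mentions_per_doc,nesting_rate Annotated-document shape.
#' @param n_patients,markers_per_class,signal,ehr_signal Cohort shape: number
#'   of patients, exclusive marker concepts per class, probability that a
#'   given own-class marker appears in a patient's note, and the multiplier
#'   on the class-conditional EHR feature shifts.
#' @return A list of class `fixtureSpec`.
#' @export
fixtureSpec <- function(seed = 2026L, n_concepts = 30L, hierarchy_depth = 3L,
                        synonyms_per_concept = 2L, ambiguity_rate = 0.2,
                        n_composites = 5L, n_abbrevs = 8L,
                        senses_per_abbrev = 2L, snippets_per_abbrev = 5L,
                        samples_per_sense = 8L, n_docs = 20L,
                        mentions_per_doc = 3L, nesting_rate = 0.25,
                        n_patients = 200L, markers_per_class = 5L,
                        signal = 0.9, ehr_signal = 1) {
  structure(as.list(environment()), class = "fixtureSpec")
}

#' Generate a toy terminology in the RF2 snapshot dialect
#'
#' Emits concept/description/relationship snapshot TSVs (read back with
#' [loadRF2()]) plus truth tables: the planted ancestor sets, the planted
#' ambiguous description texts, and the plantable mention texts used by
#' [makeAnnotatedDocs()] (unambiguous synonyms, plus composite "history of X"
#' texts that contain another concept's synonym verbatim for nesting tests).
#'
#' @param spec A [fixtureSpec()].
#' @param dir Output directory for the RF2-dialect files.
#' @return List with `files` (paths), `index` (the loaded
#'   [TerminologyIndex-class]) and `truth` (list: `ancestors`, `ambiguous`,
#'   `plantable`).
#' @export
makeTerminology <- function(spec = fixtureSpec(), dir = tempfile("term")) {
  if (spec$ambiguity_rate > 0 && spec$n_concepts < 2L)
    stop("spec error: ambiguity requires at least two concepts")
  set.seed(generatorSeed(spec$seed, "terminology"))
  nBase <- spec$n_concepts
  nWords <- nBase * (1L + spec$synonyms_per_concept) * 2L
  pool <- sample(wordPool())
  if (nWords > length(pool))
    stop("spec error: not enough distinct words for ", nBase, " concepts")
  words <- pool[seq_len(nWords)]
  nameOf <- function(k) paste(words[2L * k - 1L], words[2L * k])

  ids <- as.character(seq(100001L, by = 13L, length.out = nBase))
  cats <- sample(c("Clinical finding", "Procedure", "Body structure"),
                 nBase, replace = TRUE)
  depth <- integer(nBase); depth[1] <- 0L
  parentOf <- character(nBase); parentOf[1] <- NA_character_
  for (i in seq_len(nBase)[-1]) {
    eligible <- which(depth[seq_len(i - 1L)] < spec$hierarchy_depth - 1L)
    if (length(eligible) == 0L) eligible <- 1L
    p <- eligible[sample.int(length(eligible), 1L)]
    parentOf[i] <- ids[p]
    depth[i] <- depth[p] + 1L
  }

  k <- 0L
  prefName <- character(nBase)
  synRows <- list(); s <- 0L
  for (i in seq_len(nBase)) {
    k <- k + 1L; prefName[i] <- nameOf(k)
    for (j in seq_len(spec$synonyms_per_concept)) {
      k <- k + 1L; s <- s + 1L
      synRows[[s]] <- data.frame(concept_id = ids[i], text = nameOf(k),
                                 stringsAsFactors = FALSE)
    }
  }
  synTab <- do.call(rbind, synRows)

  # plant ambiguity: attach a fraction of synonyms to a second concept
  nAmb <- floor(spec$ambiguity_rate * nrow(synTab))
  ambiguous <- character(0)
  if (nAmb > 0L) {
    ambRows <- sample.int(nrow(synTab), nAmb)
    extra <- lapply(ambRows, function(r) {
      other <- sample(setdiff(ids, synTab$concept_id[r]), 1L)
      data.frame(concept_id = other, text = synTab$text[r],
                 stringsAsFactors = FALSE)
    })
    synTab <- rbind(synTab, do.call(rbind, extra))
    ambiguous <- sort(synTab$text[ambRows])
  }

  # composite companions for nesting: "history of <base synonym>"
  nComp <- min(spec$n_composites, nBase)
  compIds <- as.character(seq(900001L, by = 7L, length.out = nComp))
  compBase <- sample(seq_len(nBase), nComp)
  compRows <- list()
  plantComposite <- list()
  for (j in seq_len(nComp)) {
    baseSyn <- synRows[[(compBase[j] - 1L) * spec$synonyms_per_concept + 1L]]
    outerText <- paste("history of", baseSyn$text)
    compRows[[j]] <- data.frame(concept_id = compIds[j], text = outerText,
                                stringsAsFactors = FALSE)
    plantComposite[[j]] <- data.frame(
      text = outerText, concept_id = compIds[j], composite = TRUE,
      inner_text = baseSyn$text, inner_concept = baseSyn$concept_id,
      stringsAsFactors = FALSE)
  }

  concepts <- data.frame(
    concept_id = c(ids, compIds),
    preferred_name = c(prefName,
                       vapply(compRows, function(r) r$text, character(1))),
    category = c(cats, rep("Situation", nComp)),
    stringsAsFactors = FALSE)
  relationships <- rbind(
    data.frame(child = ids[-1], parent = parentOf[-1],
               stringsAsFactors = FALSE),
    data.frame(child = compIds, parent = rep(ids[1], nComp),
               stringsAsFactors = FALSE))
  descriptions <- rbind(synTab, do.call(rbind, compRows))

  idx <- terminologyIndex(concepts, relationships, descriptions)
  files <- writeRF2Fixture(idx, dir)
  index <- loadRF2(files["concept"], files["description"],
                   files["relationship"])

  ancTruth <- list()
  for (i in seq_along(c(ids, compIds))) {
    id <- c(ids, compIds)[i]
    anc <- character(0)
    cur <- id
    repeat {
      pos <- match(cur, ids)
      p <- if (!is.na(pos)) parentOf[pos] else ids[1]
      if (is.na(p)) break
      anc <- c(anc, p)
      if (cur %in% compIds && p == ids[1]) { cur <- p; next }
      cur <- p
    }
    ancTruth[[id]] <- sort(unique(anc))
  }

  plantNormal <- synTab[!synTab$text %in% ambiguous &
                        !duplicated(synTab$text), , drop = FALSE]
  plantNormal <- data.frame(text = plantNormal$text,
                            concept_id = plantNormal$concept_id,
                            composite = FALSE, inner_text = NA_character_,
                            inner_concept = NA_character_,
                            stringsAsFactors = FALSE)
  plantable <- rbind(plantNormal, do.call(rbind, plantComposite))

  list(files = files, index = index,
       truth = list(ancestors = ancTruth, ambiguous = ambiguous,
                    plantable = plantable))
}

#' Generate an abbreviation dictionary, context corpus and gold snippets
#'
#' Each abbreviation gets several senses; each sense gets a set of
#' discriminative context words planted both in its corpus sentences and in
#' the gold snippets, so a lexical-overlap embedder can separate senses. One
#' extra abbreviation carries a sense that never occurs in the corpus (and so
#' can never be selected by context).
#'
#' @param spec A [fixtureSpec()].
#' @return List with `dictionary` (no samples yet; enrich with
#'   [collectContextSamples()]), `corpus` (character vector of documents),
#'   `snippets` (data.frame: `text`, `abbreviation`, `start`, `end`,
#'   `gold_expansion`) and `truth` (including the zero-context sense).
#' @export
makeAbbrevCorpus <- function(spec = fixtureSpec()) {
  set.seed(generatorSeed(spec$seed, "abbrev"))
  nA <- spec$n_abbrevs; nS <- spec$senses_per_abbrev
  cons <- setdiff(LETTERS, c("A", "E", "I", "O", "U"))
  abbrevs <- sample(as.vector(outer(cons, cons, paste0)), nA + 1L)
  zeroAbbrev <- abbrevs[nA + 1L]
  abbrevs <- abbrevs[seq_len(nA)]

  dwords <- sample(discriminativePool())
  ewords <- sample(wordPool())
  need <- (nA + 1L) * nS
  if (3L * need > length(dwords) || 2L * need > length(ewords))
    stop("spec error: too many senses for the word pools")

  senses <- list(); d <- 0L; e <- 0L
  for (a in c(abbrevs, zeroAbbrev)) {
    senses[[a]] <- lapply(seq_len(nS), function(j) {
      d <<- d + 3L; e <<- e + 2L
      list(expansion = paste(ewords[e - 1L], ewords[e]),
           dwords = dwords[(d - 2L):d])
    })
  }

  pairs <- do.call(rbind, lapply(names(senses), function(a)
    data.frame(abbreviation = a,
               expansion = vapply(senses[[a]], `[[`, character(1),
                                  "expansion"),
               stringsAsFactors = FALSE)))
  dictionary <- abbreviationDictionary(pairs)

  corpus <- character(0)
  for (a in c(abbrevs, zeroAbbrev)) {
    for (j in seq_len(nS)) {
      if (a == zeroAbbrev && j == nS) next   # the zero-context sense
      sn <- senses[[a]][[j]]
      for (r in seq_len(spec$samples_per_sense))
        corpus <- c(corpus, paste0(sn$dwords[1], " ", sn$dwords[2], " ",
                                   sn$expansion, " noted ", sn$dwords[3],
                                   " case ", r, "."))
    }
  }

  snippets <- list(); n <- 0L
  for (a in abbrevs) {
    for (r in seq_len(spec$snippets_per_abbrev)) {
      j <- ((r - 1L) %% nS) + 1L
      sn <- senses[[a]][[j]]
      prefix <- paste0(sn$dwords[1], " ", sn$dwords[2], " ")
      text <- paste0(prefix, a, " seen with ", sn$dwords[3], ".")
      n <- n + 1L
      snippets[[n]] <- data.frame(
        text = text, abbreviation = a, start = nchar(prefix),
        end = nchar(prefix) + nchar(a), gold_expansion = sn$expansion,
        stringsAsFactors = FALSE)
    }
  }
  list(dictionary = dictionary, corpus = corpus,
       snippets = do.call(rbind, snippets),
       truth = list(senses = senses, zero_context = list(
         abbreviation = zeroAbbrev,
         expansion = senses[[zeroAbbrev]][[nS]]$expansion)))
}

#' Generate annotated documents with standoff gold entity links
#'
#' Mentions are verbatim terminology descriptions embedded in filler
#' sentences; a `nesting_rate` fraction are composite "history of X" texts
#' whose inner synonym is itself a description of another concept (the gold
#' link is the outer concept; the method should dismiss the inner link via
#' nesting minimization). Optionally writes the corpus in the PubTator and
#' pipe-delimited standoff dialects.
#'
#' @param spec A [fixtureSpec()].
#' @param terminology Result of [makeTerminology()].
#' @param pubtatorFile,shareClefFile Optional output paths.
#' @return List with `docs` (named character vector), `gold` (data.frame:
#'   `doc_id`, `start`, `end`, `text`, `concept_id`).
#' @export
makeAnnotatedDocs <- function(spec = fixtureSpec(), terminology,
                              pubtatorFile = NULL, shareClefFile = NULL) {
  set.seed(generatorSeed(spec$seed, "docs"))
  plantable <- terminology$truth$plantable
  normals <- plantable[!plantable$composite, , drop = FALSE]
  composites <- plantable[plantable$composite, , drop = FALSE]
  filler <- fillerPool()
  docs <- character(spec$n_docs)
  names(docs) <- sprintf("doc%03d", seq_len(spec$n_docs))
  gold <- list(); g <- 0L
  for (d in seq_len(spec$n_docs)) {
    sentences <- character(spec$mentions_per_doc)
    offsets <- integer(spec$mentions_per_doc)
    pos <- 0L
    for (m in seq_len(spec$mentions_per_doc)) {
      useComposite <- nrow(composites) > 0L &&
        stats::runif(1) < spec$nesting_rate
      row <- if (useComposite)
        composites[sample.int(nrow(composites), 1L), , drop = FALSE]
      else normals[sample.int(nrow(normals), 1L), , drop = FALSE]
      f <- sample(filler, 3L)
      prefix <- paste0(f[1], " ", f[2], " ")
      sentence <- paste0(prefix, row$text, " ", f[3], ".")
      sentences[m] <- sentence
      mentionStart <- pos + nchar(prefix)
      g <- g + 1L
      gold[[g]] <- data.frame(doc_id = names(docs)[d], start = mentionStart,
                              end = mentionStart + nchar(row$text),
                              text = row$text, concept_id = row$concept_id,
                              stringsAsFactors = FALSE)
      pos <- pos + nchar(sentence) + 1L   # sentences joined by one space
    }
    docs[d] <- paste(sentences, collapse = " ")
  }
  gold <- do.call(rbind, gold)

  if (!is.null(pubtatorFile)) {
    lines <- character(0)
    title <- "Synthetic clinical note"
    shift <- nchar(title) + 1L
    for (id in names(docs)) {
      lines <- c(lines, paste0(id, "|t|", title),
                 paste0(id, "|a|", docs[[id]]))
      rows <- gold[gold$doc_id == id, , drop = FALSE]
      for (r in seq_len(nrow(rows)))
        lines <- c(lines, paste(id, rows$start[r] + shift,
                                rows$end[r] + shift, rows$text[r],
                                "Finding", rows$concept_id[r], sep = "\t"))
      lines <- c(lines, "")
    }
    writeLines(lines, pubtatorFile)
  }
  if (!is.null(shareClefFile)) {
    writeLines(paste0(gold$doc_id, "|", gold$start, "-", gold$end, "|",
                      gold$concept_id), shareClefFile)
  }
  list(docs = docs, gold = gold)
}

#' Generate a class-conditional patient cohort
#'
#' Four diagnosis classes with the cohort mix 41.5/22.8/20.7/15.0%
#' (no heart failure / HFrEF / HFmrEF / HFpEF). Each class owns
#' `markers_per_class` exclusive marker concepts appearing in its patients'
#' concept bags with probability `signal`; all patients share background
#' concepts. EHR features are class-shifted normals (ejection fraction
#' foremost) scaled by `ehr_signal`, with a small missing-value rate and a
#' signal-free categorical feature.
#'
#' @param spec A [fixtureSpec()].
#' @param terminology Result of [makeTerminology()] supplying concept ids.
#' @return List with `concepts` (list of per-patient concept vectors), `ehr`
#'   (data.frame), `labels` (factor over [hfClasses()]) and `truth`
#'   (markers per class).
#' @export
makeCohort <- function(spec = fixtureSpec(), terminology) {
  set.seed(generatorSeed(spec$seed, "cohort"))
  classes <- hfClasses()
  mix <- c(0.415, 0.228, 0.207, 0.150)
  n <- spec$n_patients
  counts <- floor(mix * n)
  rem <- n - sum(counts)
  if (rem > 0L) {
    frac <- mix * n - counts
    counts[order(-frac)[seq_len(rem)]] <-
      counts[order(-frac)[seq_len(rem)]] + 1L
  }
  labels <- factor(rep(classes, counts), levels = classes)
  labels <- labels[sample.int(n)]

  ids <- terminology$index@concepts$concept_id
  need <- 4L * spec$markers_per_class + 10L
  if (length(ids) < need)
    stop("spec error: terminology too small for ", spec$markers_per_class,
         " markers per class")
  picked <- sample(ids, need)
  markers <- split(picked[seq_len(4L * spec$markers_per_class)],
                   rep(classes, each = spec$markers_per_class))
  background <- picked[(4L * spec$markers_per_class + 1L):need]

  efMean <- c(NoHF = 60, HFrEF = 30, HFmrEF = 45, HFpEF = 55)
  bnpMean <- c(NoHF = 50, HFrEF = 800, HFmrEF = 500, HFpEF = 300)
  s <- spec$ehr_signal
  concepts <- vector("list", n)
  age <- numeric(n); bmi <- numeric(n); ef <- numeric(n); bnp <- numeric(n)
  for (i in seq_len(n)) {
    cl <- as.character(labels[i])
    own <- markers[[cl]][stats::runif(spec$markers_per_class) < spec$signal]
    own <- rep(own, times = 1L + (stats::runif(length(own)) < 0.3))
    bg <- sample(background, 3L)
    noise <- if (spec$signal > 0 && stats::runif(1) < 0.05)
      sample(unlist(markers[setdiff(classes, cl)]), 1L) else character(0)
    concepts[[i]] <- unname(sample(c(own, bg, noise)))
    k <- match(cl, classes) - 1L
    age[i] <- stats::rnorm(1, 62 + s * 2 * k, 8)
    bmi[i] <- stats::rnorm(1, 26 + s * 0.8 * k, 3)
    ef[i] <- stats::rnorm(1, 50 + s * (efMean[[cl]] - 50), 5)
    bnp[i] <- stats::rnorm(1, 300 + s * (bnpMean[[cl]] - 300), 100)
  }
  ehr <- data.frame(age = age, bmi = bmi, ef = ef, bnp = bnp,
                    sex = sample(c("M", "F"), n, replace = TRUE),
                    stringsAsFactors = FALSE)
  for (col in c("age", "bmi", "bnp"))
    ehr[[col]][stats::runif(n) < 0.05] <- NA
  list(concepts = concepts, ehr = ehr, labels = labels,
       truth = list(markers = markers, background = background))
}

#' Write and read a cohort as a CSV table
#'
#' One row per patient: `patient_id`, the EHR features, a semicolon-joined
#' `concepts` column and the `label`.
#'
#' @param cohort Result of [makeCohort()].
#' @param file CSV path.
#' @return `writeCohortCSV` invisibly returns `file`; `readCohortCSV`
#'   returns a list shaped like [makeCohort()] output (without `truth`).
#' @export
writeCohortCSV <- function(cohort, file) {
  tab <- cbind(data.frame(patient_id = sprintf("p%04d",
                                               seq_along(cohort$labels))),
               cohort$ehr,
               data.frame(concepts = vapply(cohort$concepts, paste,
                                            character(1), collapse = ";"),
                          label = as.character(cohort$labels)))
  utils::write.csv(tab, file, row.names = FALSE)
  invisible(file)
}

#' @rdname writeCohortCSV
#' @param labelColumn Name of the label column (default `"label"`).
#' @export
readCohortCSV <- function(file, labelColumn = "label") {
  tab <- utils::read.csv(file, stringsAsFactors = FALSE)
  requireColumns(tab, c(labelColumn, "concepts"), file)
  ehr <- tab[, setdiff(names(tab), c("patient_id", "concepts", labelColumn)),
             drop = FALSE]
  list(concepts = strsplit(tab$concepts, ";", fixed = TRUE),
       ehr = ehr,
       labels = factor(tab[[labelColumn]]))
}
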