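# Fixtures for the selection-step tests: small hand-built candidate frames.
candFrame <- function(start, end, text, desc, concept, sim) {
  data.frame(start = start, end = end, text = text, description_id = desc,
             concept_id = concept, similarity = sim, stringsAsFactors = FALSE)
}

embeddedToy <- function() buildDescriptionIndex(makeToyIndex(), testProvider())

test_that("candidate identification drops prohibited infixes and empty input", {
  p <- testProvider()
  idx <- embeddedToy()
  cfg <- linkerConfig(maxNgramLen = 5L, topK = 2L)
  text <- "in the family. Therapy with heart failure"
  cand <- identifyCandidates(text, idx, provider = p, config = cfg)
  expect_false(any(grepl("family. Therapy", cand$text, fixed = TRUE)))
  expect_true(any(cand$text == "heart failure"))
  expect_equal(nrow(identifyCandidates("", idx, provider = p, config = cfg)),
               0L)
  expect_error(identifyCandidates("x", makeToyIndex(), provider = p,
                                  config = cfg), "state error")
})

test_that("n-gram enumeration matches the combinatorial count", {
  p <- testProvider()
  idx <- embeddedToy()
  cfg <- linkerConfig(maxNgramLen = 5L, topK = 1L)
  text <- "one two three four five six seven eight"   # 8 tokens, no infixes
  cand <- identifyCandidates(text, idx, provider = p, config = cfg)
  spans <- unique(paste(cand$start, cand$end))
  expected <- sum(vapply(1:5, function(n) 8L - n + 1L, integer(1)))
  expect_equal(length(spans), expected)

  # brute-force enumerator over token spans agrees span by span
  toks <- tokenizeText(text)
  brute <- character(0)
  for (n in 1:5)
    for (i in seq_len(nrow(toks) - n + 1L))
      brute <- c(brute, paste(toks$start[i], toks$end[i + n - 1L]))
  expect_setequal(spans, brute)
})

test_that("ambiguous description hits fan out to one candidate per concept", {
  p <- testProvider()
  idx <- embeddedToy()
  cfg <- linkerConfig(maxNgramLen = 3L, topK = 3L, selectionThreshold = 0.9)
  cand <- identifyCandidates("pump failure", idx, provider = p, config = cfg)
  exact <- cand[cand$similarity > 1 - 1e-9 & cand$text == "pump failure", ]
  expect_setequal(exact$concept_id, c("3", "4"))
})

test_that("threshold filter keeps the documented example and is monotone", {
  cand <- candFrame(c(0L, 4L), c(11L, 11L), c("The patient", "patient"),
                    c("d1", "d2"), c("116154003", "116154003"),
                    c(0.83, 1.0))
  kept <- thresholdFilter(cand, 0.9)
  expect_equal(kept$text, "patient")
  expect_equal(nrow(thresholdFilter(cand, 0)), 2L)

  set.seed(5)
  rnd <- candFrame(1:50, 2:51, "x", paste0("d", 1:50), paste0("c", 1:50),
                   runif(50))
  for (pair in list(c(0.2, 0.5), c(0.5, 0.9))) {
    lo <- thresholdFilter(rnd, pair[1]); hi <- thresholdFilter(rnd, pair[2])
    expect_true(all(rownames(hi) %in% rownames(lo)) ||
                  all(paste(hi$start, hi$similarity) %in%
                        paste(lo$start, lo$similarity)))
  }
})

test_that("pinpointing keeps the most representative overlapping candidate per concept", {
  # Fig-7-style: "The patient" (0.93) vs "patient" (1.0), same concept
  cand <- candFrame(c(0L, 4L), c(11L, 11L), c("The patient", "patient"),
                    c("d1", "d1"), "116154003", c(0.93, 1.0))
  out <- pinpointCandidates(cand)
  expect_equal(out$text, "patient")

  # disjoint repeats of the same concept all survive
  twice <- candFrame(c(0L, 50L), c(7L, 57L), "patient", "d1", "116154003",
                     c(1.0, 1.0))
  expect_equal(nrow(pinpointCandidates(twice)), 2L)
})

test_that("pinpointing equals the max-per-overlap-component oracle on random clusters", {
  oracle <- function(cand) {
    keep <- logical(nrow(cand))
    for (cc in unique(cand$concept_id)) {
      rows <- which(cand$concept_id == cc)
      # reachability over the overlap adjacency matrix
      n <- length(rows)
      adj <- outer(seq_len(n), seq_len(n), function(i, j)
        cand$start[rows[i]] < cand$end[rows[j]] &
          cand$start[rows[j]] < cand$end[rows[i]])
      reach <- adj
      for (k in seq_len(n))
        reach <- reach | (reach %*% reach > 0)
      seen <- rep(FALSE, n)
      for (i in seq_len(n)) {
        if (seen[i]) next
        comp <- which(reach[i, ] | seq_len(n) == i)
        seen[comp] <- TRUE
        grp <- rows[comp]
        ord <- order(-cand$similarity[grp], cand$end[grp] - cand$start[grp],
                     cand$start[grp], cand$description_id[grp])
        keep[grp[ord[1]]] <- TRUE
      }
    }
    cand[keep, , drop = FALSE]
  }
  set.seed(31)
  for (rep in 1:10) {
    n <- 25L
    start <- sample(0:60, n, TRUE)
    len <- sample(1:10, n, TRUE)
    cand <- candFrame(start, start + len, "t", paste0("d", seq_len(n)),
                      sample(c("A", "B", "C"), n, TRUE), round(runif(n), 3))
    got <- pinpointCandidates(cand)
    want <- oracle(cand)
    key <- function(d) sort(paste(d$start, d$end, d$concept_id, d$similarity))
    expect_equal(key(got), key(want))
  }
})

test_that("context filter implements the blacklist and max-comparison rules", {
  p <- testProvider()
  text <- "the mitral signal sentence. unrelated tail."
  cand <- candFrame(c(4L, 4L, 4L), c(10L, 10L, 10L), "mitral",
                    c("d1", "d2", "d3"), c("NEG", "NONE", "BOTH"), 1.0)
  coll <- contextCollection(
    positive = list(BOTH = "the mitral signal sentence"),
    negative = list(NEG = "whatever context", BOTH = "zzz qqq totally other"))
  out <- contextFilter(cand, coll, text, p)
  # only-negative concept dropped; no-sample concept kept; both-kinds kept
  # because the positive sample equals the sentence (similarity 1)
  expect_setequal(out$concept_id, c("NONE", "BOTH"))

  # flip: negative sample equals the sentence, positive unrelated -> dropped
  coll2 <- contextCollection(
    positive = list(BOTH = "zzz qqq totally other"),
    negative = list(BOTH = "the mitral signal sentence"))
  out2 <- contextFilter(cand[3, ], coll2, text, p)
  expect_equal(nrow(out2), 0L)
})

test_that("nesting minimization eliminates the nested family-history link", {
  p <- testProvider()
  idx <- terminologyIndex(
    data.frame(concept_id = c("38341003", "160357008"),
               preferred_name = c("hypertension", "family history: hypertension"),
               category = "Clinical finding", stringsAsFactors = FALSE),
    NULL,
    data.frame(concept_id = c("38341003", "160357008"),
               text = c("hypertension", "family history: hypertension"),
               stringsAsFactors = FALSE))
  idx <- buildDescriptionIndex(idx, p)
  links <- linkDocument("family history: hypertension", idx, provider = p,
                        config = linkerConfig(selectionThreshold = 0.9,
                                              maxNgramLen = 5L))
  expect_equal(links$concept_id, "160357008")
  expect_equal(links$text, "family history: hypertension")

  # identity when nothing nests
  flat <- candFrame(c(0L, 20L), c(5L, 28L), c("alpha", "beta"),
                    descriptionIdFor(idx, c("hypertension",
                                            "family history: hypertension")),
                    c("38341003", "160357008"), c(0.95, 0.96))
  out <- minimizeNesting(flat, p, idx)
  expect_equal(nrow(out), 2L)
})

test_that("nesting keeps both links when removing the inner raises outer similarity", {
  p <- testProvider()
  idx <- terminologyIndex(
    data.frame(concept_id = c("X", "Y"),
               preferred_name = c("alpha gamma", "beta"),
               category = "c", stringsAsFactors = FALSE),
    NULL,
    data.frame(concept_id = c("X", "Y"), text = c("alpha gamma", "beta"),
               stringsAsFactors = FALSE))
  idx <- buildDescriptionIndex(idx, p)
  outerText <- "alpha beta gamma"
  dOuter <- descriptionIdFor(idx, "alpha gamma")
  dInner <- descriptionIdFor(idx, "beta")
  simOuter <- cosineSim(embedTexts(outerText, p)[1, ],
                        embedTexts("alpha gamma", p)[1, ])
  cand <- candFrame(c(0L, 6L), c(16L, 10L), c(outerText, "beta"),
                    c(dOuter, dInner), c("X", "Y"), c(simOuter, 1.0))
  out <- minimizeNesting(cand, p, idx)
  # removing "beta" from the outer text yields exactly "alpha gamma":
  # similarity rises to 1, so the inner link is justified and kept
  expect_equal(nrow(out), 2L)
})

test_that("online-learning updates add the right samples and poison bad concepts", {
  p <- testProvider()
  coll <- contextCollection()
  text <- "pump failure observed today. second sentence."
  links <- candFrame(0L, 12L, "pump failure", "d", c("3"), 1.0)
  gold <- data.frame(start = 0L, end = 12L, concept_id = "3",
                     stringsAsFactors = FALSE)
  # all links correct: only positive samples added
  c1 <- updateCollections(links, gold, coll, text)
  expect_length(positiveSamples(c1, "3"), 1L)
  expect_length(negativeSamples(c1, "3"), 0L)

  # one false positive: exactly one negative sample for that concept
  wrong <- candFrame(0L, 12L, "pump failure", "d", "4", 1.0)
  c2 <- updateCollections(rbind(links, wrong), gold, coll, text)
  expect_length(negativeSamples(c2, "4"), 1L)
  expect_length(negativeSamples(c2, "3"), 0L)

  expect_error(updateCollections(links,
                                 data.frame(start = 0L, end = 999L,
                                            concept_id = "3"),
                                 coll, text), "outside document")

  # two-pass scenario: a concept that collected only negative evidence in
  # pass 1 is blacklisted in pass 2
  idx <- embeddedToy()
  cfg <- linkerConfig(selectionThreshold = 0.9, maxNgramLen = 4L)
  doc1 <- "pump failure observed today"
  links1 <- linkDocument(doc1, idx, provider = p, config = cfg)
  expect_setequal(links1$concept_id, c("3", "4"))    # ambiguous description
  gold1 <- data.frame(start = links1$start[1], end = links1$end[1],
                      concept_id = "3", stringsAsFactors = FALSE)
  coll2 <- updateCollections(links1, gold1, contextCollection(), doc1)
  expect_length(negativeSamples(coll2, "4"), 1L)
  doc2 <- "pump failure observed today"
  links2 <- linkDocument(doc2, idx, collections = coll2, provider = p,
                         config = cfg)
  expect_equal(links2$concept_id, "3")               # 4 is now blacklisted
})

test_that("abbreviation disambiguation changes links only at dictionary hits", {
  p <- testProvider()
  idx <- embeddedToy()
  dict <- abbreviationDictionary(data.frame(
    abbreviation = "HT", expansion = "hypertension",
    stringsAsFactors = FALSE))
  dict@entries[["HT"]][[1]]$samples <- "HT noted in the record"
  cfg <- linkerConfig(selectionThreshold = 0.9, maxNgramLen = 4L)
  doc <- "HT noted. renal disorder present"
  with <- linkDocument(doc, idx, dictionary = dict, provider = p,
                       config = cfg, withAbbrev = TRUE)
  without <- linkDocument(doc, idx, dictionary = dict, provider = p,
                          config = cfg, withAbbrev = FALSE)
  expect_true("5" %in% with$concept_id)      # hypertension via expansion
  expect_false("5" %in% without$concept_id)
  expect_equal(with[with$start == 0L, "end"], 2L)  # original coordinates
  # away from the abbreviation, both runs agree
  expect_equal(unlist(with[with$concept_id == "4", c("start", "end")]),
               unlist(without[without$concept_id == "4", c("start", "end")]))
})

test_that("selection is a subset chain and stable under candidate permutation", {
  p <- testProvider()
  idx <- embeddedToy()
  cfg <- linkerConfig(selectionThreshold = 0.9, maxNgramLen = 4L)
  doc <- "heart failure seen. hypertension later"
  cand <- identifyCandidates(doc, idx, provider = p, config = cfg)
  s1 <- thresholdFilter(cand, cfg@selectionThreshold)
  s2 <- pinpointCandidates(s1)
  s3 <- contextFilter(s2, contextCollection(), doc, p)
  s4 <- minimizeNesting(s3, p, idx)
  key <- function(d) sort(paste(d$start, d$end, d$concept_id))
  expect_true(all(key(s2) %in% key(s1)))
  expect_true(all(key(s3) %in% key(s2)))
  expect_true(all(key(s4) %in% key(s3)))

  set.seed(13)
  perm <- cand[sample.int(nrow(cand)), , drop = FALSE]
  s4p <- minimizeNesting(
    contextFilter(pinpointCandidates(thresholdFilter(perm,
                                                     cfg@selectionThreshold)),
                  contextCollection(), doc, p), p, idx)
  expect_equal(key(s4p), key(s4))
})

test_that("a planted verbatim mention yields exactly its link at t = 0.9", {
  p <- testProvider()
  idx <- embeddedToy()
  doc <- "meanwhile observed hypertension throughout afterwards"
  links <- linkDocument(doc, idx, provider = p,
                        config = linkerConfig(selectionThreshold = 0.9,
                                              maxNgramLen = 5L))
  expect_equal(nrow(links), 1L)
  expect_equal(links$concept_id, "5")
  expect_equal(substr(doc, links$start + 1L, links$end), "hypertension")
})
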