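test_that("RF2 loading keeps active content only and counts match the fixture", {
  # root, child and an extra synonym on the child: 3 concepts (one inactive),
  # FSN + synonym descriptions, one non-is-a relationship to be ignored
  concepts <- rbind(rf2ConceptRow("10"), rf2ConceptRow("11"),
                    rf2ConceptRow("12", active = "0"))
  descriptions <- rbind(
    rf2DescriptionRow("d1", "10", "body structure (body structure)",
                      typeId = "900000000000003001"),
    rf2DescriptionRow("d2", "10", "anatomy"),
    rf2DescriptionRow("d3", "11", "heart (body structure)",
                      typeId = "900000000000003001"),
    rf2DescriptionRow("d4", "11", "cardiac structure"),
    rf2DescriptionRow("d5", "11", "old heart name", active = "0"),
    rf2DescriptionRow("d6", "12", "retired concept name"))
  relationships <- rbind(
    rf2RelationshipRow("r1", "11", "10"),
    rf2RelationshipRow("r2", "11", "10", typeId = "999999"),  # not is-a
    rf2RelationshipRow("r3", "12", "10"))                      # inactive src
  paths <- writeRF2TestFiles(tempfile("rf2"), concepts, descriptions,
                             relationships)
  idx <- loadRF2(paths["concept"], paths["description"],
                 paths["relationship"])

  expect_equal(sort(conceptTable(idx)$concept_id), c("10", "11"))
  expect_equal(nrow(descriptionTable(idx)), 4L)  # 2 FSN + 2 active synonyms
  expect_equal(conceptAncestors(idx, "11"), "10")
  expect_equal(conceptAncestors(idx, "10"), character(0))
  tab <- conceptTable(idx)
  expect_equal(tab$category[tab$concept_id == "11"], "body structure")
  expect_equal(tab$preferred_name[tab$concept_id == "11"], "heart")
})

test_that("RF2 loading reports missing columns and dangling references", {
  concepts <- rf2ConceptRow("10")
  descriptions <- rf2DescriptionRow("d1", "10", "thing")
  relationships <- rf2RelationshipRow("r1", "10", "99")  # 99 never defined
  paths <- writeRF2TestFiles(tempfile("rf2"), concepts, descriptions,
                             relationships)
  expect_error(loadRF2(paths["concept"], paths["description"],
                       paths["relationship"]), "99")

  bad <- concepts; names(bad)[names(bad) == "active"] <- "act"
  paths2 <- writeRF2TestFiles(tempfile("rf2"), bad, descriptions,
                              rf2RelationshipRow("r1", "10", "10"))
  expect_error(loadRF2(paths2["concept"], paths2["description"],
                       paths2["relationship"]), "active")
})

test_that("RRF loading merges names per CUI, flags shared names, drops suppressed rows", {
  mkRow <- function(cui, str, suppress = "N", ispref = "Y") {
    f <- rep("", 18); f[1] <- cui; f[7] <- ispref; f[15] <- str
    f[17] <- suppress
    paste(f, collapse = "|")
  }
  conso <- tempfile(); sty <- tempfile()
  writeLines(c(mkRow("C001", "hypertension"),
               mkRow("C001", "high blood pressure", ispref = "N"),
               mkRow("C002", "hypertension", ispref = "N"),
               mkRow("C003", "suppressed name", suppress = "O")), conso)
  writeLines(c("C001|T047||Disease or Syndrome||",
               "C002|T047||Disease or Syndrome||",
               "C003|T047||Disease or Syndrome||"), sty)
  idx <- loadRRF(conso, sty)
  # C003's only row is suppressed, so the concept disappears entirely
  expect_equal(sort(conceptTable(idx)$concept_id), c("C001", "C002"))
  d <- descriptionTable(idx)
  shared <- d[d$text == "hypertension", ]
  expect_equal(shared$concept_ids[[1]], c("C001", "C002"))
  expect_false("suppressed name" %in% d$text)
  amb <- findAmbiguousDescriptions(idx)
  expect_equal(amb$text, "hypertension")
  # UMLS carries no hierarchy: empty ancestor sets
  expect_equal(conceptAncestors(idx, "C001"), character(0))
  expect_equal(conceptTable(idx)$category[1], "Disease or Syndrome")
})

test_that("ancestor closure handles chains, roots and diamonds", {
  idx <- makeToyIndex()
  expect_equal(conceptAncestors(idx, "3"), c("1", "2"))  # chain 3 <- 2 <- 1
  expect_equal(conceptAncestors(idx, "1"), character(0)) # root
  # diamond: both parents and the shared grandparent, each once
  diamond <- terminologyIndex(
    data.frame(concept_id = c("A", "B1", "B2", "C"),
               preferred_name = c("a", "b1", "b2", "c"),
               category = "x", stringsAsFactors = FALSE),
    data.frame(child = c("B1", "B2", "C", "C"),
               parent = c("A", "A", "B1", "B2"), stringsAsFactors = FALSE),
    data.frame(concept_id = c("A", "B1", "B2", "C"),
               text = c("a", "b1", "b2", "c"), stringsAsFactors = FALSE))
  expect_equal(conceptAncestors(diamond, "C"), c("A", "B1", "B2"))
  expect_error(conceptAncestors(idx, "nope"), "unknown concept")
})

test_that("ancestor closure equals brute-force transitive closure on random DAGs", {
  set.seed(202)
  for (rep in 1:5) {
    parents <- randomDag(15)
    idx <- dagToIndex(parents)
    for (id in names(parents))
      expect_equal(conceptAncestors(idx, id), bruteForceAncestors(parents, id))
  }
})

test_that("adding an is-a edge never shrinks any ancestor set", {
  set.seed(77)
  parents <- randomDag(12, pEdge = 0.2)
  idx <- dagToIndex(parents)
  before <- lapply(names(parents), function(id) conceptAncestors(idx, id))
  # add edge 5 -> 2 (respects the topological order, stays acyclic)
  parents2 <- parents
  parents2[["5"]] <- union(parents2[["5"]], "2")
  idx2 <- dagToIndex(parents2)
  after <- lapply(names(parents), function(id) conceptAncestors(idx2, id))
  for (i in seq_along(before))
    expect_true(all(before[[i]] %in% after[[i]]))
})

test_that("ambiguity detection returns exactly the shared descriptions", {
  idx <- makeToyIndex()
  amb <- findAmbiguousDescriptions(idx)
  expect_equal(amb$text, "pump failure")
  expect_equal(amb$concept_ids[[1]], c("3", "4"))

  flat <- terminologyIndex(
    data.frame(concept_id = "1", preferred_name = "x", category = "c",
               stringsAsFactors = FALSE),
    NULL,
    data.frame(concept_id = "1", text = "x", stringsAsFactors = FALSE))
  expect_equal(nrow(findAmbiguousDescriptions(flat)), 0L)
})

test_that("description index embedding is idempotent and fails on empty stores", {
  p <- testProvider()
  idx <- buildDescriptionIndex(makeToyIndex(), p)
  expect_equal(nrow(descriptionEmbeddings(idx)),
               nrow(descriptionTable(idx)))
  idx2 <- buildDescriptionIndex(idx, p)
  expect_identical(descriptionEmbeddings(idx), descriptionEmbeddings(idx2))
  # fresh provider in a fresh call: bit-identical matrix (determinism)
  idx3 <- buildDescriptionIndex(makeToyIndex(), testProvider())
  expect_identical(descriptionEmbeddings(idx), descriptionEmbeddings(idx3))

  empty <- terminologyIndex(
    data.frame(concept_id = "1", preferred_name = "x", category = "c",
               stringsAsFactors = FALSE),
    NULL, data.frame(concept_id = character(0), text = character(0),
                     stringsAsFactors = FALSE))
  expect_error(buildDescriptionIndex(empty, p), "state error")
})

test_that("round-trip through the RF2 dialect preserves the terminology", {
  idx <- makeToyIndex()
  dir <- tempfile("roundtrip")
  paths <- writeRF2Fixture(idx, dir)
  re <- loadRF2(paths["concept"], paths["description"],
                paths["relationship"])
  expect_equal(sort(conceptTable(re)$concept_id),
               sort(conceptTable(idx)$concept_id))
  for (id in conceptTable(idx)$concept_id)
    expect_equal(conceptAncestors(re, id), conceptAncestors(idx, id))
  # every original description text survives with the same concept set
  orig <- descriptionTable(idx); back <- descriptionTable(re)
  for (i in seq_len(nrow(orig))) {
    j <- match(tolower(orig$text[i]), tolower(back$text))
    expect_false(is.na(j))
    expect_equal(back$concept_ids[[j]], orig$concept_ids[[i]])
  }
  pn <- conceptTable(re)$preferred_name
  expect_setequal(pn, conceptTable(idx)$preferred_name)
})

test_that("terminology validity rejects self-parents and cycles", {
  expect_error(terminologyIndex(
    data.frame(concept_id = "1", preferred_name = "x", category = "c",
               stringsAsFactors = FALSE),
    data.frame(child = "1", parent = "1", stringsAsFactors = FALSE),
    data.frame(concept_id = "1", text = "x", stringsAsFactors = FALSE)),
    "own parent")
  expect_error(terminologyIndex(
    data.frame(concept_id = c("1", "2"), preferred_name = c("x", "y"),
               category = "c", stringsAsFactors = FALSE),
    data.frame(child = c("1", "2"), parent = c("2", "1"),
               stringsAsFactors = FALSE),
    data.frame(concept_id = c("1", "2"), text = c("x", "y"),
               stringsAsFactors = FALSE)),
    "cycle")
})
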