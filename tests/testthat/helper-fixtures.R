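# Shared in-code fixtures: a tiny hand-countable terminology, RF2/RRF file
# writers, and the deterministic embedding provider used throughout.

testProvider <- function(dim = 256L) hashingProvider(dim)

# Five concepts: chain root <- cardiac <- hf, a diamond top, one shared
# synonym ("pump failure") between hf and renal -> ambiguous description.
makeToyIndex <- function() {
  concepts <- data.frame(
    concept_id = c("1", "2", "3", "4", "5"),
    preferred_name = c("disorder", "cardiac disorder", "heart failure",
                       "renal disorder", "hypertension"),
    category = "Clinical finding", stringsAsFactors = FALSE)
  relationships <- data.frame(child = c("2", "3", "4", "5"),
                              parent = c("1", "2", "1", "2"),
                              stringsAsFactors = FALSE)
  descriptions <- data.frame(
    concept_id = c("1", "2", "3", "3", "4", "4", "5"),
    text = c("disorder", "cardiac disorder", "heart failure", "pump failure",
             "renal disorder", "pump failure", "hypertension"),
    stringsAsFactors = FALSE)
  terminologyIndex(concepts, relationships, descriptions)
}

writeRF2TestFiles <- function(dir, concepts, descriptions, relationships) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(concept = file.path(dir, "concept.txt"),
             description = file.path(dir, "description.txt"),
             relationship = file.path(dir, "relationship.txt"))
  write.table(concepts, paths["concept"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(descriptions, paths["description"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(relationships, paths["relationship"], sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths
}

rf2ConceptRow <- function(id, active = "1") {
  data.frame(id = id, effectiveTime = "20230531", active = active,
             moduleId = "0", definitionStatusId = "0",
             stringsAsFactors = FALSE)
}

rf2DescriptionRow <- function(id, conceptId, term, active = "1",
                              typeId = "900000000000013009") {
  data.frame(id = id, effectiveTime = "20230531", active = active,
             moduleId = "0", conceptId = conceptId, languageCode = "en",
             typeId = typeId, term = term, caseSignificanceId = "0",
             stringsAsFactors = FALSE)
}

rf2RelationshipRow <- function(id, sourceId, destinationId, active = "1",
                               typeId = "116680003") {
  data.frame(id = id, effectiveTime = "20230531", active = active,
             moduleId = "0", sourceId = sourceId,
             destinationId = destinationId, relationshipGroup = "0",
             typeId = typeId, characteristicTypeId = "0", modifierId = "0",
             stringsAsFactors = FALSE)
}

# Brute-force transitive closure over a child -> parents list (independent
# of the package's memoized implementation).
bruteForceAncestors <- function(parents, id) {
  anc <- character(0)
  frontier <- parents[[id]]
  while (length(frontier)) {
    anc <- union(anc, frontier)
    frontier <- setdiff(unique(unlist(parents[frontier], use.names = FALSE)),
                        anc)
  }
  sort(anc)
}

# Random DAG as a child -> parents list: node i may only point to nodes < i.
randomDag <- function(n, pEdge = 0.3) {
  parents <- setNames(vector("list", n), as.character(seq_len(n)))
  parents[] <- list(character(0))
  for (i in 2:n) {
    sel <- which(runif(i - 1L) < pEdge)
    parents[[as.character(i)]] <- as.character(sel)
  }
  parents
}

dagToIndex <- function(parents) {
  ids <- names(parents)
  concepts <- data.frame(concept_id = ids,
                         preferred_name = paste("node", ids),
                         category = "Clinical finding",
                         stringsAsFactors = FALSE)
  edges <- do.call(rbind, lapply(ids, function(id) {
    if (length(parents[[id]]) == 0L) return(NULL)
    data.frame(child = id, parent = parents[[id]], stringsAsFactors = FALSE)
  }))
  descriptions <- data.frame(concept_id = ids, text = paste("node", ids),
                             stringsAsFactors = FALSE)
  terminologyIndex(concepts, edges, descriptions)
}

descriptionIdFor <- function(index, text) {
  d <- descriptionTable(index)
  d$description_id[match(text, d$text)]
}
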