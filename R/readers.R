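# Readers for standoff entity-annotation formats and the link-table writer.

#' Read a MedMentions-style PubTator file
#'
#' The PubTator text format: per document a `PMID|t|title` line, a
#' `PMID|a|abstract` line, then one tab-delimited annotation line per mention
#' (`pmid, start, end, mention, type, concept_id`), documents separated by
#' blank lines. Offsets are over `title + " " + abstract`.
#'
#' @param file Path to the PubTator file.
#' @return List with `docs` (named character vector of document texts) and
#'   `annotations` (data.frame: `doc_id`, `start`, `end`, `text`, `type`,
#'   `concept_id`).
#' @export
readPubTator <- function(file) {
  lines <- readLines(file, warn = FALSE)
  titles <- list(); abstracts <- list()
  ann <- list(); n <- 0L
  for (ln in lines) {
    if (!nzchar(ln)) next
    if (grepl("^[^\t|]+\\|t\\|", ln)) {
      id <- sub("\\|.*$", "", ln)
      titles[[id]] <- sub("^[^|]+\\|t\\|", "", ln)
    } else if (grepl("^[^\t|]+\\|a\\|", ln)) {
      id <- sub("\\|.*$", "", ln)
      abstracts[[id]] <- sub("^[^|]+\\|a\\|", "", ln)
    } else {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 6L)
        stop("format error: annotation line with fewer than 6 fields in '",
             file, "'")
      n <- n + 1L
      ann[[n]] <- data.frame(doc_id = f[1], start = as.integer(f[2]),
                             end = as.integer(f[3]), text = f[4],
                             type = f[5], concept_id = f[6],
                             stringsAsFactors = FALSE)
    }
  }
  ids <- union(names(titles), names(abstracts))
  docs <- vapply(ids, function(id) {
    t <- titles[[id]]; a <- abstracts[[id]]
    paste(c(t, a), collapse = " ")
  }, character(1))
  annotations <- if (n > 0L) do.call(rbind, ann) else
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               text = character(0), type = character(0),
               concept_id = character(0), stringsAsFactors = FALSE)
  list(docs = docs, annotations = annotations)
}

#' Read ShARe/CLEF-style pipe-delimited standoff annotations
#'
#' Each line is `doc_id|spans|concept_id` where `spans` is one or more
#' `start-end` intervals joined by commas. Annotations with disjoint spans
#' are skipped and counted as unreachable, and "CUI-less" annotations (no
#' concept identifier) are excluded.
#'
#' @param file Path to the annotation file.
#' @return data.frame with columns `doc_id`, `start`, `end`, `concept_id`
#'   and attributes `skipped_disjoint` and `skipped_cuiless`.
#' @export
readShareClef <- function(file) {
  lines <- readLines(file, warn = FALSE)
  lines <- lines[nzchar(lines)]
  out <- list(); n <- 0L
  disjoint <- 0L; cuiless <- 0L
  for (ln in lines) {
    f <- strsplit(ln, "|", fixed = TRUE)[[1]]
    if (length(f) < 3L)
      stop("format error: line with fewer than 3 pipe-delimited fields in '",
           file, "'")
    spans <- strsplit(f[2], ",", fixed = TRUE)[[1]]
    if (length(spans) > 1L) { disjoint <- disjoint + 1L; next }
    if (f[3] %in% c("", "CUI-less", "CUIless")) { cuiless <- cuiless + 1L; next }
    se <- as.integer(strsplit(spans, "-", fixed = TRUE)[[1]])
    if (length(se) != 2L || any(is.na(se)))
      stop("format error: malformed span '", spans, "' in '", file, "'")
    n <- n + 1L
    out[[n]] <- data.frame(doc_id = f[1], start = se[1], end = se[2],
                           concept_id = f[3], stringsAsFactors = FALSE)
  }
  res <- if (n > 0L) do.call(rbind, out) else
    data.frame(doc_id = character(0), start = integer(0), end = integer(0),
               concept_id = character(0), stringsAsFactors = FALSE)
  attr(res, "skipped_disjoint") <- disjoint
  attr(res, "skipped_cuiless") <- cuiless
  res
}

#' Write a link table with optional JSON provenance sidecar
#'
#' @param links data.frame of links (any columns; typically `doc_id`,
#'   `start`, `end`, `concept_id`, `similarity`).
#' @param file Output TSV path.
#' @param provenance Optional list (e.g. resolved config + seed) written to
#'   `<file>.json`.
#' @return Invisibly, `file`.
#' @export
writeLinkTable <- function(links, file, provenance = NULL) {
  drop <- vapply(links, is.list, logical(1))
  utils::write.table(links[, !drop, drop = FALSE], file, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  if (!is.null(provenance))
    jsonlite::write_json(provenance, paste0(file, ".json"),
                         auto_unbox = TRUE, digits = NA)
  invisible(file)
}
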