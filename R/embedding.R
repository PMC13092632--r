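# Embedding backend: a uniform contract for turning text into unit vectors
# plus exact top-k retrieval over a description-embedding index.
#
# The default provider is a deterministic, seedless character 3-gram feature
# hashing embedder. It is platform stable (pure integer arithmetic on
# Unicode code points, exact in double precision), so every downstream
# module is testable fully offline. Neural semantic-similarity providers can
# be registered by name at run time; the package never bundles model weights.

#' @import methods
NULL

#' Embedding provider
#'
#' Wraps a text-embedding function together with its name and output
#' dimension. Embeddings of a fixed string are identical across calls and
#' across processes for a fixed provider configuration, and all vectors
#' returned by [embedTexts()] have unit L2 norm.
#'
#' @slot name Identifier string for the provider.
#' @slot dim Positive integer vector dimension.
#' @slot embedFun Function taking a character vector and returning a numeric
#'   matrix with one row per input (rows need not be pre-normalized).
#' @slot cache Environment used to memoize embeddings within a process.
#' @export
setClass("EmbeddingProvider",
         representation(name = "character", dim = "integer",
                        embedFun = "function", cache = "environment"))

setValidity("EmbeddingProvider", function(object) {
  if (length(object@name) != 1L || !nzchar(object@name))
    return("'name' must be a single non-empty string")
  if (length(object@dim) != 1L || is.na(object@dim) || object@dim < 1L)
    return("'dim' must be a positive integer")
  TRUE
})

setMethod("show", "EmbeddingProvider", function(object) {
  cat("EmbeddingProvider:", object@name, "(", object@dim, "dimensions )\n")
})

#' @describeIn EmbeddingProvider Provider name accessor.
#' @param provider An `EmbeddingProvider`.
#' @export
providerName <- function(provider) provider@name

#' @describeIn EmbeddingProvider Embedding dimension accessor.
#' @export
providerDim <- function(provider) provider@dim

#' Construct an embedding provider
#'
#' @param name Provider identifier.
#' @param dim Output dimension.
#' @param embedFun Function mapping a character vector to a numeric matrix
#'   (one row per text).
#' @return An [EmbeddingProvider-class] object.
#' @export
embeddingProvider <- function(name, dim, embedFun) {
  new("EmbeddingProvider", name = name, dim = as.integer(dim),
      embedFun = embedFun, cache = new.env(parent = emptyenv()))
}

# -- deterministic hashing fallback ------------------------------------------

# Character 3-gram feature hashing for one normalized string. Texts are
# lowercased, whitespace-collapsed and padded with a leading/trailing space
# before trigram extraction; each trigram t maps to bucket (h(t) mod dim)
# with sign given by the parity of floor(h(t) / dim), where
# h(t) = 961*c1 + 31*c2 + c3 over Unicode code points (exact in doubles).
hashEmbedOne <- function(text, dim) {
  s <- squeezeWhitespace(tolower(text))
  s <- paste0(" ", s, " ")
  cp <- utf8ToInt(s)
  n <- length(cp)
  if (n < 3L) cp <- c(cp, rep.int(32L, 3L - n))
  n <- length(cp)
  v <- cp[1:(n - 2L)] * 961 + cp[2:(n - 1L)] * 31 + cp[3:n]
  bucket <- (v %% dim) + 1
  sgn <- 1 - 2 * ((v %/% dim) %% 2)
  out <- numeric(dim)
  acc <- vapply(split(sgn, bucket), sum, numeric(1))
  out[as.integer(names(acc))] <- acc
  out
}

#' Deterministic character 3-gram hashing provider
#'
#' A seedless, platform-stable embedding provider: lowercases and
#' whitespace-collapses the text, extracts padded character trigrams, and
#' feature-hashes them (with alternating signs) into a fixed-dimension vector
#' which is then L2-normalized by [embedTexts()]. Two runs in separate
#' processes produce bit-identical vectors. Intended for offline operation
#' and reproducible tests; register a neural semantic-similarity provider via
#' [registerEmbeddingProvider()] for production-quality semantics.
#'
#' @param dim Vector dimension (default 256).
#' @return An [EmbeddingProvider-class].
#' @export
hashingProvider <- function(dim = 256L) {
  dim <- as.integer(dim)
  embeddingProvider(paste0("hashing-", dim), dim, function(texts) {
    t(vapply(texts, hashEmbedOne, numeric(dim), dim = dim, USE.NAMES = FALSE))
  })
}

# -- provider registry --------------------------------------------------------

.providerRegistry <- new.env(parent = emptyenv())

#' Register or resolve embedding providers by configuration name
#'
#' `registerEmbeddingProvider` installs a provider factory under a name;
#' `resolveProvider` turns a configuration string into a provider. Names of
#' the form `"hashing-<dim>"` are always available.
#'
#' @param name Provider configuration name.
#' @param factory Zero-argument function returning an
#'   [EmbeddingProvider-class].
#' @return `resolveProvider` returns an [EmbeddingProvider-class].
#' @export
registerEmbeddingProvider <- function(name, factory) {
  assign(name, factory, envir = .providerRegistry)
  invisible(name)
}

#' @rdname registerEmbeddingProvider
#' @export
resolveProvider <- function(name) {
  if (exists(name, envir = .providerRegistry, inherits = FALSE))
    return(get(name, envir = .providerRegistry)())
  if (grepl("^hashing-[0-9]+$", name))
    return(hashingProvider(as.integer(sub("^hashing-", "", name))))
  stop("unknown embedding provider: '", name,
       "' (register it with registerEmbeddingProvider)")
}

# -- core operations ----------------------------------------------------------

#' Embed texts as unit vectors
#'
#' @param texts Non-empty character vector; every element must be non-empty
#'   after whitespace stripping.
#' @param provider An [EmbeddingProvider-class].
#' @return A numeric matrix with one unit-normalized row per input text.
#' @export
embedTexts <- function(texts, provider) {
  if (!is(provider, "EmbeddingProvider")) stop("'provider' must be an EmbeddingProvider")
  if (length(texts) == 0L) stop("input error: 'texts' must be non-empty")
  blank <- !nzchar(trimws(texts)) | is.na(texts)
  if (any(blank))
    stop("input error: empty text at index ", which(blank)[1])
  keys <- texts
  cached <- vapply(keys, exists, logical(1), envir = provider@cache,
                   inherits = FALSE, USE.NAMES = FALSE)
  out <- matrix(0, nrow = length(texts), ncol = provider@dim)
  if (any(!cached)) {
    todo <- which(!cached)
    raw <- provider@embedFun(texts[todo])
    if (!is.matrix(raw) || nrow(raw) != length(todo) || ncol(raw) != provider@dim)
      stop("provider '", provider@name, "' returned a malformed matrix")
    nrm <- sqrt(rowSums(raw^2))
    if (any(nrm == 0))
      stop("provider '", provider@name, "' returned a zero vector")
    raw <- raw / nrm
    for (j in seq_along(todo))
      assign(keys[todo[j]], raw[j, ], envir = provider@cache)
    out[todo, ] <- raw
  }
  if (any(cached)) {
    done <- which(cached)
    out[done, ] <- t(vapply(keys[done], get, numeric(provider@dim),
                            envir = provider@cache, USE.NAMES = FALSE))
  }
  rownames(out) <- NULL
  out
}

#' Cosine similarity between two vectors
#'
#' @param u,v Non-zero numeric vectors of equal dimension.
#' @return Cosine similarity in `[-1, 1]`.
#' @export
cosineSim <- function(u, v) {
  if (length(u) != length(v)) stop("input error: dimension mismatch")
  nu <- sqrt(sum(u^2)); nv <- sqrt(sum(v^2))
  if (nu == 0 || nv == 0) stop("input error: zero vector")
  sum(u * v) / (nu * nv)
}

#' Exact top-k retrieval over an embedding matrix
#'
#' Scores a unit query vector against every row of `embeddings` by dot
#' product (cosine similarity for unit rows) and returns the `min(k, n)`
#' best hits sorted by non-increasing score, ties broken by ascending row
#' identifier.
#'
#' @param embeddings Numeric matrix of unit row vectors; rownames are the
#'   description identifiers.
#' @param query Numeric query vector (same dimension).
#' @param k Positive integer.
#' @return A data.frame with columns `description_id` and `score`.
#' @export
topKHits <- function(embeddings, query, k) {
  if (!is.matrix(embeddings) || nrow(embeddings) == 0L)
    stop("state error: empty embedding index")
  if (k < 1L) stop("input error: k must be >= 1")
  ids <- rownames(embeddings)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(embeddings)))
  scores <- as.numeric(embeddings %*% query)
  ord <- order(-scores, ids)
  take <- ord[seq_len(min(k, length(ord)))]
  data.frame(description_id = ids[take], score = scores[take],
             stringsAsFactors = FALSE)
}
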