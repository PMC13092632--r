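# Heart-failure classification: TF-IDF weighted concept+ancestor bags fused
# with normalized EHR features, hinge-loss linear SVM (one-vs-rest), and
# stratified cross-validation with a fixed seed.
#
# The TF-IDF variant is the conventional smoothed one: idf = ln((1+N)/(1+df))
# + 1 with raw term-frequency counts and L2-normalized rows. All weighting
# and normalization state is fit on training folds only, so unseen test-fold
# concepts contribute nothing (the test-fold concept vector is sparse).

HF_CLASSES <- c("NoHF", "HFrEF", "HFmrEF", "HFpEF")

#' The four heart-failure diagnosis classes
#'
#' No heart failure, plus the three subtypes defined by left-ventricular
#' ejection fraction: reduced (HFrEF), mildly reduced (HFmrEF) and preserved
#' (HFpEF).
#'
#' @return Character vector of the class labels in canonical order.
#' @export
hfClasses <- function() HF_CLASSES

#' Expand a concept multiset with all ontology ancestors
#'
#' Every occurrence of a concept contributes one occurrence of itself plus
#' one of each of its is-a ancestors. Concepts unknown to the index (e.g.
#' links into a terminology without hierarchy) are skipped with a warning.
#'
#' @param conceptIds Character vector (multiset) of concept ids.
#' @param index A [TerminologyIndex-class].
#' @return Character vector multiset of concepts plus ancestors.
#' @export
expandWithAncestors <- function(conceptIds, index) {
  if (length(conceptIds) == 0L) return(character(0))
  known <- conceptIds %in% index@concepts$concept_id
  if (any(!known))
    warning("skipping ", sum(!known), " concept id(s) not in the index: ",
            paste(utils::head(unique(conceptIds[!known]), 5L), collapse = ", "))
  ids <- conceptIds[known]
  unlist(lapply(ids, function(id) c(id, conceptAncestors(index, id))),
         use.names = FALSE)
}

#' Fit a TF-IDF weighting model on training concept bags
#'
#' @param bags List of character vectors (one concept multiset per patient).
#' @return An object of class `tfidfModel` with the training vocabulary and
#'   smoothed idf values.
#' @export
fitTfidf <- function(bags) {
  if (length(bags) == 0L) stop("input error: empty training corpus")
  vocab <- sort(unique(unlist(bags, use.names = FALSE)))
  n <- length(bags)
  df <- numeric(length(vocab))
  names(df) <- vocab
  for (b in bags) {
    u <- unique(b)
    df[u] <- df[u] + 1
  }
  idf <- log((1 + n) / (1 + df)) + 1
  structure(list(vocab = vocab, idf = idf, nDocs = n), class = "tfidfModel")
}

#' Transform concept bags into an L2-normalized TF-IDF matrix
#'
#' Concepts outside the training vocabulary contribute nothing.
#'
#' @param model A `tfidfModel` from [fitTfidf()].
#' @param bags List of character vectors.
#' @return A sparse [Matrix::dgCMatrix-class], rows = bags, columns =
#'   training vocabulary.
#' @export
transformTfidf <- function(model, bags) {
  i <- integer(0); j <- integer(0); x <- numeric(0)
  for (r in seq_along(bags)) {
    tf <- table(bags[[r]])
    cols <- match(names(tf), model$vocab)
    ok <- !is.na(cols)
    if (!any(ok)) next
    w <- as.numeric(tf)[ok] * model$idf[cols[ok]]
    i <- c(i, rep.int(r, sum(ok))); j <- c(j, cols[ok]); x <- c(x, w)
  }
  m <- Matrix::sparseMatrix(i = i, j = j, x = x,
                            dims = c(length(bags), length(model$vocab)),
                            dimnames = list(NULL, model$vocab))
  nrm <- sqrt(Matrix::rowSums(m^2))
  nrm[nrm == 0] <- 1
  Matrix::Diagonal(x = 1 / nrm) %*% m
}

#' Fit an EHR feature normalizer on training rows
#'
#' Numeric features are median-imputed and z-scored with training statistics
#' (zero-variance features get a unit divisor); categorical features are
#' one-hot encoded over training levels plus an explicit `"missing"` level.
#'
#' @param ehr data.frame of training-fold EHR rows.
#' @return An object of class `ehrNormalizer`.
#' @export
fitEhrNormalizer <- function(ehr) {
  if (nrow(ehr) == 0L) stop("input error: empty EHR table")
  numeric <- names(ehr)[vapply(ehr, is.numeric, logical(1))]
  categorical <- setdiff(names(ehr), numeric)
  stats <- lapply(numeric, function(col) {
    v <- ehr[[col]]
    med <- stats::median(v, na.rm = TRUE)
    if (is.na(med)) med <- 0
    v[is.na(v)] <- med
    sdv <- stats::sd(v)
    if (is.na(sdv) || sdv == 0) sdv <- 1
    list(median = med, mean = mean(v), sd = sdv)
  })
  names(stats) <- numeric
  levelsOf <- lapply(categorical, function(col) {
    v <- as.character(ehr[[col]])
    v[is.na(v)] <- "missing"
    sort(unique(c(v, "missing")))
  })
  names(levelsOf) <- categorical
  structure(list(numeric = numeric, categorical = categorical,
                 stats = stats, levels = levelsOf), class = "ehrNormalizer")
}

#' Apply an EHR normalizer
#'
#' @param model An `ehrNormalizer` from [fitEhrNormalizer()].
#' @param ehr data.frame with the training schema (missing columns are a
#'   schema error).
#' @return Dense numeric matrix, one row per patient.
#' @export
applyEhrNormalizer <- function(model, ehr) {
  missing <- setdiff(c(model$numeric, model$categorical), names(ehr))
  if (length(missing))
    stop("schema error: EHR table is missing feature(s): ",
         paste(missing, collapse = ", "))
  cols <- list()
  for (col in model$numeric) {
    v <- ehr[[col]]
    st <- model$stats[[col]]
    v[is.na(v)] <- st$median
    cols[[col]] <- (v - st$mean) / st$sd
  }
  for (col in model$categorical) {
    v <- as.character(ehr[[col]])
    v[is.na(v)] <- "missing"
    v[!v %in% model$levels[[col]]] <- "missing"
    for (lev in model$levels[[col]])
      cols[[paste(col, lev, sep = "=")]] <- as.numeric(v == lev)
  }
  m <- do.call(cbind, cols)
  rownames(m) <- NULL
  m
}

#' Train a hinge-loss linear SVM (one-vs-rest, balanced class weights)
#'
#' One linear support vector machine per class against the rest, with class
#' weights inversely proportional to class frequency; prediction takes the
#' class with the largest decision value. Deterministic given the seed.
#'
#' @param x Numeric matrix (dense or sparse) of patient vectors.
#' @param y Factor (or character) of class labels; at least two classes.
#' @param seed Random seed (default 2026).
#' @param cost SVM cost parameter (default 1).
#' @return An object of class `hfClassifier`.
#' @export
trainHfClassifier <- function(x, y, seed = 2026L, cost = 1) {
  x <- as.matrix(x)
  y <- factor(as.character(y))
  if (nlevels(y) < 2L) stop("input error: need at least two classes")
  set.seed(seed)
  models <- list()
  for (cl in levels(y)) {
    yk <- factor(ifelse(y == cl, "pos", "neg"), levels = c("pos", "neg"))
    nPos <- sum(yk == "pos"); nNeg <- sum(yk == "neg")
    w <- c(pos = length(y) / (2 * nPos), neg = length(y) / (2 * nNeg))
    fit <- e1071::svm(x = x, y = yk, kernel = "linear", scale = FALSE,
                      cost = cost, class.weights = w)
    models[[cl]] <- fit
  }
  structure(list(classes = levels(y), models = models), class = "hfClassifier")
}

#' Predict classes with a trained classifier
#'
#' @param object An `hfClassifier`.
#' @param x Patient-vector matrix with the training column layout.
#' @return Factor of predicted classes.
#' @export
predictHf <- function(object, x) {
  x <- as.matrix(x)
  scores <- vapply(object$classes, function(cl) {
    fit <- object$models[[cl]]
    dv <- attr(stats::predict(fit, x, decision.values = TRUE),
               "decision.values")
    v <- as.numeric(dv[, 1])
    # orient so that larger means "pos" regardless of libsvm's pair order
    if (!grepl("^pos/", colnames(dv)[1])) v <- -v
    v
  }, numeric(nrow(x)))
  if (is.null(dim(scores))) scores <- matrix(scores, nrow = 1L)
  picks <- apply(scores, 1L, which.max)
  factor(object$classes[picks], levels = object$classes)
}

# Deterministic stratified fold assignment.
stratifiedFolds <- function(labels, folds, seed) {
  counts <- table(labels)
  if (any(counts < folds))
    stop("stratification error: class(es) with fewer members than folds: ",
         paste(names(counts)[counts < folds], collapse = ", "))
  set.seed(seed)
  fold <- integer(length(labels))
  for (cl in names(counts)) {
    idx <- which(labels == cl)
    idx <- idx[sample.int(length(idx))]
    fold[idx] <- rep_len(seq_len(folds), length(idx))
  }
  fold
}

# Per-class precision/recall/F1 plus weighted and macro averages.
pooledMetrics <- function(truth, predicted, classes) {
  perClass <- lapply(classes, function(cl) {
    tp <- sum(predicted == cl & truth == cl)
    fp <- sum(predicted == cl & truth != cl)
    fn <- sum(predicted != cl & truth == cl)
    c(unlist(prf(tp, fp, fn)), support = sum(truth == cl))
  })
  perClass <- do.call(rbind, perClass)
  rownames(perClass) <- classes
  w <- perClass[, "support"] / sum(perClass[, "support"])
  list(per_class = as.data.frame(perClass),
       precision = sum(perClass[, "precision"] * w),
       recall = sum(perClass[, "recall"] * w),
       f1 = sum(perClass[, "f1"] * w),
       macro_f1 = mean(perClass[, "f1"]))
}

#' Stratified cross-validation of the heart-failure classifier
#'
#' Per fold, the TF-IDF model and the EHR normalizer are fit on the training
#' fold only; test-fold predictions are pooled across folds before computing
#' precision, recall, F1 (support-weighted averages over the four classes,
#' plus macro-F1) and the row-normalized confusion matrix.
#'
#' @param concepts List of per-patient concept-id vectors (ignored for
#'   `featureMode = "ehr_only"`).
#' @param ehr data.frame of per-patient EHR features (ignored for
#'   `featureMode = "concepts_only"`).
#' @param labels Vector of labels from [hfClasses()] (or any class set).
#' @param index A [TerminologyIndex-class] used for ancestor expansion, or
#'   `NULL` to skip expansion.
#' @param featureMode One of `"combined"`, `"ehr_only"`, `"concepts_only"`.
#' @param folds Number of folds (default 5).
#' @param seed Seed for the stratified fold assignment and the learner
#'   (default 2026).
#' @return Named list: `precision`, `recall`, `f1`, `macro_f1`, `per_class`,
#'   `confusion` (counts + proportions), `fold` (assignment vector),
#'   `predictions`.
#' @export
crossValidate <- function(concepts, ehr, labels, index = NULL,
                          featureMode = c("combined", "ehr_only",
                                          "concepts_only"),
                          folds = 5L, seed = 2026L) {
  featureMode <- match.arg(featureMode)
  labels <- factor(as.character(labels))
  n <- length(labels)
  fold <- stratifiedFolds(labels, folds, seed)
  bags <- NULL
  if (featureMode != "ehr_only") {
    bags <- if (is.null(index)) concepts
            else lapply(concepts, function(b)
              suppressWarnings(expandWithAncestors(b, index)))
  }
  predicted <- factor(rep(NA_character_, n), levels = levels(labels))
  for (f in seq_len(folds)) {
    tr <- which(fold != f); te <- which(fold == f)
    parts <- list(train = NULL, test = NULL)
    if (featureMode != "ehr_only") {
      tf <- fitTfidf(bags[tr])
      parts$train <- as.matrix(transformTfidf(tf, bags[tr]))
      parts$test <- as.matrix(transformTfidf(tf, bags[te]))
    }
    if (featureMode != "concepts_only") {
      nm <- fitEhrNormalizer(ehr[tr, , drop = FALSE])
      xtr <- applyEhrNormalizer(nm, ehr[tr, , drop = FALSE])
      xte <- applyEhrNormalizer(nm, ehr[te, , drop = FALSE])
      parts$train <- if (is.null(parts$train)) xtr else cbind(parts$train, xtr)
      parts$test <- if (is.null(parts$test)) xte else cbind(parts$test, xte)
    }
    model <- trainHfClassifier(parts$train, labels[tr], seed = seed)
    predicted[te] <- as.character(predictHf(model, parts$test))
  }
  classes <- levels(labels)
  metrics <- pooledMetrics(as.character(labels), as.character(predicted),
                           classes)
  c(metrics,
    list(confusion = classConfusion(labels, predicted, classes),
         fold = fold, predictions = predicted))
}
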