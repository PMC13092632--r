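# Evaluation metric suite: precision/recall/F1, expansion and total accuracy
# for abbreviation disambiguation, exact-match entity-link scoring, Cohen's
# kappa and absolute agreement for survey ratings, and confusion matrices.

checkCounts <- function(...) {
  x <- c(...)
  if (any(is.na(x)) || any(x < 0)) stop("input error: counts must be >= 0")
}

safeDiv <- function(num, den) if (den == 0) 0 else num / den

#' Precision, recall and F1 from counts
#'
#' Standard definitions: precision = TP/(TP+FP), recall = TP/(TP+FN), and F1
#' the harmonic mean of the two. Degenerate 0/0 ratios are 0 by convention.
#'
#' @param tp,fp,fn Non-negative counts.
#' @return Named list with `precision`, `recall`, `f1` (fractions in
#'   `[0, 1]`).
#' @export
prf <- function(tp, fp, fn) {
  checkCounts(tp, fp, fn)
  p <- safeDiv(tp, tp + fp)
  r <- safeDiv(tp, tp + fn)
  list(precision = p, recall = r, f1 = f1FromPrecisionRecall(p, r))
}

#' Harmonic mean of precision and recall
#'
#' @param precision,recall Fractions in `[0, 1]`.
#' @return The F1 score (0 when both inputs are 0).
#' @export
f1FromPrecisionRecall <- function(precision, recall) {
  safeDiv(2 * precision * recall, precision + recall)
}

#' Expansion accuracy and total accuracy
#'
#' Expansion accuracy is the share of attempted expansions that were correct;
#' total accuracy is recall times expansion accuracy — the end-to-end
#' disambiguation score.
#'
#' @param correct,incorrect Counts of correct/incorrect expansions.
#' @param tp,fn Detection true-positive and false-negative counts.
#' @return Named list with `expansion_accuracy`, `total_accuracy`, `recall`.
#' @export
expansionMetrics <- function(correct, incorrect, tp, fn) {
  checkCounts(correct, incorrect, tp, fn)
  ea <- safeDiv(correct, correct + incorrect)
  r <- safeDiv(tp, tp + fn)
  list(expansion_accuracy = ea, total_accuracy = r * ea, recall = r)
}

#' Score predicted entity links against gold annotations
#'
#' A prediction is a true positive only when it matches a gold annotation on
#' the exact text span and concept identifier (and document id when
#' present); overlapping-but-inexact spans count as both a false positive
#' and a false negative. Counts are micro-averaged across documents.
#'
#' @param predicted,gold data.frames with columns `start`, `end`,
#'   `concept_id` and optionally `doc_id`.
#' @return Named list with `counts` (tp/fp/fn), `precision`, `recall`, `f1`.
#' @export
scoreLinks <- function(predicted, gold) {
  keyOf <- function(d) {
    doc <- if ("doc_id" %in% names(d)) d$doc_id else ""
    unique(paste(doc, d$start, d$end, d$concept_id, sep = "\r"))
  }
  pk <- keyOf(predicted); gk <- keyOf(gold)
  tp <- sum(pk %in% gk)
  fp <- length(pk) - tp
  fn <- length(gk) - tp
  c(list(counts = c(tp = tp, fp = fp, fn = fn)), prf(tp, fp, fn))
}

#' Cohen's kappa for two raters
#'
#' Chance-corrected agreement: kappa = (p_o - p_e) / (1 - p_e), where p_o is
#' observed and p_e marginal chance agreement. Degenerate p_e = 1 (both
#' raters constant and identical) returns 1. Values range from -1 to 1;
#' imbalanced rating marginals can make kappa far smaller than raw agreement
#' (the kappa paradox).
#'
#' @param raterA,raterB Equal-length categorical rating vectors.
#' @return Kappa in `[-1, 1]`.
#' @export
cohensKappa <- function(raterA, raterB) {
  if (length(raterA) != length(raterB))
    stop("input error: rating vectors differ in length")
  if (length(raterA) == 0L) stop("input error: no items")
  a <- as.character(raterA); b <- as.character(raterB)
  po <- mean(a == b)
  cats <- union(a, b)
  pe <- sum(vapply(cats, function(k) mean(a == k) * mean(b == k), numeric(1)))
  if (pe >= 1) return(1)
  (po - pe) / (1 - pe)
}

#' Absolute agreement over a rating matrix
#'
#' Share of items on which all raters chose the same category.
#'
#' @param ratings Matrix or data.frame, one row per item, one column per
#'   rater.
#' @return Fraction in `[0, 1]`.
#' @export
absoluteAgreement <- function(ratings) {
  ratings <- as.matrix(ratings)
  if (nrow(ratings) == 0L) stop("input error: no items")
  unanimous <- apply(ratings, 1L, function(r) length(unique(r)) == 1L)
  mean(unanimous)
}

#' Confusion matrix with row-normalized percentages
#'
#' Rows are actual classes, columns predicted classes.
#'
#' @param truth,predicted Label vectors drawn from `classes`.
#' @param classes Class order for rows/columns.
#' @return Named list with `counts` (integer matrix) and `proportions`
#'   (row-normalized; all-zero rows stay zero).
#' @export
classConfusion <- function(truth, predicted, classes) {
  truth <- as.character(truth); predicted <- as.character(predicted)
  unknown <- setdiff(union(truth, predicted), classes)
  if (length(unknown))
    stop("input error: unknown label(s): ", paste(unknown, collapse = ", "))
  counts <- table(factor(truth, levels = classes),
                  factor(predicted, levels = classes))
  counts <- matrix(as.integer(counts), nrow = length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  rs <- rowSums(counts)
  props <- counts / ifelse(rs == 0, 1, rs)
  list(counts = counts, proportions = props)
}

#' Render a fraction as a percentage string
#'
#' One decimal, round half up — the precision the metric tables use.
#'
#' @param x Fraction in `[0, 1]`.
#' @param digits Decimal places (default 1).
#' @return Character vector like `"96.1"`.
#' @export
formatPercent <- function(x, digits = 1L) {
  scaled <- x * 100 * 10^digits
  sprintf(paste0("%.", digits, "f"), floor(scaled + 0.5) / 10^digits)
}
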