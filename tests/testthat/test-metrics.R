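test_that("precision/recall/F1 reproduce the published worked examples", {
  # P = 63.8%, R = 99.7% -> F1 = 77.8%
  expect_equal(formatPercent(f1FromPrecisionRecall(0.638, 0.997)), "77.8")
  # same arithmetic from raw counts
  m <- prf(tp = 997, fp = ceiling(997 * (1 - 0.638) / 0.638), fn = 3)
  expect_equal(formatPercent(m$f1), "77.8")

  expect_equal(prf(0, 0, 0), list(precision = 0, recall = 0, f1 = 0))
  expect_equal(prf(5, 5, 5)$f1, 0.5)        # P = R = x -> F1 = x
  expect_error(prf(-1, 0, 0), "input error")
})

test_that("expansion and total accuracy reproduce the published rows", {
  # R = 99.7%, EA = 94.8% -> TA = 94.5%
  t1 <- expansionMetrics(correct = 948, incorrect = 52, tp = 997, fn = 3)
  expect_equal(formatPercent(t1$expansion_accuracy), "94.8")
  expect_equal(formatPercent(t1$total_accuracy), "94.5")
  # R = 75.2%, EA = 69.7% -> TA = 52.4%
  t2 <- expansionMetrics(correct = 697, incorrect = 303, tp = 752, fn = 248)
  expect_equal(formatPercent(t2$total_accuracy), "52.4")
  # R = 100% -> TA = EA
  t3 <- expansionMetrics(correct = 3, incorrect = 1, tp = 10, fn = 0)
  expect_equal(t3$total_accuracy, t3$expansion_accuracy)
  expect_equal(expansionMetrics(0, 0, 0, 0)$expansion_accuracy, 0)
})

test_that("F1 and total accuracy respect their bounds", {
  set.seed(3)
  for (i in 1:25) {
    p <- runif(1); r <- runif(1)
    f1 <- f1FromPrecisionRecall(p, r)
    expect_lte(f1, max(p, r) + 1e-12)
    expect_gte(f1, min(p, r) - 1e-12)
    em <- expansionMetrics(sample(0:9, 1), sample(0:9, 1),
                           sample(0:9, 1), sample(0:9, 1))
    expect_lte(em$total_accuracy, em$recall + 1e-12)
    expect_lte(em$total_accuracy, em$expansion_accuracy + 1e-12)
  }
})

test_that("link scoring demands exact span and concept matches", {
  gold <- data.frame(doc_id = "d1", start = c(0L, 10L), end = c(5L, 15L),
                     concept_id = c("A", "B"), stringsAsFactors = FALSE)
  same <- scoreLinks(gold, gold)
  expect_equal(same$precision, 1)
  expect_equal(same$recall, 1)
  expect_equal(same$f1, 1)

  off <- gold; off$start[1] <- 1L        # off-by-one span: FP + FN
  sc <- scoreLinks(off, gold)
  expect_equal(unname(sc$counts), c(1L, 1L, 1L))

  # brute-force set-intersection oracle on random link tables
  set.seed(21)
  for (i in 1:10) {
    mk <- function(n) data.frame(
      doc_id = sample(c("d1", "d2"), n, TRUE),
      start = sample(0:8, n, TRUE), end = sample(9:12, n, TRUE),
      concept_id = sample(c("A", "B", "C"), n, TRUE),
      stringsAsFactors = FALSE)
    p <- mk(12); g <- mk(12)
    sc <- scoreLinks(p, g)
    pk <- unique(apply(p, 1, paste, collapse = "#"))
    gk <- unique(apply(g, 1, paste, collapse = "#"))
    expect_equal(unname(sc$counts["tp"]), length(intersect(pk, gk)))
    expect_equal(unname(sc$counts["fp"]), length(setdiff(pk, gk)))
    expect_equal(unname(sc$counts["fn"]), length(setdiff(gk, pk)))
  }
})

test_that("Cohen's kappa matches the formula and shows the kappa paradox", {
  expect_equal(cohensKappa(c("a", "b", "c"), c("a", "b", "c")), 1)
  expect_error(cohensKappa(c("a"), c("a", "b")), "length")

  # independent uniform ratings: kappa near zero at large n
  set.seed(8)
  a <- sample(c("x", "y", "z"), 6000, TRUE)
  b <- sample(c("x", "y", "z"), 6000, TRUE)
  expect_lt(abs(cohensKappa(a, b)), 0.05)

  # 40-item imbalanced fixture: hand computation, and kappa far below the
  # raw agreement (the kappa paradox under marginal imbalance)
  a <- c(rep("complete", 36), "no", "no", "partial", "partial")
  b <- c(rep("complete", 34), "no", "no", rep("complete", 2),
         "partial", "complete")
  po <- mean(a == b)
  pe <- sum(vapply(c("complete", "partial", "no"), function(k)
    mean(a == k) * mean(b == k), numeric(1)))
  byHand <- (po - pe) / (1 - pe)
  expect_equal(cohensKappa(a, b), byHand)
  expect_gt(po, 0.85)
  expect_lt(cohensKappa(a, b), po - 0.3)
})

test_that("absolute agreement counts unanimous items", {
  # 25 unanimous of 40 -> 62.5%
  ratings <- cbind(rep(c("complete", "partial"), c(25, 15)),
                   rep("complete", 40),
                   rep("complete", 40))
  expect_equal(absoluteAgreement(ratings), 25 / 40)
  expect_equal(formatPercent(absoluteAgreement(ratings)), "62.5")
  expect_equal(absoluteAgreement(matrix("complete", 5, 3)), 1)
  # simulated matrix vs direct count
  set.seed(14)
  sim <- matrix(sample(c("a", "b"), 60, TRUE), 20, 3)
  direct <- mean(sim[, 1] == sim[, 2] & sim[, 2] == sim[, 3])
  expect_equal(absoluteAgreement(sim), direct)
})

test_that("confusion matrices count and row-normalize correctly", {
  cls <- hfClasses()
  idm <- classConfusion(cls, cls, cls)
  expect_equal(unname(diag(idm$counts)), rep(1L, 4))
  expect_equal(unname(diag(idm$proportions)), rep(1, 4))

  onecol <- classConfusion(cls, rep("NoHF", 4), cls)
  expect_equal(unname(colSums(onecol$counts)), c(4L, 0L, 0L, 0L))

  set.seed(2)
  t20 <- sample(cls, 20, TRUE); p20 <- sample(cls, 20, TRUE)
  cm <- classConfusion(t20, p20, cls)
  for (i in cls) for (j in cls)
    expect_equal(cm$counts[i, j], sum(t20 == i & p20 == j))
  expect_error(classConfusion(c("NoHF", "weird"), c("NoHF", "NoHF"), cls),
               "unknown label")
})

test_that("percent rendering rounds half up to one decimal", {
  expect_equal(formatPercent(0.625), "62.5")
  expect_equal(formatPercent(0.96145), "96.1")
  expect_equal(formatPercent(0.94515), "94.5")
  expect_equal(formatPercent(0.0005), "0.1")   # half rounds up
})
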