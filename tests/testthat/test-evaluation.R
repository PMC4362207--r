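test_that("error matrices match a hand-rolled confusion loop", {
  set.seed(81)
  pv <- runif(300)
  lab <- sample(paste0("M", 1:5), 300, TRUE)
  e <- causalityErrorMatrix(pv, lab, alpha = 0.1)
  tp <- fp <- tn <- fn <- 0
  for (i in seq_along(pv)) {
    pos <- lab[i] %in% c("M1", "M4")
    call <- pv[i] <= 0.1
    if (call && pos) tp <- tp + 1 else if (call) fp <- fp + 1
    else if (pos) fn <- fn + 1 else tn <- tn + 1
  }
  expect_equal(unlist(e[c("TP", "FP", "TN", "FN")]),
               c(TP = tp, FP = fp, TN = tn, FN = fn))
  expect_equal(e$TP + e$FP + e$TN + e$FN, 300)
  # vacuous threshold
  e1 <- causalityErrorMatrix(pv, lab, alpha = 1)
  expect_equal(e1$TN + e1$FN, 0)
})

test_that("balanced accuracy and balanced FDR evaluate their formulas", {
  e <- errorMatrix(TP = 8, FN = 2, TN = 45, FP = 5)
  expect_equal(balancedAccuracy(e), (0.8 + 0.9) / 2)
  # frozen balanced-FDR example: pi0 = 92/8 = 11.5, FPa = 2/11.5,
  # FDR = FPa/(FPa + 8) = 0.021277
  e2 <- errorMatrix(TP = 8, FP = 2, TN = 90, FN = 0)
  expect_equal(balancedFdr(e2), 0.0212766, tolerance = 1e-6)
  # pi0 = 1 reduces to plain FDR
  e3 <- errorMatrix(TP = 10, FP = 4, TN = 10, FN = 4)
  expect_equal(balancedFdr(e3), 4 / 14)
  expect_equal(balancedFdr(errorMatrix(5, 0, 50, 5)), 0)
  expect_error(balancedFdr(errorMatrix(0, 3, 50, 0)), "positives")
  expect_error(balancedAccuracy(errorMatrix(0, 0, 50, 0)), "classes")

  set.seed(82)
  for (i in 1:30) {
    cts <- rpois(4, 20) + c(1, 0, 1, 0)
    e <- errorMatrix(cts[1], cts[2], cts[3], cts[4])
    tpr <- cts[1] / (cts[1] + cts[4]); tnr <- cts[3] / (cts[3] + cts[2])
    expect_equal(balancedAccuracy(e), (tpr + tnr) / 2)
    pi0 <- (cts[2] + cts[3]) / (cts[1] + cts[4])
    expect_equal(balancedFdr(e), (cts[2] / pi0) / (cts[2] / pi0 + cts[1]))
  }
})

test_that("AUC equals the Mann-Whitney pairwise oracle; behaves at extremes", {
  set.seed(83)
  pv <- runif(60)
  truth <- sample(c(TRUE, FALSE), 60, TRUE)
  # brute-force pairwise comparisons on score = -p with tie credit 1/2
  s <- -pv
  num <- 0
  for (i in which(truth)) for (j in which(!truth))
    num <- num + (s[i] > s[j]) + 0.5 * (s[i] == s[j])
  expect_equal(aucBroadSense(pv, truth), num / (sum(truth) * sum(!truth)),
               tolerance = 1e-12)
  expect_equal(aucBroadSense(c(0.01, 0.02, 0.8, 0.9),
                             c(TRUE, TRUE, FALSE, FALSE)), 1)
  # label-independent p-values hover near 1/2
  aucs <- replicate(50, aucBroadSense(runif(100), rep(c(TRUE, FALSE), 50)))
  expect_lt(abs(mean(aucs) - 0.5), 0.05)
  expect_error(aucBroadSense(pv, rep(TRUE, 60)), "both classes")
})

test_that("grouping error matrices: perfect, naive-vs-causal, hand toy", {
  truth <- list(
    s1 = list(traits = c("a", "b", "c", "r1", "i1"),
              causalTraits = c("a", "b", "c")),
    s2 = list(traits = c("d", "e", "r2", "i2"),
              causalTraits = c("d", "e")))
  universe <- c("a", "b", "c", "d", "e", "r1", "r2", "i1", "i2", "x")

  perfect <- list(c("a", "b", "c"), c("d", "e"))
  g <- groupingErrorMatrices(perfect, truth, universe)
  expect_equal(g$causal$FP + g$causal$FN, 0)

  # predicting full P(s) is perfect naively but accrues causal FPs
  full <- list(truth$s1$traits, truth$s2$traits)
  g2 <- groupingErrorMatrices(full, truth, universe)
  expect_equal(g2$naive$FP + g2$naive$FN, 0)
  expect_equal(g2$causal$FP, 4)               # r1, i1, r2, i2

  # hand-enumerated toy with an imperfect group and a decoy
  pred <- list(c("a", "b", "x"), c("d"))
  g3 <- groupingErrorMatrices(pred, truth, universe)
  # s1 matches group 1: TP {a,b}, FP {x}, FN {c}; s2 matches group 2:
  # TP {d}, FN {e}; causal TN = pooled remainder
  expect_equal(g3$causal$TP, 3)
  expect_equal(g3$causal$FP, 1)
  expect_equal(g3$causal$FN, 2)
  expect_equal(g3$causal$TN, 2 * length(universe) - 3 - 1 - 2)

  # no predictions: everything positive becomes FN
  g4 <- groupingErrorMatrices(list(), truth, universe)
  expect_equal(g4$causal$TP, 0)
  expect_equal(g4$causal$FN, 5)
})

test_that("largest-intersection matching breaks ties deterministically", {
  truth <- list(s1 = list(traits = c("a", "b"), causalTraits = c("a", "b")))
  # both groups intersect in 1; the smaller group wins
  g <- groupingErrorMatrices(list(c("a", "z", "y"), c("b")), truth,
                             c("a", "b", "y", "z"))
  expect_equal(g$matched, 2L)
  # equal size: lexicographically first member id wins
  g2 <- groupingErrorMatrices(list(c("b", "z"), c("a", "y")), truth,
                              c("a", "b", "y", "z"))
  expect_equal(g2$matched, 2L)
})

test_that("triplet causality benchmark wires metrics together", {
  tri <- simulateTriplets(perModelCount = 8, lambda = 0.6, sigma = 0.3,
                          seed = 84)
  b <- benchmarkCausality(tri, B = 100, seed = 85)
  expect_length(b$pvals, 40)
  expect_equal(b$auc, aucBroadSense(b$pvals, tri$causal))
  expect_equal(b$balancedFdr, balancedFdr(b$errorMatrix))
  # in the identifiable regime the chain models beat the nulls (M5, whose
  # direct variant-transcript edge survives conditioning, is the intrinsic
  # false-positive mode of the broad-sense definition)
  expect_gt(b$auc, 0.7)
})
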