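# Accuracy, Cohen's kappa, per-class metrics, ROC/AUC.

test_that("confusion matrix counts by (true, predicted)", {
  cm <- confusionCounts(c("a", "b", "a", "a"), c("a", "b", "b", "a"),
                        c("a", "b"))
  expect_identical(cm, matrix(c(2L, 0L, 1L, 1L), 2, 2,
                              dimnames = list(true = c("a", "b"),
                                              predicted = c("a", "b"))))
  # identical lists give a diagonal matrix
  cm2 <- confusionCounts(letters[1:3], letters[1:3])
  expect_equal(sum(cm2) - sum(diag(cm2)), 0)
  # one mislabel -> exactly one off-diagonal count
  cm3 <- confusionCounts(c("a", "a", "b"), c("a", "b", "b"))
  expect_equal(sum(cm3[row(cm3) != col(cm3)]), 1)
  expect_error(confusionCounts("a", "z", classes = c("a", "b")), "z")
})

test_that("overall accuracy, expected accuracy and kappa follow the formulas", {
  perfect <- confusionCounts(rep(c("a", "b"), 10), rep(c("a", "b"), 10))
  m <- overallMetrics(perfect)
  expect_equal(m$accuracy, 1)
  expect_equal(m$kappa, 1)

  indep <- matrix(c(25, 25, 25, 25), 2, 2,
                  dimnames = list(c("a", "b"), c("a", "b")))
  m2 <- overallMetrics(indep)
  expect_equal(m2$accuracy, 0.5)
  expect_equal(m2$expected_accuracy, 0.5)
  expect_equal(m2$kappa, 0)

  # hand-computed: Po = 0.7, Pe = (40*50 + 60*50)/100^2 = 0.5, kappa = 0.4
  cm <- matrix(c(30, 20, 10, 40), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  m3 <- overallMetrics(cm)
  expect_equal(m3$accuracy, 0.7)
  expect_equal(m3$expected_accuracy, 0.5)
  expect_equal(m3$kappa, 0.4)

  # degenerate single-cell matrix: kappa undefined
  expect_error(overallMetrics(matrix(5, 1, 1, dimnames = list("a", "a"))),
               "undefined")
})

test_that("kappa is 1 only for perfect tables and ~0 under independence", {
  set.seed(81)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    n <- 200
    truth <- sample(letters[1:k], n, replace = TRUE)
    pred <- truth
    flip <- sample(n, sample(0:20, 1))
    pred[flip] <- sample(letters[1:k], length(flip), replace = TRUE)
    cm <- confusionCounts(truth, pred, letters[1:k])
    m <- overallMetrics(cm)
    offDiag <- sum(cm) - sum(diag(cm))
    expect_equal(m$kappa == 1, offDiag == 0)
  }
  truth <- sample(mobClasses(), 10000, replace = TRUE)
  pred <- sample(mobClasses(), 10000, replace = TRUE)
  m <- overallMetrics(confusionCounts(truth, pred, mobClasses()))
  expect_lt(abs(m$kappa), 0.05)
})

test_that("per-class one-vs-rest metrics follow the stated formulas", {
  cm <- matrix(c(30, 20, 10, 40), 2, 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  # class b: TP=40, FN=20, FP=10, TN=30
  m <- classMetrics(cm, "b")
  expect_equal(m$tpr, 40 / 60)
  expect_equal(m$tnr, 30 / 40)
  expect_equal(m$precision, 40 / 50)
  expect_equal(m$balanced_accuracy, (40 / 60 + 30 / 40) / 2)
  expect_equal(m$harmonic_mean, 2 * (40 / 60) * (30 / 40) / (40 / 60 + 30 / 40))
  expect_equal(m$f1, 2 * 0.8 * (40 / 60) / (0.8 + 40 / 60))
  # class a: TPR = 30/40 = 0.75, TNR = 40/60; balanced accuracy 0.7083
  ma <- classMetrics(cm, "a")
  expect_equal(ma$tpr, 0.75)
  expect_equal(ma$balanced_accuracy, (0.75 + 40 / 60) / 2)

  perfect <- confusionCounts(rep(c("a", "b"), 5), rep(c("a", "b"), 5))
  mp <- classMetrics(perfect, "a")
  expect_equal(mp$balanced_accuracy, 1)
  expect_equal(mp$harmonic_mean, 1)
  expect_equal(mp$f1, 1)

  # class never true and never predicted: zeros with degenerate flag
  cm3 <- confusionCounts(c("a", "b"), c("a", "b"), c("a", "b", "c"))
  mc <- classMetrics(cm3, "c")
  expect_true(mc$degenerate)
  expect_equal(mc$f1, 0)
  expect_equal(mc$harmonic_mean, 0)
  expect_error(classMetrics(cm3, "z"), "unknown class")
})

test_that("ROC curve and trapezoid AUC match hand-derived values", {
  # brute-force pair counting: 3 of 4 positive-negative pairs ordered
  r <- rocCurve(c(0.9, 0.8, 0.3, 0.1), c(TRUE, FALSE, TRUE, FALSE))
  expect_equal(r$auc, 0.75)
  expect_equal(r$points$fpr[1], 0)
  expect_equal(r$points$tpr[nrow(r$points)], 1)

  # perfect separation and all-tied scores
  expect_equal(rocCurve(c(5, 4, 1, 0), c(TRUE, TRUE, FALSE, FALSE))$auc, 1)
  expect_equal(rocCurve(rep(0.5, 6), c(TRUE, FALSE, TRUE, FALSE, TRUE,
                                       FALSE))$auc, 0.5)
  expect_error(rocCurve(c(1, 2), c(TRUE, TRUE)), "undefined")
})

test_that("trapezoid AUC equals pair-counting AUC on random instances", {
  pairAUC <- function(scores, truth) {
    pos <- scores[truth]; neg <- scores[!truth]
    total <- 0
    for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
    total / (length(pos) * length(neg))
  }
  set.seed(91)
  for (i in 1:100) {
    n <- sample(5:30, 1)
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    r <- rocCurve(scores, truth)
    expect_equal(r$auc, pairAUC(scores, truth), tolerance = 1e-12)
    expect_true(all(diff(r$points$fpr) >= 0))
    expect_true(all(diff(r$points$tpr) >= 0))
  }
})

test_that("AUC agrees with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(92)
  for (i in 1:5) {
    truth <- c(TRUE, FALSE, sample(c(TRUE, FALSE), 40, replace = TRUE))
    scores <- round(runif(42), 2)
    ref <- as.numeric(pROC::auc(pROC::roc(response = truth,
                                          predictor = scores, quiet = TRUE,
                                          direction = "<")))
    expect_equal(rocCurve(scores, truth)$auc, ref, tolerance = 1e-12)
  }
})

test_that("balanced accuracy equals accuracy for balanced symmetric errors", {
  cm <- matrix(c(40, 10, 10, 40), 2, 2, dimnames = list(c("a", "b"),
                                                        c("a", "b")))
  m <- overallMetrics(cm)
  expect_equal(classMetrics(cm, "a")$balanced_accuracy, m$accuracy)
  expect_equal(classMetrics(cm, "b")$balanced_accuracy, m$accuracy)
})

test_that("evaluatePredictions assembles the full suite", {
  w <- toyWorld()
  te <- w$genomes[w$split == "test"]
  fr <- sampleFragments(te, c(801, 1200), 15, seed = 401)
  pred <- predictMob(fr, w$ens)
  ev <- evaluatePredictions(pred, S4Vectors::mcols(fr)$true_class,
                            classes = w$classes)
  expect_equal(sum(ev$confusion), nrow(pred) - ev$n_unclassified)
  expect_equal(nrow(ev$per_class), length(w$classes))
  expect_true(all(vapply(ev$roc, function(r) r$auc, numeric(1)) >= 0))
})
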