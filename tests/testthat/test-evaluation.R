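test_that("perfect, chance and constant predictions score as expected", {
  y <- rep(c("wake", "light", "deep", "REM"), each = 25)
  perf <- scoreClassifier(y, y)
  expect_equal(perf@accuracy, 1)
  expect_equal(perf@kappa, 1)
  expect_equal(perf@matthews, 1)
  const <- scoreClassifier(y, rep("light", 100))
  expect_equal(const@accuracy, 0.25)
  expect_equal(const@kappa, 0)
  expect_equal(const@matthews, 0)
  expect_error(scoreClassifier(character(0), character(0)), "empty")
})

test_that("metrics match the definitional oracle on a fixed confusion matrix", {
  # 4x4 fixture with known counts, expanded into label vectors
  cm <- matrix(c(50, 3, 2, 5,
                 4, 120, 18, 8,
                 1, 10, 40, 2,
                 5, 7, 3, 45), 4, 4, byrow = TRUE)
  lev <- c("wake", "light", "deep", "REM")
  yTrue <- yPred <- character(0)
  for (i in 1:4) for (j in 1:4) {
    yPred <- c(yPred, rep(lev[i], cm[i, j]))
    yTrue <- c(yTrue, rep(lev[j], cm[i, j]))
  }
  rep_ <- scoreClassifier(yTrue, yPred)
  orc <- oracleMetrics(yTrue, yPred)
  expect_equal(rep_@accuracy, orc$acc)
  expect_equal(rep_@precisionW, orc$precW)
  expect_equal(rep_@recallW, orc$recW)
  expect_equal(rep_@f1W, orc$f1W)
  expect_equal(rep_@kappa, orc$kappa)
  # independent kappa cross-check
  ca <- e1071::classAgreement(table(yPred, yTrue))
  expect_equal(rep_@kappa, ca$kappa)
  expect_equal(sum(confusionMatrix(rep_)), rep_@nTest)
})

test_that("weighted recall is identically the accuracy", {
  for (s in 1:25) {
    fx <- randomLabels(60, sample(2:5, 1), seed = s)
    r <- scoreClassifier(fx$truth, fx$pred)
    expect_equal(r@recallW, r@accuracy)
    expect_lte(abs(r@kappa), 1)
  }
})

test_that("metrics are invariant to a consistent label permutation", {
  fx <- randomLabels(200, 4, seed = 3)
  r1 <- metrics(scoreClassifier(fx$truth, fx$pred))
  perm <- c(s1 = "s3", s2 = "s4", s3 = "s1", s4 = "s2")
  r2 <- metrics(scoreClassifier(perm[fx$truth], perm[fx$pred]))
  expect_equal(r1[c("acc", "prc", "recall", "kappa", "f1", "mc")],
               r2[c("acc", "prc", "recall", "kappa", "f1", "mc")])
})

test_that("rmse scores probabilistic outputs against one-hot truth", {
  y <- c("a", "b")
  p <- matrix(c(1, 0, 0, 1), 2, 2, byrow = TRUE,
              dimnames = list(NULL, c("a", "b")))
  expect_equal(scoreClassifier(y, y, probabilities = p)@rmse, 0)
  pu <- matrix(0.5, 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_equal(scoreClassifier(y, y, probabilities = pu)@rmse, 0.5)
})

test_that("imbalance report sums to one and recounts the labels", {
  bal <- imbalanceReport(rep(c("wake", "light", "deep", "REM"), 10))
  expect_true(all(bal$fraction == 0.25))
  one <- imbalanceReport(rep("light", 7))
  expect_equal(one$fraction, 1)
  set.seed(4)
  lab <- sample(c("wake", "light"), 300, replace = TRUE, prob = c(0.2, 0.8))
  rep_ <- imbalanceReport(lab)
  expect_equal(sum(rep_$fraction), 1)
  expect_equal(rep_$count[rep_$stage == "wake"], sum(lab == "wake"))
})

test_that("sweep summary picks the first ns attaining maximum accuracy", {
  mkRep <- function(ns, acc) {
    y <- rep(c("a", "b"), each = 50)
    nWrong <- round((1 - acc) * 100)
    pred <- y
    pred[seq_len(nWrong)] <- ifelse(y[seq_len(nWrong)] == "a", "b", "a")
    scoreClassifier(y, pred, metadata = list(ns = ns))
  }
  reports <- list(mkRep(1, 0.6), mkRep(2, 0.9), mkRep(3, 0.9), mkRep(4, 0.8))
  expect_message(sweepSummary(reports), "tie")
  s <- suppressMessages(sweepSummary(reports))
  expect_equal(s$bestNs, 2)
  expect_equal(s$bestAccuracy, 0.9)
  expect_equal(nrow(s$top3), 3L)
  # order invariance
  s2 <- suppressMessages(sweepSummary(reports[c(3, 1, 4, 2)]))
  expect_equal(s2$bestNs, s$bestNs)
  expect_equal(s2$table, s$table)
  # monotone accuracies -> best is the last ns
  mono <- list(mkRep(1, 0.5), mkRep(2, 0.7), mkRep(3, 0.9))
  expect_equal(sweepSummary(mono)$bestNs, 3)
})

test_that("hypnogram comparison measures per-stage agreement", {
  cfg <- fastGenConfig()
  hyp <- generateHypnogram(cfg, seed = 21)
  same <- hypnogramCompare(hyp, hyp)
  expect_equal(same$agreement, 1)
  expect_true(all(same$perStage$recall == 1))
  # shifting by one epoch leaves only within-run epochs agreeing
  st <- as.character(stages(hyp))
  shifted <- c(st[1], st[-length(st)])
  pred <- EpochTable(epochTimestamps(hyp), epochInterval(hyp),
                     data.frame(stage = shifted))
  cmp <- hypnogramCompare(hyp, pred)
  expect_equal(cmp$agreement, mean(st == shifted))
  r <- rle(st)
  expect_equal(cmp$agreement, (length(st) - length(r$lengths) + 1) / length(st))
  other <- EpochTable(epochTimestamps(hyp), epochInterval(hyp),
                      data.frame(stage = rep("unscored", nEpochs(hyp))))
  expect_equal(hypnogramCompare(hyp, other)$agreement, 0)
})
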