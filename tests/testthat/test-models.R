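test_that("stratified split preserves class proportions and is deterministic", {
  df <- toyFeatureFrame(100, seed = 11)
  df$stage <- rep(c("wake", "light", "deep", "REM"), 25)
  ds <- makeWindows(df, 0)
  sp <- splitData(ds, 0.75, seed = 3)
  expect_lte(abs(length(sp$train@labels) - 75L), 2L)
  tr <- table(sp$train@labels)
  expect_true(all(abs(tr - 0.75 * 25) <= 1))
  sp2 <- splitData(ds, 0.75, seed = 3)
  expect_identical(sp$trainIdx, sp2$trainIdx)
  expect_false(identical(sp$trainIdx,
                         splitData(ds, 0.75, seed = 4)$trainIdx))
})

test_that("subject-held-out split never spans a subject across sides", {
  df <- toyFeatureFrame(60, seed = 12)
  df$patientId <- rep(1:3, each = 20)
  ds <- makeWindows(df, 0)
  subj <- df$patientId
  sp <- splitData(ds, 0.67, strategy = "subject_held_out", seed = 2,
                  subjects = subj)
  expect_equal(length(intersect(unique(subj[sp$trainIdx]),
                                unique(subj[sp$testIdx]))), 0L)
})

test_that("every engine separates a linearly separable toy problem", {
  set.seed(13)
  n <- 80
  x <- rbind(matrix(rnorm(n, 3), n / 2, 2), matrix(rnorm(n, -3), n / 2, 2))
  colnames(x) <- c("a", "b")
  y <- factor(rep(c("p", "q"), each = n / 2))
  for (eng in c("LR", "RF", "kNN", "SVM", "MLP")) {
    fit <- fitMemoryless(x, y, engine = eng, grid = NULL, seed = 1)
    expect_equal(mean(predict(fit, x) == y), 1, info = eng)
  }
  expect_error(fitMemoryless(x, factor(rep("p", n)), "RF"), "single class")
})

test_that("grid selection returns the single point of a unit grid", {
  set.seed(14)
  x <- matrix(rnorm(60), 30, 2, dimnames = list(NULL, c("a", "b")))
  y <- factor(sample(c("p", "q"), 30, replace = TRUE))
  fit <- fitMemoryless(x, y, "kNN", grid = list(list(k = 3)))
  expect_equal(fit@gridPoint$k, 3)
  expect_true(is.na(fit@cvScore))
})

test_that("label shuffling leaves no skill in the windowing/split machinery", {
  cfg <- fastGenConfig()
  nights <- generateNights(cfg, 4, seed = 7, signals = TRUE)
  tab0 <- assembleNights(nights)
  for (r in 1:3) {
    tab <- tab0
    set.seed(15 + r)
    tab$stage <- sample(tab$stage)         # break the feature-label link
    ds <- makeWindows(tab, 2, featureCols = featureSet)
    sp <- splitData(ds, seed = 5)
    f <- flattenWindows(sp$train); fte <- flattenWindows(sp$test)
    fit <- fitMemoryless(f$x, f$y, "RF",
                         grid = list(list(ntree = 80, mtry = 2)))
    r_ <- scoreClassifier(fte$y, predict(fit, fte$x))
    base <- max(table(fte$y)) / length(fte$y)
    # no model beats the majority rate on destroyed labels, and the
    # chance-corrected agreement sits at zero
    expect_lt(r_@accuracy - base, 0.05)
    expect_lt(abs(r_@kappa), 0.06)
  }
})

test_that("memory sweep returns one scored report per ns", {
  cfg <- fastGenConfig()
  nights <- generateNights(cfg, 3, seed = 22, signals = TRUE)
  tab <- assembleNights(nights)
  sw <- memorySweep(tab, c(1, 3), model = "RF",
                    grid = list(list(ntree = 60, mtry = 2)),
                    seed = 2, featureCols = featureSet)
  expect_length(sw$reports, 2L)
  expect_equal(sw$summary$table$ns, c(1, 3))
  expect_true(sw$summary$bestNs %in% c(1, 3))
  single <- memorySweep(tab, 1, model = "RF",
                        grid = list(list(ntree = 60, mtry = 2)),
                        seed = 2, featureCols = featureSet)
  expect_length(single$reports, 1L)
})

test_that("sequence prediction emits a full night aligned with the truth", {
  cfg <- fastGenConfig()
  nights <- generateNights(cfg, 4, seed = 31, signals = TRUE)
  tab <- assembleNights(nights[1:3])
  ns <- 4L
  ds <- makeWindows(tab, ns, featureCols = featureSet)
  f <- flattenWindows(ds)
  fit <- fitMemoryless(f$x, f$y, "RF", grid = list(list(ntree = 100, mtry = 3)))
  night4 <- nightFeatureTable(nights[[4]], patientId = 4L)
  truth <- EpochTable(night4$time, 60, data.frame(stage = night4$stage))
  predHyp <- predictSequence(fit, EpochTable(night4$time, 60,
                                             night4[-1]), ns = ns,
                             featureCols = featureSet)
  expect_equal(nEpochs(predHyp), nEpochs(truth))
  cmp <- hypnogramCompare(truth, predHyp)
  expect_gt(cmp$agreement, 0.4)
  # transition structure is in the right ballpark (smoke property)
  nTrans <- function(x) sum(diff(as.integer(factor(as.character(stages(x))))) != 0)
  expect_lt(nTrans(predHyp), 3 * max(nTrans(truth), 1) + 20)
})
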