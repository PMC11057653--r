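zeroParams <- function(F, H, C) {
  p <- lstmInit(F, H, C, seed = 1)
  lapply(p, function(m) m * 0)
}

test_that("zero weights propagate to zero states and uniform probabilities", {
  p <- zeroParams(2, 4, 4)
  set.seed(1)
  fw <- lstmForward(matrix(rnorm(10), 5, 2), p)
  expect_true(all(fw$hSeq == 0))
  expect_true(all(fw$cSeq == 0))
  expect_equal(fw$probs, rep(0.25, 4))
})

test_that("a two-step scalar network matches a hand-evaluated composition", {
  sig <- function(z) 1 / (1 + exp(-z))
  p <- list(Wf = matrix(0.5), Wi = matrix(-0.3), Wo = matrix(0.7),
            Wc = matrix(1.0), Uf = matrix(0.2), Ui = matrix(0.4),
            Uo = matrix(-0.1), Uc = matrix(0.5),
            bf = 0.1, bi = 0, bo = 0.2, bc = -0.2,
            V = matrix(c(1, -1), 2, 1), by = c(0, 0))
  x <- matrix(c(0.3, -0.6), 2, 1)
  # step 1, written out longhand
  f1 <- sig(0.5 * 0.3 + 0.1); i1 <- sig(-0.3 * 0.3)
  o1 <- sig(0.7 * 0.3 + 0.2); g1 <- tanh(1.0 * 0.3 - 0.2)
  c1 <- i1 * g1
  h1 <- o1 * tanh(c1)
  # step 2
  f2 <- sig(0.5 * -0.6 + 0.2 * h1 + 0.1); i2 <- sig(-0.3 * -0.6 + 0.4 * h1)
  o2 <- sig(0.7 * -0.6 - 0.1 * h1 + 0.2); g2 <- tanh(1.0 * -0.6 + 0.5 * h1 - 0.2)
  c2 <- i2 * g2 + f2 * c1
  h2 <- o2 * tanh(c2)
  fw <- lstmForward(x, p)
  expect_equal(fw$hSeq[1, 1], h1, tolerance = 1e-12)
  expect_equal(fw$hSeq[2, 1], h2, tolerance = 1e-12)
  expect_equal(fw$cSeq[2, 1], c2, tolerance = 1e-12)
  e <- exp(c(h2, -h2) - max(h2, -h2))
  expect_equal(fw$probs, e / sum(e), tolerance = 1e-12)
})

test_that("gate outputs stay in (0,1) and hidden states inside (-1,1)", {
  set.seed(12)
  p <- lstmInit(3, 5, 4, seed = 2)
  p <- lapply(p, function(m) m * 10)      # extreme weights
  fw <- lstmForward(matrix(rnorm(30, sd = 3), 10, 3), p)
  expect_true(all(abs(fw$hSeq) < 1))
})

test_that("cross-entropy closed forms hold and batches average", {
  expect_equal(lstmLoss(matrix(c(1, 0, 0, 0)), 1), 0)
  expect_equal(lstmLoss(matrix(rep(0.25, 4)), 3), log(4))
  p2 <- cbind(c(0.7, 0.2, 0.1), c(0.1, 0.8, 0.1))
  expect_equal(lstmLoss(p2, c(1, 2)),
               mean(c(-log(0.7), -log(0.8))))
  # zero probability at the true class is clipped, not infinite
  expect_true(is.finite(lstmLoss(matrix(c(0, 1)), 1)))
})

test_that("BPTT gradients match central finite differences", {
  set.seed(31)
  H <- 3; F <- 2; T <- 3; C <- 4; B <- 2
  params <- lstmInit(F, H, C, seed = 31)
  params <- lapply(params, function(p)
    if (is.matrix(p)) matrix(rnorm(length(p), 0, 0.4), nrow(p))
    else rnorm(length(p), 0, 0.2))
  X <- array(rnorm(B * T * F), dim = c(B, T, F))
  Y <- matrix(0, C, B); Y[cbind(c(2, 4), 1:2)] <- 1
  an <- SleepStaging:::lstmGradients(params, X, Y)
  eps <- 1e-5
  maxRel <- 0
  for (k in names(params)) for (idx in seq_along(params[[k]])) {
    pp <- params; pp[[k]][idx] <- pp[[k]][idx] + eps
    pm <- params; pm[[k]][idx] <- pm[[k]][idx] - eps
    fd <- (SleepStaging:::lstmGradients(pp, X, Y)$loss -
             SleepStaging:::lstmGradients(pm, X, Y)$loss) / (2 * eps)
    rel <- abs(fd - an$grads[[k]][idx]) / max(1e-8, abs(fd) + abs(an$grads[[k]][idx]))
    maxRel <- max(maxRel, rel)
  }
  expect_lt(maxRel, 1e-4)
  # the sigmoid-candidate variant is differentiated correctly too
  anS <- SleepStaging:::lstmGradients(params, X, Y, "sigmoid")
  ppS <- params; ppS$Wc[1] <- ppS$Wc[1] + eps
  pmS <- params; pmS$Wc[1] <- pmS$Wc[1] - eps
  fdS <- (SleepStaging:::lstmGradients(ppS, X, Y, "sigmoid")$loss -
            SleepStaging:::lstmGradients(pmS, X, Y, "sigmoid")$loss) / (2 * eps)
  expect_lt(abs(fdS - anS$grads$Wc[1]) / max(1e-8, abs(fdS)), 1e-4)
})

test_that("training converges on a separable sequence task, deterministically", {
  # class depends on the sign of the lagged feature: solvable with memory
  set.seed(41)
  n <- 300; steps <- 3L
  X <- array(rnorm(n * steps * 2), dim = c(n, steps, 2),
             dimnames = list(NULL, NULL, c("u", "v")))
  y <- factor(ifelse(X[, 1, 1] > 0, "a", "b"))
  ds <- new("WindowedDataset", ns = steps - 1L, sequences = X, labels = y,
            featureNames = c("u", "v"))
  cfg <- trainConfig(hiddenSize = 6, epochs = 40, learningRate = 0.02,
                     batchSize = 64, seed = 5, scale = FALSE)
  m1 <- trainLSTM(ds, cfg)
  expect_lt(tail(m1@lossHistory, 1), 0.1 * m1@lossHistory[1])
  m2 <- trainLSTM(ds, cfg)
  expect_identical(m1@lossHistory, m2@lossHistory)
  expect_identical(m1@params, m2@params)
  acc <- mean(predict(m1, ds) == y)
  expect_gt(acc, 0.95)
  probs <- predict(m1, ds, type = "prob")
  expect_equal(rowSums(probs), rep(1, n), tolerance = 1e-12)
})
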