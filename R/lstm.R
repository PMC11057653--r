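## LSTM from first principles. Gates:
##   f_t = sig(Wf x_t + Uf h_{t-1} + bf)
##   i_t = sig(Wi x_t + Ui h_{t-1} + bi)
##   o_t = sig(Wo x_t + Uo h_{t-1} + bo)
##   cbar_t = act(Wc x_t + Uc h_{t-1} + bc)   (act = tanh, sigmoid variant kept)
##   c_t = i_t * cbar_t + f_t * c_{t-1}
##   h_t = o_t * tanh(c_t)
## Terminal h feeds a dense softmax readout; loss is categorical
## cross-entropy; training is full backpropagation through time with Adam.
## All state is (hidden x batch) matrices so training is vectorized over the
## mini-batch.

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Initialize LSTM parameters
#'
#' Small uniform random weights in `[-0.08, 0.08]`, zero biases.
#'
#' @param nFeatures input width.
#' @param hiddenSize hidden width.
#' @param nClasses readout width.
#' @param seed integer seed.
#' @return named list of gate matrices `Wf..Wc` (hidden x features),
#'   recurrent matrices `Uf..Uc` (hidden x hidden), biases `bf..bc`, and
#'   readout `V` (classes x hidden), `by`.
#' @export
lstmInit <- function(nFeatures, hiddenSize, nClasses, seed = 1L) {
  set.seed(seed)
  r <- function(nr, nc) matrix(runif(nr * nc, -0.08, 0.08), nr, nc)
  H <- hiddenSize; F <- nFeatures; C <- nClasses
  list(Wf = r(H, F), Wi = r(H, F), Wo = r(H, F), Wc = r(H, F),
       Uf = r(H, H), Ui = r(H, H), Uo = r(H, H), Uc = r(H, H),
       bf = numeric(H), bi = numeric(H), bo = numeric(H), bc = numeric(H),
       V = r(C, H), by = numeric(C))
}

## Batched forward pass with caches for BPTT.
## X: array (B, T, F). Returns probs (C x B) and per-step caches.
lstmForwardBatch <- function(X, params, candidateActivation = "tanh",
                             keepCache = TRUE) {
  d <- dim(X); B <- d[1]; T <- d[2]
  H <- nrow(params$Wf)
  h <- matrix(0, H, B); c_ <- matrix(0, H, B)
  cache <- if (keepCache) vector("list", T)
  for (t in seq_len(T)) {
    Xt <- t(matrix(X[, t, ], nrow = B))          # F x B
    f <- sigmoid(params$Wf %*% Xt + params$Uf %*% h + params$bf)
    i <- sigmoid(params$Wi %*% Xt + params$Ui %*% h + params$bi)
    o <- sigmoid(params$Wo %*% Xt + params$Uo %*% h + params$bo)
    a <- params$Wc %*% Xt + params$Uc %*% h + params$bc
    cbar <- if (candidateActivation == "tanh") tanh(a) else sigmoid(a)
    cPrev <- c_; hPrev <- h
    c_ <- i * cbar + f * cPrev
    tc <- tanh(c_)
    h <- o * tc
    if (any(!is.finite(h)))
      stop("non-finite LSTM activations at step ", t)
    if (keepCache)
      cache[[t]] <- list(Xt = Xt, f = f, i = i, o = o, cbar = cbar,
                         c = c_, tc = tc, cPrev = cPrev, hPrev = hPrev)
  }
  logits <- params$V %*% h + params$by          # C x B
  m <- apply(logits, 2, max)
  e <- exp(sweep(logits, 2, m))
  probs <- sweep(e, 2, colSums(e), "/")
  list(probs = probs, hT = h, cT = c_, cache = cache)
}

#' LSTM forward pass over one sequence
#'
#' @param xSeq matrix of feature vectors, one row per time step.
#' @param params parameter list from [lstmInit()] (or an
#'   [LSTMModel-class]'s `params`).
#' @param h0,c0 initial hidden / cell state (default zeros).
#' @param candidateActivation `"tanh"` (standard) or `"sigmoid"`.
#' @return list with `hSeq`, `cSeq` (steps x hidden) and `probs` (named
#'   class probabilities from the terminal hidden state).
#' @export
lstmForward <- function(xSeq, params, h0 = NULL, c0 = NULL,
                        candidateActivation = c("tanh", "sigmoid")) {
  candidateActivation <- match.arg(candidateActivation)
  xSeq <- as.matrix(xSeq)
  T <- nrow(xSeq); H <- nrow(params$Wf)
  h <- if (is.null(h0)) numeric(H) else h0
  c_ <- if (is.null(c0)) numeric(H) else c0
  hSeq <- matrix(0, T, H); cSeq <- matrix(0, T, H)
  for (t in seq_len(T)) {
    x <- xSeq[t, ]
    f <- sigmoid(params$Wf %*% x + params$Uf %*% h + params$bf)
    i <- sigmoid(params$Wi %*% x + params$Ui %*% h + params$bi)
    o <- sigmoid(params$Wo %*% x + params$Uo %*% h + params$bo)
    a <- params$Wc %*% x + params$Uc %*% h + params$bc
    cbar <- if (candidateActivation == "tanh") tanh(a) else sigmoid(a)
    c_ <- as.numeric(i * cbar + f * c_)
    h <- as.numeric(o * tanh(c_))
    if (any(!is.finite(h))) stop("non-finite LSTM activations at step ", t)
    hSeq[t, ] <- h; cSeq[t, ] <- c_
  }
  logits <- as.numeric(params$V %*% h + params$by)
  e <- exp(logits - max(logits))
  list(hSeq = hSeq, cSeq = cSeq, probs = e / sum(e))
}

#' Categorical cross-entropy
#'
#' `-mean(log p(true class))`, probabilities clipped at `eps` so a zero
#' probability on the true class stays finite.
#'
#' @param probabilities matrix (classes x cases) or vector of class
#'   probabilities.
#' @param yIdx integer index of the true class per case.
#' @param eps clip floor (default 1e-12).
#' @return scalar mean loss.
#' @export
lstmLoss <- function(probabilities, yIdx, eps = 1e-12) {
  p <- as.matrix(probabilities)
  pt <- p[cbind(yIdx, seq_len(ncol(p)))]
  -mean(log(pmax(pt, eps)))
}

## Loss + gradients for a batch. Y: one-hot C x B.
lstmGradients <- function(params, X, Y, candidateActivation = "tanh") {
  fw <- lstmForwardBatch(X, params, candidateActivation)
  B <- ncol(Y)
  yIdx <- max.col(t(Y))
  loss <- lstmLoss(fw$probs, yIdx)
  g <- lapply(params, function(p) p * 0)

  dlogits <- (fw$probs - Y) / B                 # C x B
  g$V <- dlogits %*% t(fw$hT)
  g$by <- rowSums(dlogits)
  dh <- t(params$V) %*% dlogits                 # H x B
  dc <- matrix(0, nrow(dh), ncol(dh))
  for (t in rev(seq_along(fw$cache))) {
    cc <- fw$cache[[t]]
    do_ <- dh * cc$tc
    dc <- dc + dh * cc$o * (1 - cc$tc^2)
    dzo <- do_ * cc$o * (1 - cc$o)
    dcbar <- dc * cc$i
    dza <- if (candidateActivation == "tanh") dcbar * (1 - cc$cbar^2)
           else dcbar * cc$cbar * (1 - cc$cbar)
    di <- dc * cc$cbar
    dzi <- di * cc$i * (1 - cc$i)
    df <- dc * cc$cPrev
    dzf <- df * cc$f * (1 - cc$f)
    g$Wf <- g$Wf + dzf %*% t(cc$Xt); g$Uf <- g$Uf + dzf %*% t(cc$hPrev)
    g$Wi <- g$Wi + dzi %*% t(cc$Xt); g$Ui <- g$Ui + dzi %*% t(cc$hPrev)
    g$Wo <- g$Wo + dzo %*% t(cc$Xt); g$Uo <- g$Uo + dzo %*% t(cc$hPrev)
    g$Wc <- g$Wc + dza %*% t(cc$Xt); g$Uc <- g$Uc + dza %*% t(cc$hPrev)
    g$bf <- g$bf + rowSums(dzf); g$bi <- g$bi + rowSums(dzi)
    g$bo <- g$bo + rowSums(dzo); g$bc <- g$bc + rowSums(dza)
    dh <- t(params$Uf) %*% dzf + t(params$Ui) %*% dzi +
      t(params$Uo) %*% dzo + t(params$Uc) %*% dza
    dc <- dc * cc$f
  }
  list(loss = loss, grads = g)
}

#' Training configuration for the LSTM
#'
#' @param hiddenSize hidden width (default 16).
#' @param epochs training epochs (default 50).
#' @param learningRate Adam step size (canonical 0.001).
#' @param beta1,beta2,epsilon Adam moment rates and stabilizer.
#' @param batchSize mini-batch size (default 128).
#' @param seed integer seed (initialization and shuffling).
#' @param candidateActivation `"tanh"` or `"sigmoid"` candidate gate.
#' @param scale min-max scale features on the training set?
#' @return named list of training settings.
#' @export
trainConfig <- function(hiddenSize = 16L, epochs = 50L, learningRate = 0.001,
                        beta1 = 0.9, beta2 = 0.999, epsilon = 1e-8,
                        batchSize = 128L, seed = 1L,
                        candidateActivation = c("tanh", "sigmoid"),
                        scale = TRUE) {
  stopifnot(epochs >= 1)
  list(hiddenSize = as.integer(hiddenSize), epochs = as.integer(epochs),
       learningRate = learningRate, beta1 = beta1, beta2 = beta2,
       epsilon = epsilon, batchSize = as.integer(batchSize),
       seed = as.integer(seed),
       candidateActivation = match.arg(candidateActivation), scale = scale)
}

scaleSequences <- function(arr, scaler = NULL) {
  F <- dim(arr)[3]
  if (is.null(scaler)) {
    mins <- vapply(seq_len(F), function(j) min(arr[, , j]), numeric(1))
    maxs <- vapply(seq_len(F), function(j) max(arr[, , j]), numeric(1))
    names(mins) <- names(maxs) <- dimnames(arr)[[3]]
    scaler <- list(mins = mins, maxs = maxs)
  }
  for (j in seq_len(F)) {
    rng <- scaler$maxs[j] - scaler$mins[j]
    arr[, , j] <- if (rng == 0) 0 else (arr[, , j] - scaler$mins[j]) / rng
  }
  list(arr = arr, scaler = scaler)
}

#' Train the LSTM by backpropagation through time
#'
#' Mini-batch Adam on the categorical cross-entropy of the terminal softmax
#' readout. Deterministic given `config$seed`. Aborts with diagnostics if
#' the epoch loss exceeds 10x the initial loss.
#'
#' @param train a [WindowedDataset-class].
#' @param config a [trainConfig()] list.
#' @return an [LSTMModel-class] with per-epoch `lossHistory`.
#' @export
trainLSTM <- function(train, config = trainConfig()) {
  stopifnot(is(train, "WindowedDataset"))
  arr <- train@sequences
  scaler <- NULL
  if (isTRUE(config$scale)) {
    sc <- scaleSequences(arr)
    arr <- sc$arr; scaler <- sc$scaler
  }
  y <- droplevels(train@labels)
  lev <- levels(y)
  C <- length(lev)
  n <- dim(arr)[1]; F <- dim(arr)[3]
  params <- lstmInit(F, config$hiddenSize, C, seed = config$seed)
  mAdam <- lapply(params, function(p) p * 0)
  vAdam <- lapply(params, function(p) p * 0)
  step <- 0L
  lossHist <- numeric(config$epochs)
  set.seed(config$seed + 7L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    batches <- split(ord, ceiling(seq_along(ord) / config$batchSize))
    lossSum <- 0
    for (b in batches) {
      X <- arr[b, , , drop = FALSE]
      Y <- t(outer(as.character(y[b]), lev, `==`) * 1)   # C x B
      gr <- lstmGradients(params, X, Y, config$candidateActivation)
      lossSum <- lossSum + gr$loss * length(b)
      step <- step + 1L
      for (k in names(params)) {
        mAdam[[k]] <- config$beta1 * mAdam[[k]] + (1 - config$beta1) * gr$grads[[k]]
        vAdam[[k]] <- config$beta2 * vAdam[[k]] + (1 - config$beta2) * gr$grads[[k]]^2
        mhat <- mAdam[[k]] / (1 - config$beta1^step)
        vhat <- vAdam[[k]] / (1 - config$beta2^step)
        params[[k]] <- params[[k]] -
          config$learningRate * mhat / (sqrt(vhat) + config$epsilon)
      }
    }
    lossHist[ep] <- lossSum / n
    if (ep > 1 && is.finite(lossHist[1]) && lossHist[ep] > 10 * lossHist[1])
      stop("LSTM training diverged at epoch ", ep,
           " (loss ", signif(lossHist[ep], 4), " vs initial ",
           signif(lossHist[1], 4), ")")
  }
  new("LSTMModel", params = params, ns = train@ns,
      hiddenSize = config$hiddenSize,
      candidateActivation = config$candidateActivation,
      featureNames = train@featureNames, classLevels = lev,
      lossHistory = lossHist, scaler = scaler)
}

#' @export
setMethod("featureNames", "LSTMModel", function(x) x@featureNames)

setMethod("show", "LSTMModel", function(object) {
  cat(sprintf("LSTMModel: %d hidden unit(s), ns = %d, classes: %s\n",
              object@hiddenSize, object@ns,
              paste(object@classLevels, collapse = "/")))
  if (length(object@lossHistory))
    cat(sprintf("  training loss: %.4f -> %.4f over %d epoch(s)\n",
                object@lossHistory[1], tail(object@lossHistory, 1),
                length(object@lossHistory)))
})

#' Predict stages with a trained LSTM
#'
#' @param object an [LSTMModel-class].
#' @param newdata a [WindowedDataset-class] with matching `ns` and features.
#' @param type `"class"` for labels, `"prob"` for the probability matrix.
#' @param ... ignored.
#' @return factor of predicted stages, or a cases x classes matrix.
#' @export
setMethod("predict", "LSTMModel", function(object, newdata,
                                           type = c("class", "prob"), ...) {
  type <- match.arg(type)
  stopifnot(is(newdata, "WindowedDataset"))
  if (newdata@ns != object@ns)
    stop("dataset ns (", newdata@ns, ") != model ns (", object@ns, ")")
  arr <- newdata@sequences[, , object@featureNames, drop = FALSE]
  if (!is.null(object@scaler)) arr <- scaleSequences(arr, object@scaler)$arr
  fw <- lstmForwardBatch(arr, object@params, object@candidateActivation,
                         keepCache = FALSE)
  probs <- t(fw$probs)
  colnames(probs) <- object@classLevels
  if (type == "prob") return(probs)
  factor(object@classLevels[max.col(probs)], levels = object@classLevels)
})
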