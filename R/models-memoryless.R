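## Memoryless classifier suite behind one surface. These are standard
## learners, delegated to established engines: multinomial logistic
## regression (nnet), random forest (randomForest), k-nearest neighbours
## (class), radial-kernel SVM (e1071) and a single-hidden-layer MLP (nnet).
## Grid selection maximizes cross-validated weighted F1.

#' Subset a windowed dataset by sequence index
#'
#' @param ds a [WindowedDataset-class].
#' @param idx integer indices of sequences to keep.
#' @return a [WindowedDataset-class].
#' @export
subsetWindows <- function(ds, idx) {
  new("WindowedDataset", ns = ds@ns,
      sequences = ds@sequences[idx, , , drop = FALSE],
      labels = droplevels(ds@labels[idx]), featureNames = ds@featureNames)
}

#' Train/test split of a windowed dataset
#'
#' `stratified_random` samples `trainFraction` of each class (class
#' proportions preserved to within one sample per class);
#' `subject_held_out` assigns whole subjects to one side. Deterministic
#' given `seed`. A class absent from the training side is an error.
#'
#' @param ds a [WindowedDataset-class].
#' @param trainFraction fraction of rows (or subjects) for training.
#' @param strategy `"stratified_random"` or `"subject_held_out"`.
#' @param seed integer seed.
#' @param subjects subject id per sequence (required for
#'   `subject_held_out`).
#' @return list with `train`, `test` ([WindowedDataset-class]) and the
#'   index vectors `trainIdx`, `testIdx`.
#' @export
splitData <- function(ds, trainFraction = 0.75,
                      strategy = c("stratified_random", "subject_held_out"),
                      seed = 1L, subjects = NULL) {
  strategy <- match.arg(strategy)
  stopifnot(trainFraction > 0, trainFraction < 1)
  set.seed(seed)
  n <- length(ds@labels)
  if (strategy == "stratified_random") {
    trainIdx <- sort(unlist(lapply(split(seq_len(n), ds@labels), function(ix) {
      k <- round(trainFraction * length(ix))
      k <- min(max(k, 1L), length(ix) - 1L)
      sample(ix, k)
    })))
  } else {
    if (is.null(subjects) || length(subjects) != n)
      stop("subject_held_out needs one subject id per sequence")
    subj <- unique(subjects)
    k <- max(1L, round(trainFraction * length(subj)))
    k <- min(k, length(subj) - 1L)
    trainSubj <- sample(subj, k)
    trainIdx <- which(subjects %in% trainSubj)
  }
  testIdx <- setdiff(seq_len(n), trainIdx)
  if (!all(levels(droplevels(ds@labels)) %in%
           unique(as.character(ds@labels[trainIdx]))))
    stop("a class is absent from the training split")
  list(train = subsetWindows(ds, trainIdx), test = subsetWindows(ds, testIdx),
       trainIdx = trainIdx, testIdx = testIdx)
}

defaultGrid <- function(engine, p) {
  switch(engine,
    LR  = list(list(decay = 0), list(decay = 0.1)),
    RF  = list(list(ntree = 100, mtry = max(1L, floor(sqrt(p))))),
    kNN = list(list(k = 3), list(k = 5), list(k = 7)),
    SVM = list(list(cost = 1, gamma = 1 / p), list(cost = 10, gamma = 1 / p)),
    MLP = list(list(size = 8, decay = 0.01), list(size = 16, decay = 0.01)))
}

fitEngine <- function(engine, x, y, gp) {
  x <- as.data.frame(x)
  switch(engine,
    LR = nnet::multinom(y ~ ., data = cbind(x, y = y), decay = gp$decay,
                        maxit = 200, trace = FALSE),
    RF = randomForest::randomForest(x, y, ntree = gp$ntree, mtry = gp$mtry),
    kNN = list(x = x, y = y, k = gp$k),
    SVM = e1071::svm(x, y, kernel = "radial", cost = gp$cost,
                     gamma = gp$gamma),
    MLP = nnet::nnet(x, nnet::class.ind(y), size = gp$size, decay = gp$decay,
                     softmax = TRUE, maxit = 200, trace = FALSE))
}

predictEngine <- function(engine, fit, x, levels_) {
  x <- as.data.frame(x)
  out <- switch(engine,
    LR = as.character(predict(fit, newdata = x)),
    RF = as.character(predict(fit, x)),
    kNN = as.character(class::knn(fit$x, x, fit$y, k = fit$k)),
    SVM = as.character(predict(fit, x)),
    MLP = colnames(predict(fit, x))[max.col(predict(fit, x))])
  factor(out, levels = levels_)
}

#' Fit a memoryless classifier with grid selection
#'
#' Fits one of `LR`, `RF`, `kNN`, `SVM`, `MLP` on a flattened feature
#' matrix, selecting the hyper-parameter grid point that maximizes
#' cross-validated weighted F1. Defaults: kNN `k = 3`, SVM radial kernel.
#' A single-point grid skips cross-validation.
#'
#' @param x feature matrix / data.frame.
#' @param y factor labels.
#' @param engine one of `"LR"`, `"RF"`, `"kNN"`, `"SVM"`, `"MLP"`.
#' @param grid list of named hyper-parameter lists; `NULL` uses a small
#'   engine-specific default.
#' @param cvFolds cross-validation folds for grid selection.
#' @param seed integer seed (fold assignment and stochastic engines).
#' @return a [MemorylessModel-class].
#' @export
fitMemoryless <- function(x, y, engine = c("RF", "LR", "kNN", "SVM", "MLP"),
                          grid = NULL, cvFolds = 3L, seed = 1L) {
  engine <- match.arg(engine)
  y <- droplevels(factor(y))
  if (nlevels(y) < 2L) stop("training labels contain a single class")
  x <- as.matrix(x)
  if (is.null(grid)) grid <- defaultGrid(engine, ncol(x))
  set.seed(seed)
  if (length(grid) == 1L) {
    bestGp <- grid[[1]]; bestScore <- NA_real_
  } else {
    folds <- sample(rep_len(seq_len(cvFolds), nrow(x)))
    scores <- vapply(grid, function(gp) {
      f1 <- vapply(seq_len(cvFolds), function(k) {
        tr <- folds != k
        if (nlevels(droplevels(y[tr])) < 2L) return(NA_real_)
        fit <- fitEngine(engine, x[tr, , drop = FALSE], droplevels(y[tr]), gp)
        pred <- predictEngine(engine, fit, x[!tr, , drop = FALSE], levels(y))
        metrics(scoreClassifier(y[!tr], pred))[["f1"]]
      }, numeric(1))
      mean(f1, na.rm = TRUE)
    }, numeric(1))
    bestGp <- grid[[which.max(scores)]]
    bestScore <- max(scores)
  }
  set.seed(seed + 1L)
  fit <- fitEngine(engine, x, y, bestGp)
  new("MemorylessModel", engine = engine, fit = fit, gridPoint = bestGp,
      cvScore = bestScore, featureNames = colnames(x),
      classLevels = levels(y))
}

#' @export
setMethod("featureNames", "MemorylessModel", function(x) x@featureNames)

setMethod("show", "MemorylessModel", function(object) {
  cat(sprintf("MemorylessModel: %s (%d features, classes: %s)\n",
              object@engine, length(object@featureNames),
              paste(object@classLevels, collapse = "/")))
  cat("  grid point:", paste(names(object@gridPoint),
                             unlist(object@gridPoint), sep = "=",
                             collapse = ", "), "\n")
})

#' Predict stages with a fitted memoryless model
#'
#' @param object a [MemorylessModel-class].
#' @param newdata feature matrix with the training columns.
#' @param ... ignored.
#' @return factor of predicted stages.
#' @export
setMethod("predict", "MemorylessModel", function(object, newdata, ...) {
  newdata <- as.matrix(newdata)
  missingCols <- setdiff(object@featureNames, colnames(newdata))
  if (length(missingCols))
    stop("newdata lacks feature(s): ", paste(missingCols, collapse = ", "))
  predictEngine(object@engine, object@fit,
                newdata[, object@featureNames, drop = FALSE],
                object@classLevels)
})
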