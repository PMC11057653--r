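## Weighted multiclass evaluation: because stage classes are imbalanced
## (light sleep dominates), precision/recall/F1 are support-weighted, and
## chance-robust agreement is reported as Cohen's kappa and the multiclass
## Matthews coefficient. Weighted recall is identically the accuracy.

#' Score predictions against truth
#'
#' Computes the weighted metric bundle from the predicted-by-true confusion
#' matrix: accuracy, support-weighted precision/recall/F1 (per-class scores
#' averaged with class-support weights), Cohen's kappa (chance agreement
#' from the marginals), the multiclass Matthews correlation coefficient
#' (covariance form), and, when class probabilities are supplied, the RMSE
#' of probabilities against the one-hot truth.
#'
#' @param yTrue true labels (factor or character).
#' @param yPred predicted labels, same length.
#' @param probabilities optional matrix of class probabilities
#'   (rows = cases, columns named by class).
#' @param metadata free-form list recorded in the report.
#' @return an [EvalReport-class].
#' @export
scoreClassifier <- function(yTrue, yPred, probabilities = NULL,
                            metadata = list()) {
  if (!length(yTrue)) stop("empty inputs")
  if (length(yTrue) != length(yPred)) stop("length mismatch")
  lev <- union(levels(factor(yTrue)), levels(factor(yPred)))
  yTrue <- factor(yTrue, levels = lev)
  yPred <- factor(yPred, levels = lev)
  cm <- table(predicted = yPred, true = yTrue)
  n <- sum(cm)
  support <- colSums(cm)                    # per true class
  diagc <- diag(cm)
  acc <- sum(diagc) / n

  recallC <- ifelse(support > 0, diagc / support, 0)
  predTot <- rowSums(cm)
  precC <- ifelse(predTot > 0, diagc / predTot, 0)
  f1C <- ifelse(precC + recallC > 0, 2 * precC * recallC / (precC + recallC), 0)
  w <- support / n
  precW <- sum(w * precC)
  recW <- sum(w * recallC)                  # == acc by construction
  f1W <- sum(w * f1C)

  pe <- sum((rowSums(cm) / n) * (colSums(cm) / n))
  kappa <- if (abs(1 - pe) < 1e-15) 0 else (acc - pe) / (1 - pe)

  ## multiclass Matthews: covariance form over the confusion matrix
  t_k <- colSums(cm); p_k <- rowSums(cm); c_ <- sum(diagc)
  s <- n
  num <- c_ * s - sum(p_k * t_k)
  den <- sqrt(s^2 - sum(p_k^2)) * sqrt(s^2 - sum(t_k^2))
  mcc <- if (den == 0) 0 else num / den

  rmse <- NA_real_
  if (!is.null(probabilities)) {
    probabilities <- as.matrix(probabilities)
    oh <- outer(as.character(yTrue), colnames(probabilities), `==`) * 1
    rmse <- sqrt(mean((probabilities - oh)^2))
  }
  new("EvalReport", accuracy = acc, precisionW = precW, recallW = recW,
      f1W = f1W, kappa = kappa, matthews = mcc, rmse = rmse,
      confusion = unclass(cm), nTest = as.integer(n), metadata = metadata)
}

#' @export
setMethod("metrics", "EvalReport", function(x) {
  c(acc = x@accuracy, prc = x@precisionW, recall = x@recallW,
    kappa = x@kappa, f1 = x@f1W, mc = x@matthews, rmse = x@rmse)
})

#' @export
setMethod("confusionMatrix", "EvalReport", function(x) x@confusion)

setMethod("show", "EvalReport", function(object) {
  cat(sprintf("EvalReport (n = %d)\n", object@nTest))
  m <- metrics(object)
  cat("  ", paste(sprintf("%s = %.3f", names(m), m), collapse = "  "), "\n")
  if (length(object@metadata))
    cat("  metadata:", paste(names(object@metadata),
                             unlist(lapply(object@metadata, format)),
                             sep = "=", collapse = ", "), "\n")
})

#' Per-class label fractions
#'
#' The class-distribution summary used to document stage imbalance.
#'
#' @param labels factor or character labels.
#' @return `data.frame` with `stage`, `count`, `fraction` (fractions sum
#'   to 1), in decreasing count order.
#' @export
imbalanceReport <- function(labels) {
  if (!length(labels)) stop("empty labels")
  tab <- table(labels)
  out <- data.frame(stage = names(tab), count = as.integer(tab),
                    fraction = as.numeric(tab) / sum(tab))
  out <- out[order(-out$count), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summarize a memory-step sweep
#'
#' Identifies the first (smallest) ns attaining the maximum accuracy, the
#' top-3 ns set, and emits plot-ready long-format metric data. Ties on the
#' maximum are reported at the smallest ns, with a message.
#'
#' @param reports list of [EvalReport-class], each with `ns` in metadata.
#' @return list with `bestNs`, `bestAccuracy`, `top3` (data.frame), and
#'   `table` (ns x metric data.frame, sorted by ns).
#' @export
sweepSummary <- function(reports) {
  if (!length(reports)) stop("at least one report required")
  tab <- do.call(rbind, lapply(reports, function(r) {
    m <- metrics(r)
    data.frame(ns = r@metadata$ns, acc = m["acc"], prc = m["prc"],
               recall = m["recall"], kappa = m["kappa"], f1 = m["f1"],
               mc = m["mc"], row.names = NULL)
  }))
  tab <- tab[order(tab$ns), , drop = FALSE]
  rownames(tab) <- NULL
  best <- max(tab$acc)
  at <- tab$ns[tab$acc == best]
  if (length(at) > 1L)
    message("accuracy tie at ns = ", paste(at, collapse = ", "),
            "; reporting the smallest")
  top3 <- tab[order(-tab$acc, tab$ns), , drop = FALSE]
  top3 <- head(top3, 3L)
  list(bestNs = min(at), bestAccuracy = best, top3 = top3, table = tab)
}

#' Compare a predicted hypnogram with the truth
#'
#' Aligns the two stage sequences on their shared grid and returns
#' step-plot-ready series, overall agreement, and a per-stage recall table.
#'
#' @param true an [EpochTable-class] hypnogram.
#' @param predicted an [EpochTable-class] on the same grid.
#' @return list with `agreement` (fraction of epochs equal), `perStage`
#'   (`data.frame` stage/recall/support), and `series` (`data.frame`
#'   time/true/predicted for plotting).
#' @export
hypnogramCompare <- function(true, predicted) {
  stopifnot(is(true, "EpochTable"), is(predicted, "EpochTable"))
  if (nEpochs(true) != nEpochs(predicted) ||
      epochInterval(true) != epochInterval(predicted) ||
      any(abs(as.numeric(epochTimestamps(true)) -
              as.numeric(epochTimestamps(predicted))) > 1e-6))
    stop("hypnograms are not on the same grid")
  st <- as.character(stages(true))
  sp <- as.character(stages(predicted))
  agree <- mean(st == sp)
  per <- do.call(rbind, lapply(unique(st), function(s) {
    idx <- st == s
    data.frame(stage = s, recall = mean(sp[idx] == s), support = sum(idx))
  }))
  rownames(per) <- NULL
  list(agreement = agree, perStage = per,
       series = data.frame(time = epochTimestamps(true), true = st,
                           predicted = sp))
}
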