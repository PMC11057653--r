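#' @rdname EpochTable-class
#' @param x,object an object.
#' @export
setGeneric("nEpochs", function(x) standardGeneric("nEpochs"))

#' @rdname EpochTable-class
#' @export
setGeneric("epochInterval", function(x) standardGeneric("epochInterval"))

#' @rdname EpochTable-class
#' @export
setGeneric("epochTimestamps", function(x) standardGeneric("epochTimestamps"))

#' @rdname EpochTable-class
#' @export
setGeneric("epochData", function(x) standardGeneric("epochData"))

#' @rdname EpochTable-class
#' @export
setGeneric("schemaId", function(x) standardGeneric("schemaId"))

#' Extract the stage-label column of an object
#' @param x an [EpochTable-class] with a `stage` column, or a
#'   [WindowedDataset-class].
#' @return a factor or character vector of stage labels.
#' @export
setGeneric("stages", function(x) standardGeneric("stages"))

#' Number of history steps of a windowed dataset
#' @param x a [WindowedDataset-class].
#' @export
setGeneric("memorySteps", function(x) standardGeneric("memorySteps"))

#' Feature names carried by a model or dataset
#' @param x a model or dataset object.
#' @export
setGeneric("featureNames", function(x) standardGeneric("featureNames"))

#' Confusion matrix of an evaluation report
#' @param x an [EvalReport-class].
#' @export
setGeneric("confusionMatrix", function(x) standardGeneric("confusionMatrix"))

#' Metrics of an evaluation report as a named numeric vector
#' @param x an [EvalReport-class].
#' @return named numeric: acc, prc, recall, kappa, f1, mc, rmse.
#' @export
setGeneric("metrics", function(x) standardGeneric("metrics"))
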