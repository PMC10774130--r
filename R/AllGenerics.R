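#' @rdname KeypointSchema-class
#' @param x,object a facekit object.
#' @export
setGeneric("bodyparts", function(x) standardGeneric("bodyparts"))
#' @rdname KeypointSchema-class
#' @export
setGeneric("bodypartGroups", function(x) standardGeneric("bodypartGroups"))
#' @rdname KeypointSchema-class
#' @export
setGeneric("neuralSubset", function(x) standardGeneric("neuralSubset"))

#' @rdname KeypointSeries-class
#' @export
setGeneric("coords", function(x) standardGeneric("coords"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("likelihoods", function(x) standardGeneric("likelihoods"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("outlierMask", function(x) standardGeneric("outlierMask"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("frameRate", function(x) standardGeneric("frameRate"))
#' @rdname KeypointSeries-class
#' @export
setGeneric("schema", function(x) standardGeneric("schema"))

#' @rdname NeuralRecording-class
#' @export
setGeneric("activity", function(x) standardGeneric("activity"))
#' @rdname NeuralRecording-class
#' @export
setGeneric("positions", function(x) standardGeneric("positions"))

#' @rdname HmmModel-class
#' @export
setGeneric("transitionMatrix", function(x) standardGeneric("transitionMatrix"))
#' @rdname HmmModel-class
#' @export
setGeneric("initialProbs", function(x) standardGeneric("initialProbs"))
#' @rdname HmmModel-class
#' @export
setGeneric("emissionMeans", function(x) standardGeneric("emissionMeans"))

#' @rdname EncodingFit-class
#' @export
setGeneric("varianceLedger", function(x) standardGeneric("varianceLedger"))
#' @rdname EncodingFit-class
#' @export
setGeneric("deepFeatures", function(x) standardGeneric("deepFeatures"))

#' @rdname KeypointSchema-class
setMethod("bodyparts", "KeypointSchema", function(x) x@bodyparts)
#' @rdname KeypointSchema-class
setMethod("bodypartGroups", "KeypointSchema", function(x) x@groups)
#' @rdname KeypointSchema-class
setMethod("neuralSubset", "KeypointSchema", function(x) x@neuralSubset)
#' @rdname KeypointSeries-class
setMethod("bodyparts", "KeypointSeries", function(x) x@schema@bodyparts)

#' @rdname KeypointSeries-class
setMethod("coords", "KeypointSeries", function(x) x@coords)
#' @rdname KeypointSeries-class
setMethod("likelihoods", "KeypointSeries", function(x) x@likelihood)
#' @rdname KeypointSeries-class
setMethod("outlierMask", "KeypointSeries", function(x) x@outlierMask)
#' @rdname KeypointSeries-class
setMethod("frameRate", "KeypointSeries", function(x) x@rate)
#' @rdname KeypointSeries-class
setMethod("schema", "KeypointSeries", function(x) x@schema)

#' @rdname NeuralRecording-class
setMethod("activity", "NeuralRecording", function(x)
  SummarizedExperiment::assay(x, "activity"))
#' @rdname NeuralRecording-class
setMethod("positions", "NeuralRecording", function(x) {
  rd <- SummarizedExperiment::rowData(x)
  cbind(x_um = rd$x_um, y_um = rd$y_um)
})
#' @rdname NeuralRecording-class
setMethod("frameRate", "NeuralRecording", function(x)
  S4Vectors::metadata(x)$rate)

#' @rdname HmmModel-class
setMethod("transitionMatrix", "HmmModel", function(x) softmaxRows(x@Q))
#' @rdname HmmModel-class
setMethod("initialProbs", "HmmModel", function(x) {
  b <- exp(x@blogits - max(x@blogits)); b / sum(b)
})
#' @rdname HmmModel-class
setMethod("emissionMeans", "HmmModel", function(x) x@means)

#' @rdname EncodingFit-class
setMethod("varianceLedger", "EncodingFit", function(x) x@ledger)
#' @rdname EncodingFit-class
setMethod("deepFeatures", "EncodingFit", function(x) x@features)

setMethod("show", "KeypointSchema", function(object) {
  cat("KeypointSchema with", length(object@bodyparts), "bodyparts\n")
  grp <- split(object@bodyparts, object@groups[object@bodyparts])
  for (g in names(grp))
    cat("  ", g, ": ", paste(grp[[g]], collapse = ", "), "\n", sep = "")
  cat("  neural subset:", length(object@neuralSubset), "bodyparts (",
      2L * length(object@neuralSubset), "coordinates )\n")
})

setMethod("show", "KeypointSeries", function(object) {
  d <- dim(object@coords)
  cat("KeypointSeries:", d[1], "frames x", d[2], "bodyparts @",
      object@rate, "Hz\n")
  nf <- sum(object@outlierMask)
  cat(sprintf("  flagged outliers: %d (%.3f%% of samples)\n", nf,
              100 * nf / (d[1] * d[2])))
})

setMethod("show", "SegmentSplit", function(object) {
  cat("SegmentSplit:", object@nSegments, "segments,",
      length(object@trainIdx), "train /", length(object@testIdx),
      "test frames (gap", object@gapSec, "s)\n")
})

setMethod("show", "HmmModel", function(object) {
  cat("HmmModel:", object@K, "states,", ncol(object@means),
      "feature dimensions, sigma2 =", signif(object@sigma2, 4), "\n")
  A <- transitionMatrix(object)
  cat("  mean self-transition:", signif(mean(diag(A)), 4), "\n")
})

setMethod("show", "EncodingFit", function(object) {
  cat("EncodingFit (", object@type, "): ", nrow(object@ledger),
      " output units\n", sep = "")
  if (nrow(object@ledger))
    cat("  mean test VE:", signif(mean(object@ledger$ve, na.rm = TRUE), 4),
        "\n")
})

setMethod("show", "ClusterModel", function(object) {
  cat("ClusterModel:", nrow(object@centers), "clusters,",
      length(object@assignments), "neurons\n")
})

setMethod("show", "TrackerNet", function(object) {
  np <- sum(vapply(object@layers, function(l)
    sum(vapply(l, length, 0L)), 0))
  cat("TrackerNet:", object@config$n_keypoints, "keypoints, input",
      object@config$input_size, "px, downsample",
      object@config$downsample_factor, "x;", np, "parameters\n")
})
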