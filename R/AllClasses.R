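#' @useDynLib facekit, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @import methods
#' @importFrom stats approx cor filter fft kmeans mad median optim quantile
#'   rnorm runif sd var
NULL

#' Keypoint schema for mouse orofacial tracking
#'
#' An ordered set of named bodyparts, each assigned to a face region
#' (eye, mouth, nose, whisker, paw or other), together with the ordered
#' subset of bodyparts used as input to neural encoding models.
#'
#' The default schema has 13 bodyparts: four eye corners, two mouth points,
#' four nose points and three whisker bases. The extended 15-point schema
#' adds a paw keypoint and a nose-bridge keypoint; both are flagged as
#' excluded by default because they are hard to track consistently across
#' camera views. The neural-prediction subset is the four eye, four nose and
#' three whisker bodyparts (11 bodyparts, 22 x/y coordinates).
#'
#' @slot bodyparts ordered character vector of bodypart labels.
#' @slot groups named character vector mapping bodypart to face region.
#' @slot neuralSubset ordered character vector of bodyparts used for neural
#'   prediction.
#' @slot excluded bodyparts present in the schema but excluded by default.
#' @export
setClass("KeypointSchema",
  representation(bodyparts = "character", groups = "character",
                 neuralSubset = "character", excluded = "character"))

setValidity("KeypointSchema", function(object) {
  msg <- NULL
  if (anyDuplicated(object@bodyparts))
    msg <- c(msg, "duplicate bodypart labels")
  if (!all(object@bodyparts %in% names(object@groups)))
    msg <- c(msg, "every bodypart needs a group")
  if (!all(object@neuralSubset %in% object@bodyparts))
    msg <- c(msg, "neuralSubset must be a subset of bodyparts")
  if (is.null(msg)) TRUE else msg
})

#' Per-frame keypoint coordinates, likelihoods and outlier flags
#'
#' The central behavioral record: for each video frame and bodypart, the
#' (x, y) position in full-image pixels, the tracker likelihood (the peak
#' heatmap value) in \[0, 1\], and a logical outlier flag. Coordinates are
#' 0-based pixel centers with x = column, y = row and origin at the top-left
#' corner of the image. Coordinates may be missing (NaN) only where the
#' outlier mask is set.
#'
#' @slot schema a [KeypointSchema-class].
#' @slot coords numeric array, frames x bodyparts x 2 (x, y).
#' @slot likelihood numeric matrix, frames x bodyparts, in \[0, 1\].
#' @slot outlierMask logical matrix, frames x bodyparts.
#' @slot rate sampling rate in Hz (nominally 50).
#' @export
setClass("KeypointSeries",
  representation(schema = "KeypointSchema", coords = "array",
                 likelihood = "matrix", outlierMask = "matrix",
                 rate = "numeric"))

setValidity("KeypointSeries", function(object) {
  msg <- NULL
  d <- dim(object@coords)
  if (length(d) != 3L || d[3] != 2L)
    msg <- c(msg, "coords must be frames x bodyparts x 2")
  if (d[2] != length(object@schema@bodyparts))
    msg <- c(msg, "coords bodypart dimension does not match schema")
  if (!all(dim(object@likelihood) == d[1:2]))
    msg <- c(msg, "likelihood shape must match coords")
  if (!all(dim(object@outlierMask) == d[1:2]))
    msg <- c(msg, "outlierMask shape must match coords")
  lk <- object@likelihood
  if (any(lk < 0 | lk > 1, na.rm = TRUE))
    msg <- c(msg, "likelihood values must lie in [0, 1]")
  if (length(object@rate) != 1L || !is.finite(object@rate) || object@rate <= 0)
    msg <- c(msg, "rate must be a positive scalar (Hz)")
  bad <- !is.finite(object@coords[, , 1]) | !is.finite(object@coords[, , 2])
  if (any(bad & !object@outlierMask))
    msg <- c(msg, "coords must be finite wherever outlierMask is FALSE")
  if (is.null(msg)) TRUE else msg
})

#' Segmented train/test split with exclusion gaps
#'
#' The recording is divided into equal-length contiguous segments (remainder
#' frames are appended to the last segment). Within each segment the first
#' `trainFrac` of frames form a contiguous training block, the next
#' `ceiling(gap * rate)` frames are excluded to break temporal
#' autocorrelation, and the remaining frames form the test block.
#'
#' @slot trainIdx,testIdx disjoint 1-based frame indices.
#' @slot segTrain,segTest per-segment index lists.
#' @slot nSegments,trainFrac,gapSec,rate,nTimepoints split parameters.
#' @export
setClass("SegmentSplit",
  representation(trainIdx = "integer", testIdx = "integer",
                 segTrain = "list", segTest = "list",
                 nSegments = "integer", trainFrac = "numeric",
                 gapSec = "numeric", rate = "numeric",
                 nTimepoints = "integer"))

setValidity("SegmentSplit", function(object) {
  msg <- NULL
  if (length(intersect(object@trainIdx, object@testIdx)) > 0L)
    msg <- c(msg, "train and test indices must be disjoint")
  if (any(c(object@trainIdx, object@testIdx) > object@nTimepoints))
    msg <- c(msg, "indices exceed the recording span")
  if (is.null(msg)) TRUE else msg
})

#' Neural population recording
#'
#' A thin wrapper around [SummarizedExperiment::SummarizedExperiment] holding
#' a neurons x timepoints activity matrix (assay `"activity"`), per-neuron
#' 2-D positions in the imaging plane (`rowData` columns `x_um`, `y_um`) and
#' the neural frame rate in Hz (`metadata$rate`, nominally 3 Hz for ~300 ms
#' bins).
#'
#' @export
#' @import SummarizedExperiment
setClass("NeuralRecording", contains = "SummarizedExperiment")

setValidity("NeuralRecording", function(object) {
  msg <- NULL
  if (!"activity" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'activity' is required")
  rd <- SummarizedExperiment::rowData(object)
  if (!all(c("x_um", "y_um") %in% colnames(rd)))
    msg <- c(msg, "rowData must contain x_um and y_um positions")
  else if (!all(is.finite(rd$x_um)) || !all(is.finite(rd$y_um)))
    msg <- c(msg, "neuron positions must be finite")
  r <- S4Vectors::metadata(object)$rate
  if (is.null(r) || !is.finite(r) || r <= 0)
    msg <- c(msg, "metadata$rate must be a positive scalar (Hz)")
  if (is.null(msg)) TRUE else msg
})

#' Per-keypoint heatmaps and location-refinement maps
#'
#' The two tracker network outputs at downsampled resolution: `heatmaps`
#' holds per-keypoint probability maps with values in \[0, 1\], and
#' `refineX`/`refineY` hold, for every heatmap cell, the predicted x/y offset
#' (in full-image pixels) from the cell's full-resolution center to the true
#' keypoint position.
#'
#' @slot heatmaps numeric array, h x w x keypoints.
#' @slot refineX,refineY numeric arrays, h x w x keypoints.
#' @slot downsample integer downsampling factor between image and maps.
#' @export
setClass("HeatmapBundle",
  representation(heatmaps = "array", refineX = "array", refineY = "array",
                 downsample = "integer"))

setValidity("HeatmapBundle", function(object) {
  msg <- NULL
  if (any(object@heatmaps < -1e-8 | object@heatmaps > 1 + 1e-8, na.rm = TRUE))
    msg <- c(msg, "heatmap values must lie in [0, 1]")
  if (!all(dim(object@refineX) == dim(object@heatmaps)) ||
      !all(dim(object@refineY) == dim(object@heatmaps)))
    msg <- c(msg, "refinement map shapes must match heatmaps")
  if (is.null(msg)) TRUE else msg
})

#' Fitted behavior-to-neural encoding model
#'
#' Holds a trained encoder (deep network or reduced-rank regression), the
#' train/test segmentation it was fit under, and the per-neuron variance
#' ledger: variance explained (VE), explainable variance (EV) from peer
#' prediction when supplied, and normalized VE where EV exceeds 1e-3.
#'
#' @slot type `"deep"` or `"rrr"`.
#' @slot model fitted parameters (implementation-specific list).
#' @slot split the [SegmentSplit-class] used for fitting.
#' @slot ledger data.frame with per-neuron `ve` (and optionally `ev`,
#'   `nve`).
#' @slot features deep behavioral features (time x 256) at behavior rate, or
#'   a 0 x 0 matrix for linear models.
#' @slot history training loss per epoch.
#' @export
setClass("EncodingFit",
  representation(type = "character", model = "list", split = "SegmentSplit",
                 ledger = "data.frame", features = "matrix",
                 history = "numeric"))

#' Discrete Gaussian-emission hidden Markov model
#'
#' States evolve as a Markov chain with row-stochastic transition matrix
#' `A = softmax(Q)` (row-wise over the log-transition matrix `Q`), initial
#' distribution `b = softmax(blogits)`, and isotropic Gaussian emissions with
#' state means `C` (K x n) and a fixed, never-learned emission variance
#' `sigma2`. The variance follows a policy proportional to the summed data
#' variance: 1 for 256-dimensional deep behavioral features and 30/256 for
#' keypoint inputs.
#'
#' @slot K number of states.
#' @slot Q K x K log-transition matrix.
#' @slot means K x n emission means.
#' @slot blogits length-K initial-state logits.
#' @slot sigma2 fixed emission variance.
#' @export
setClass("HmmModel",
  representation(K = "integer", Q = "matrix", means = "matrix",
                 blogits = "numeric", sigma2 = "numeric"))

setValidity("HmmModel", function(object) {
  msg <- NULL
  if (nrow(object@Q) != object@K || ncol(object@Q) != object@K)
    msg <- c(msg, "Q must be K x K")
  if (nrow(object@means) != object@K)
    msg <- c(msg, "C must have K rows")
  if (length(object@blogits) != object@K)
    msg <- c(msg, "blogits must have length K")
  if (object@sigma2 <= 0) msg <- c(msg, "sigma2 must be positive")
  if (is.null(msg)) TRUE else msg
})

#' Scaled k-means clustering of neurons
#'
#' Each neuron i is modeled as a scalar gain times its cluster's temporal
#' pattern, `x_i = lambda_i * mu_{sigma_i} + noise`. Holds assignments,
#' per-neuron gains, cluster patterns, mean member-activity traces and the
#' objective value per iteration.
#'
#' @slot assignments integer cluster per neuron.
#' @slot lambda per-neuron scalar gain.
#' @slot centers k x T cluster patterns mu.
#' @slot traces k x T mean member activity.
#' @slot objective sum-of-squares objective per iteration (non-increasing).
#' @export
setClass("ClusterModel",
  representation(assignments = "integer", lambda = "numeric",
                 centers = "matrix", traces = "matrix",
                 objective = "numeric"))

#' U-Net-style tracker network
#'
#' @slot config tracker configuration (see [trackerConfig()]).
#' @slot layers named list of layer parameter lists.
#' @export
setClass("TrackerNet",
  representation(config = "list", layers = "list"))
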