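#' Default orofacial keypoint schema
#'
#' Returns the 13-bodypart schema used for mouse orofacial tracking: four eye
#' corners (bottom, top, front, back), two mouth points (mouth, lower lip),
#' four nose points (bottom, top, tip, right-bottom) and three whisker bases.
#' With `extended = TRUE` the 15-point schema is returned, adding the paw and
#' nose-bridge keypoints; both are flagged excluded-by-default. The neural
#' prediction subset is always the eye, nose and whisker bodyparts
#' (11 bodyparts, 22 coordinates).
#'
#' @param extended include the paw and nose-bridge keypoints.
#' @return a [KeypointSchema-class].
#' @examples
#' sc <- defaultSchema()
#' length(bodyparts(sc))           # 13
#' length(neuralSubset(sc)) * 2    # 22 coordinates
#' @export
defaultSchema <- function(extended = FALSE) {
  eye <- c("eye_bottom", "eye_top", "eye_front", "eye_back")
  mouth <- c("mouth", "lowerlip")
  nose <- c("nose_bottom", "nose_top", "nose_tip", "nose_rbottom")
  whisker <- c("whisker1", "whisker2", "whisker3")
  parts <- c(eye, mouth, nose, whisker)
  groups <- c(rep("eye", 4), rep("mouth", 2), rep("nose", 4),
              rep("whisker", 3))
  excluded <- character(0)
  if (extended) {
    parts <- c(parts, "paw", "nose_bridge")
    groups <- c(groups, "paw", "nose")
    excluded <- c("paw", "nose_bridge")
  }
  names(groups) <- parts
  new("KeypointSchema", bodyparts = parts, groups = groups,
      neuralSubset = c(eye, nose, whisker), excluded = excluded)
}

#' Build a schema from arbitrary bodypart labels
#'
#' Labels present in the default schema keep their face-region group; unknown
#' labels are preserved with group `"other"`.
#' @param parts character vector of bodypart labels.
#' @keywords internal
inferSchema <- function(parts) {
  ref <- defaultSchema(extended = TRUE)
  groups <- ifelse(parts %in% ref@bodyparts, ref@groups[parts], "other")
  names(groups) <- parts
  new("KeypointSchema", bodyparts = parts, groups = groups,
      neuralSubset = intersect(ref@neuralSubset, parts),
      excluded = character(0))
}

#' Construct a KeypointSeries
#'
#' @param coords frames x bodyparts x 2 array of (x, y) pixel coordinates.
#' @param likelihood frames x bodyparts matrix in \[0, 1\]; defaults to 1.
#' @param rate sampling rate in Hz.
#' @param schema a [KeypointSchema-class]; inferred from `dimnames(coords)`
#'   when omitted.
#' @param outlierMask logical frames x bodyparts matrix; frames with missing
#'   coordinates are flagged automatically.
#' @return a [KeypointSeries-class].
#' @export
keypointSeries <- function(coords, likelihood = NULL, rate = 50,
                           schema = NULL, outlierMask = NULL) {
  stopifnot(length(dim(coords)) == 3L, dim(coords)[3] == 2L)
  nT <- dim(coords)[1]; nP <- dim(coords)[2]
  if (is.null(schema)) {
    parts <- dimnames(coords)[[2]]
    if (is.null(parts)) parts <- paste0("kp", seq_len(nP))
    schema <- inferSchema(parts)
  }
  if (is.null(likelihood)) likelihood <- matrix(1, nT, nP)
  if (is.null(outlierMask)) outlierMask <- matrix(FALSE, nT, nP)
  miss <- !is.finite(coords[, , 1, drop = FALSE]) |
    !is.finite(coords[, , 2, drop = FALSE])
  outlierMask <- outlierMask | matrix(miss, nT, nP)
  dimnames(coords) <- list(NULL, schema@bodyparts, c("x", "y"))
  colnames(likelihood) <- schema@bodyparts
  colnames(outlierMask) <- schema@bodyparts
  new("KeypointSeries", schema = schema, coords = coords,
      likelihood = likelihood, outlierMask = outlierMask, rate = rate)
}

#' Read keypoints from a long-format CSV file
#'
#' The long dialect has one row per (frame, bodypart) with columns
#' `frame,bodypart,x,y,likelihood`. Frames are 0-based in the file. Unknown
#' bodyparts are preserved with group `"other"`; rows with missing
#' coordinates are flagged in the outlier mask.
#'
#' @param path CSV file path.
#' @param rate sampling rate in Hz to record on the series.
#' @return a [KeypointSeries-class].
#' @export
readKeypoints <- function(path, rate = 50) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("frame", "bodypart", "x", "y", "likelihood")
  if (!all(need %in% names(df)))
    stop("keypoint CSV must have columns ", paste(need, collapse = ","))
  bad <- which(!is.finite(df$frame))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": non-numeric frame")
  if (any(df$likelihood < 0 | df$likelihood > 1, na.rm = TRUE)) {
    bad <- which(df$likelihood < 0 | df$likelihood > 1)[1]
    stop("likelihood out of [0,1] at line ", bad + 1L)
  }
  key <- paste(df$frame, df$bodypart)
  if (anyDuplicated(key))
    stop("duplicate (frame, bodypart) entry: ", key[anyDuplicated(key)][1])
  parts <- unique(df$bodypart)
  frames <- sort(unique(df$frame))
  nT <- length(frames); nP <- length(parts)
  co <- array(NA_real_, c(nT, nP, 2))
  lk <- matrix(NA_real_, nT, nP)
  fi <- match(df$frame, frames); pi <- match(df$bodypart, parts)
  co[cbind(fi, pi, 1L)] <- df$x
  co[cbind(fi, pi, 2L)] <- df$y
  lk[cbind(fi, pi)] <- df$likelihood
  dimnames(co) <- list(NULL, parts, c("x", "y"))
  keypointSeries(co, lk, rate = rate, schema = inferSchema(parts))
}

#' Write keypoints to a long-format CSV file
#'
#' @param x a [KeypointSeries-class].
#' @param path output CSV path.
#' @export
writeKeypoints <- function(x, path) {
  d <- dim(x@coords)
  df <- data.frame(
    frame = rep(seq_len(d[1]) - 1L, d[2]),
    bodypart = rep(bodyparts(x), each = d[1]),
    x = as.vector(x@coords[, , 1]),
    y = as.vector(x@coords[, , 2]),
    likelihood = as.vector(x@likelihood))
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Construct a NeuralRecording
#'
#' @param activity neurons x timepoints matrix.
#' @param positions neurons x 2 matrix of positions in micrometers.
#' @param rate neural frame rate in Hz (nominally 3 Hz, ~300 ms bins).
#' @return a [NeuralRecording-class].
#' @export
neuralRecording <- function(activity, positions, rate = 3) {
  stopifnot(nrow(activity) == nrow(positions), ncol(positions) == 2)
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(activity = activity),
    rowData = S4Vectors::DataFrame(x_um = positions[, 1],
                                   y_um = positions[, 2]),
    metadata = list(rate = rate))
  new("NeuralRecording", se)
}

#' Read / write a NeuralRecording as plain-text CSV
#'
#' `prefix_activity.csv` holds the neurons x timepoints matrix (no header),
#' `prefix_positions.csv` the per-neuron `x_um,y_um` positions and
#' `prefix_meta.yaml` the frame rate.
#' @param prefix file path prefix.
#' @export
readNeural <- function(prefix) {
  act <- as.matrix(utils::read.csv(paste0(prefix, "_activity.csv"),
                                   header = FALSE))
  dimnames(act) <- NULL
  pos <- as.matrix(utils::read.csv(paste0(prefix, "_positions.csv")))
  meta <- yaml::read_yaml(paste0(prefix, "_meta.yaml"))
  neuralRecording(act, pos, rate = meta$rate)
}

#' @rdname readNeural
#' @param x a [NeuralRecording-class].
#' @export
writeNeural <- function(x, prefix) {
  utils::write.table(activity(x), paste0(prefix, "_activity.csv"),
                     sep = ",", row.names = FALSE, col.names = FALSE)
  utils::write.csv(as.data.frame(positions(x)),
                   paste0(prefix, "_positions.csv"), row.names = FALSE)
  yaml::write_yaml(list(rate = frameRate(x)), paste0(prefix, "_meta.yaml"))
  invisible(prefix)
}

#' Segmented train/test split
#'
#' Splits `nTimepoints` frames into `nSegments` equal-length contiguous
#' segments (remainder appended to the last). The first
#' `floor(trainFrac * segment length)` frames of each segment are training
#' frames; the following `ceiling(gapSec * rate)` frames are excluded; the
#' remainder are test frames. Used with a 3 s gap for neural prediction and a
#' 2.6 s gap for the autoregressive keypoint model.
#'
#' @param nTimepoints total number of frames.
#' @param rate sampling rate in Hz.
#' @param nSegments number of segments (default 10).
#' @param trainFrac training fraction per segment (default 0.75).
#' @param gapSec excluded gap after the training block, in seconds.
#' @return a [SegmentSplit-class].
#' @examples
#' sp <- makeSplit(1000, rate = 1, gapSec = 3)
#' length(sp@trainIdx)  # 750
#' length(sp@testIdx)   # 220
#' @export
makeSplit <- function(nTimepoints, rate, nSegments = 10L, trainFrac = 0.75,
                      gapSec = 3.0) {
  nTimepoints <- as.integer(nTimepoints)
  nSegments <- as.integer(nSegments)
  stopifnot(nTimepoints > 0, nSegments > 0, trainFrac > 0, trainFrac < 1,
            gapSec >= 0, rate > 0)
  base <- nTimepoints %/% nSegments
  if (base < 2) stop("segments too short: fewer than 2 frames per segment")
  gap <- as.integer(ceiling(gapSec * rate))
  starts <- (seq_len(nSegments) - 1L) * base + 1L
  ends <- c(starts[-1L] - 1L, nTimepoints)
  segTrain <- segTest <- vector("list", nSegments)
  for (s in seq_len(nSegments)) {
    len <- ends[s] - starts[s] + 1L
    ntr <- as.integer(floor(trainFrac * len))
    nte <- len - ntr - gap
    if (nte <= 0L)
      stop("segment ", s, " too short for gap: no test frames remain")
    segTrain[[s]] <- seq.int(starts[s], length.out = ntr)
    segTest[[s]] <- seq.int(starts[s] + ntr + gap, length.out = nte)
  }
  new("SegmentSplit",
      trainIdx = as.integer(unlist(segTrain)),
      testIdx = as.integer(unlist(segTest)),
      segTrain = segTrain, segTest = segTest,
      nSegments = nSegments, trainFrac = trainFrac, gapSec = gapSec,
      rate = rate, nTimepoints = nTimepoints)
}

#' Read a YAML configuration file
#' @param path YAML file path.
#' @export
readConfig <- function(path) yaml::read_yaml(path)

# timestamped log line (ISO 8601), silent unless option facekit.verbose
logMsg <- function(...) {
  if (isTRUE(getOption("facekit.verbose", TRUE)))
    message(format(Sys.time(), "%Y-%m-%dT%H:%M:%S "), ...)
  invisible(NULL)
}

# row-wise softmax, numerically stable
softmaxRows <- function(Q) {
  m <- apply(Q, 1L, max)
  E <- exp(Q - m)
  E / rowSums(E)
}
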