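#' Autoregressive timescale configuration
#'
#' Settings for predicting keypoints into the future: exponential-decay
#' basis functions with timescales log-spaced from 40 ms to 5 s (10 by
#' default; only the range is prescribed), future lags from 20 ms to 10 s in
#' 20 ms steps then 10 s to 40 s in 500 ms steps, a ten-segment split with a
#' 2.6 s exclusion gap, and a small ridge penalty on standardized features to
#' stabilize the collinear basis.
#'
#' @param taus basis decay timescales in seconds.
#' @param lags future lags in seconds.
#' @param lambda ridge penalty.
#' @param nSegments,trainFrac,gapSec split parameters.
#' @export
arConfig <- function(taus = exp(seq(log(0.04), log(5), length.out = 10)),
                     lags = c(seq(0.02, 10, by = 0.02),
                              seq(10.5, 40, by = 0.5)),
                     lambda = 1e-4, nSegments = 10L, trainFrac = 0.75,
                     gapSec = 2.6) {
  stopifnot(all(diff(taus) > 0), all(taus > 0), all(lags > 0),
            all(diff(lags) > 0))
  list(taus = taus, lags = lags, lambda = lambda, nSegments = nSegments,
       trainFrac = trainFrac, gapSec = gapSec)
}

#' Exponential-decay basis features
#'
#' Causally convolves each input column with normalized exponential kernels
#' `exp(-t / tau)`; kernels have unit sum so constant inputs map to constant
#' features, and features at time t use only samples at or before t.
#'
#' @param traces T x C numeric matrix.
#' @param taus decay timescales in seconds.
#' @param rate sampling rate in Hz.
#' @return T x (C * length(taus)) feature matrix.
#' @export
basisFeatures <- function(traces, taus, rate) {
  traces <- as.matrix(traces)
  stopifnot(all(is.finite(traces)))
  nT <- nrow(traces); C <- ncol(traces)
  out <- matrix(0, nT, C * length(taus))
  for (j in seq_along(taus)) {
    a <- exp(-1 / (taus[j] * rate))
    for (cc in seq_len(C)) {
      out[, (j - 1L) * C + cc] <-
        stats::filter(traces[, cc] * (1 - a), a, method = "recursive")
    }
  }
  out
}

#' Fit the future-prediction regression at one lag
#'
#' A joint multi-output ridge regression from basis features at time t to all
#' keypoint coordinates at time t + lag, fit on training timepoints and
#' scored on test timepoints with variance explained.
#'
#' @param traces T x C matrix of keypoint coordinates.
#' @param split a [SegmentSplit-class].
#' @param lag future lag in seconds.
#' @param rate sampling rate in Hz.
#' @param taus basis timescales.
#' @param lambda ridge penalty on standardized features.
#' @param features optional precomputed [basisFeatures()] matrix; assumed
#'   already standardized when `standardized = TRUE`.
#' @param standardized set when `features` are pre-standardized.
#' @param trainStride keep every `trainStride`-th training timepoint
#'   (training samples are strongly autocorrelated, so striding trades
#'   little accuracy for speed).
#' @return list with `weights` and per-column test `ve`.
#' @export
fitFuture <- function(traces, split, lag, rate,
                      taus = arConfig()$taus, lambda = 1e-4,
                      features = NULL, standardized = FALSE,
                      trainStride = 1L) {
  traces <- as.matrix(traces)
  if (is.null(features)) features <- basisFeatures(traces, taus, rate)
  if (standardized) {
    F <- features
  } else {
    mu <- colMeans(features[split@trainIdx, , drop = FALSE])
    sdv <- apply(features[split@trainIdx, , drop = FALSE], 2, sd)
    sdv[sdv == 0] <- 1
    F <- sweep(sweep(features, 2, mu), 2, sdv, "/")
  }
  dlag <- as.integer(round(lag * rate))
  tr <- split@trainIdx[split@trainIdx - dlag >= 1L]
  if (trainStride > 1L) tr <- tr[seq(1L, length(tr), by = trainStride)]
  te <- split@testIdx[split@testIdx - dlag >= 1L]
  if (length(te) < 2L)
    stop("insufficient test samples at lag ", lag, " s")
  Xtr <- cbind(1, F[tr - dlag, , drop = FALSE])
  Ytr <- traces[tr, , drop = FALSE]
  G <- crossprod(Xtr)
  diag(G) <- diag(G) + lambda * nrow(Xtr)
  W <- solve(G, crossprod(Xtr, Ytr))
  Yhat <- cbind(1, F[te - dlag, , drop = FALSE]) %*% W
  Yte <- traces[te, , drop = FALSE]
  ve <- vapply(seq_len(ncol(Yte)), function(j)
    varianceExplained(Yte[, j], Yhat[, j]), 0)
  list(weights = W, ve = ve)
}

#' Half-decay timescale of a VE-versus-lag curve
#'
#' The first lag (linearly interpolated between grid points) at which
#' variance explained falls to half its value at the 20 ms lag; `Inf` when
#' the curve never reaches half within the lag range, `NA` (flagged with a
#' warning) when VE at 20 ms is not positive.
#'
#' @param lags lags in seconds (ascending; must include 0.02).
#' @param ve variance explained at each lag.
#' @export
halfDecayTime <- function(lags, ve) {
  i0 <- which.min(abs(lags - 0.02))
  v0 <- ve[i0]
  if (!is.finite(v0) || v0 <= 0) {
    warning("VE at 20 ms is not positive; half-decay undefined")
    return(NA_real_)
  }
  half <- 0.5 * v0
  below <- which(ve <= half & seq_along(ve) >= i0)
  if (!length(below)) return(Inf)
  j <- below[1]
  if (j == i0) return(lags[i0])
  # linear interpolation between the bracketing grid points
  l0 <- lags[j - 1]; l1 <- lags[j]
  f <- (ve[j - 1] - half) / (ve[j - 1] - ve[j])
  l0 + f * (l1 - l0)
}

#' Per-keypoint predictability timescales
#'
#' Fits the future-prediction regression at every configured lag and
#' summarizes VE-versus-lag curves and half-decay times per keypoint and per
#' face region (eye / whisker / nose keypoints order by their dynamics:
#' fast-decaying nose, intermediate whiskers, slow eye).
#'
#' @param series a [KeypointSeries-class] (neural-subset bodyparts are
#'   used when present).
#' @param config from [arConfig()].
#' @param lags optional subset of lags to evaluate.
#' @param trainStride passed to [fitFuture()].
#' @return list with `curve` (lag x coordinate VE matrix), `ve_part`,
#'   `ve_group`, `half_decay_part`, `half_decay_group`, `lags`.
#' @export
keypointTimescales <- function(series, config = arConfig(), lags = NULL,
                               trainStride = 1L) {
  if (is.null(lags)) lags <- config$lags
  parts <- if (length(neuralSubset(schema(series))))
    neuralSubset(schema(series)) else bodyparts(series)
  pidx <- match(parts, bodyparts(series))
  co <- series@coords[, pidx, , drop = FALSE]
  nT <- dim(co)[1]
  traces <- cbind(matrix(co[, , 1], nT), matrix(co[, , 2], nT))
  colnames(traces) <- c(paste0(parts, "_x"), paste0(parts, "_y"))
  split <- makeSplit(nT, series@rate, config$nSegments, config$trainFrac,
                     config$gapSec)
  feats <- basisFeatures(traces, config$taus, series@rate)
  mu <- colMeans(feats[split@trainIdx, , drop = FALSE])
  sdv <- apply(feats[split@trainIdx, , drop = FALSE], 2, sd)
  sdv[sdv == 0] <- 1
  feats <- sweep(sweep(feats, 2, mu), 2, sdv, "/")
  curve <- matrix(NA_real_, length(lags), ncol(traces),
                  dimnames = list(NULL, colnames(traces)))
  for (i in seq_along(lags)) {
    curve[i, ] <- fitFuture(traces, split, lags[i], series@rate,
                            config$taus, config$lambda, features = feats,
                            standardized = TRUE,
                            trainStride = trainStride)$ve
  }
  grp <- bodypartGroups(schema(series))[parts]
  partOf <- rep(parts, 2)
  ve_part <- sapply(parts, function(p)
    rowMeans(curve[, partOf == p, drop = FALSE]))
  ve_part <- matrix(ve_part, nrow = length(lags),
                    dimnames = list(NULL, parts))
  ve_group <- sapply(unique(grp), function(g)
    rowMeans(ve_part[, grp == g, drop = FALSE]))
  ve_group <- matrix(ve_group, nrow = length(lags),
                     dimnames = list(NULL, unique(grp)))
  hd <- function(M) apply(M, 2, function(v) halfDecayTime(lags, v))
  list(curve = curve, ve_part = ve_part, ve_group = ve_group,
       half_decay_part = hd(ve_part), half_decay_group = hd(ve_group),
       lags = lags)
}
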