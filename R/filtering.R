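#' Filtering configuration for keypoint trace QC
#'
#' Defaults follow the published rules: the likelihood trace is baselined
#' with a Gaussian filter of s.d. 4 s and samples more than 8 baseline s.d.
#' below baseline are outliers; a Euclidean step of more than 25 px from the
#' previous frame, or a per-axis deviation of more than 25 px from the 1 s
#' median-filtered trace, also flags a frame; imputation uses a 300 ms
#' median filter followed by linear interpolation.
#'
#' @param baseline_sigma Gaussian baseline s.d. in seconds.
#' @param likelihood_threshold_sd residual threshold in baseline s.d.
#'   (negative).
#' @param jump_px maximum Euclidean step between consecutive frames.
#' @param deviation_px maximum deviation from the median-filtered trace.
#' @param deviation_window median filter window for the deviation rule, s.
#' @param impute_window median filter window for imputation, s.
#' @export
filterConfig <- function(baseline_sigma = 4.0, likelihood_threshold_sd = -8,
                         jump_px = 25, deviation_px = 25,
                         deviation_window = 1.0, impute_window = 0.3) {
  stopifnot(baseline_sigma > 0, jump_px > 0, deviation_px > 0,
            deviation_window > 0, impute_window > 0,
            likelihood_threshold_sd < 0)
  list(baseline_sigma = baseline_sigma,
       likelihood_threshold_sd = likelihood_threshold_sd,
       jump_px = jump_px, deviation_px = deviation_px,
       deviation_window = deviation_window, impute_window = impute_window)
}

# Gaussian smoothing with reflective padding
gaussSmooth <- function(x, sigma) {
  r <- max(1L, as.integer(ceiling(3 * sigma)))
  n <- length(x)
  kern <- exp(-((-r):r)^2 / (2 * sigma^2))
  kern <- kern / sum(kern)
  pad <- c(x[pmin(r:1 + 1L, n)], x, x[pmax(n - (1:r), 1L)])
  as.numeric(stats::filter(pad, kern, sides = 2))[r + seq_len(n)]
}

# odd window length (>= 1) nearest to seconds * rate
oddWindow <- function(seconds, rate, n) {
  w <- as.integer(round(seconds * rate))
  if (w %% 2L == 0L) w <- w + 1L
  min(max(w, 1L), if (n %% 2L == 0L) n - 1L else n)
}

#' Likelihood-based outlier detection
#'
#' Per bodypart, the likelihood trace is baselined with a Gaussian filter
#' (s.d. `baseline_sigma` seconds) and the residual is thresholded at
#' `likelihood_threshold_sd` times its standard deviation (default -8 s.d.,
#' so only strong confidence drops are flagged).
#'
#' @param series a [KeypointSeries-class].
#' @param config from [filterConfig()].
#' @return logical frames x bodyparts outlier mask.
#' @export
likelihoodOutliers <- function(series, config = filterConfig()) {
  lik <- series@likelihood
  sig <- config$baseline_sigma * series@rate
  if (nrow(lik) < sig)
    stop("series shorter than one baseline s.d. (", sig, " frames)")
  mask <- matrix(FALSE, nrow(lik), ncol(lik))
  for (p in seq_len(ncol(lik))) {
    resid <- lik[, p] - gaussSmooth(lik[, p], sig)
    s <- sd(resid)
    if (s > 0) mask[, p] <- resid < config$likelihood_threshold_sd * s
  }
  colnames(mask) <- colnames(lik)
  mask
}

#' Jump and deviation outlier detection on coordinate traces
#'
#' Flags frame t when the (x, y) Euclidean step from frame t-1 exceeds
#' `jump_px`, or when either coordinate deviates from its median-filtered
#' trace (window `deviation_window` seconds) by more than `deviation_px`.
#'
#' @inheritParams likelihoodOutliers
#' @return logical frames x bodyparts outlier mask.
#' @export
traceOutliers <- function(series, config = filterConfig()) {
  co <- series@coords
  nT <- dim(co)[1]; nP <- dim(co)[2]
  mask <- matrix(FALSE, nT, nP)
  w <- oddWindow(config$deviation_window, series@rate, nT)
  for (p in seq_len(nP)) {
    x <- co[, p, 1]; y <- co[, p, 2]
    step <- c(0, sqrt(diff(x)^2 + diff(y)^2))
    jump <- step > config$jump_px
    devx <- abs(x - stats::runmed(x, w)) > config$deviation_px
    devy <- abs(y - stats::runmed(y, w)) > config$deviation_px
    mask[, p] <- jump | devx | devy
  }
  colnames(mask) <- bodyparts(series)
  mask
}

#' Impute flagged samples
#'
#' Replaces flagged samples by linear interpolation of the median-filtered
#' trace (window `impute_window` seconds) computed over the non-flagged
#' samples only. Non-flagged samples are never modified.
#'
#' @inheritParams likelihoodOutliers
#' @param mask logical frames x bodyparts matrix of samples to replace.
#' @return a [KeypointSeries-class] with imputed coordinates and an updated
#'   outlier mask.
#' @export
imputeOutliers <- function(series, mask, config = filterConfig()) {
  co <- series@coords
  nT <- dim(co)[1]
  for (p in seq_len(dim(co)[2])) {
    bad <- mask[, p]
    if (!any(bad)) next
    if (all(bad))
      stop("all frames flagged for bodypart '", bodyparts(series)[p], "'")
    good <- which(!bad)
    w <- oddWindow(config$impute_window, series@rate, length(good))
    for (ax in 1:2) {
      med <- stats::runmed(co[good, p, ax], w)
      co[bad, p, ax] <- approx(good, med, xout = which(bad), rule = 2)$y
    }
  }
  new("KeypointSeries", schema = series@schema, coords = co,
      likelihood = series@likelihood, outlierMask = series@outlierMask | mask,
      rate = series@rate)
}

#' Full keypoint QC pipeline
#'
#' Applies likelihood-based and trace-based outlier detection, imputes the
#' flagged samples, and reports per-bodypart flag counts per rule. The
#' flagged fraction is logged for comparison with typical recordings (a few
#' tenths of a percent of samples).
#'
#' @inheritParams likelihoodOutliers
#' @return list with the filtered `series` and a `report` data.frame.
#' @export
filterKeypoints <- function(series, config = filterConfig()) {
  m1 <- likelihoodOutliers(series, config)
  m2 <- traceOutliers(series, config)
  mask <- m1 | m2
  out <- imputeOutliers(series, mask, config)
  report <- data.frame(bodypart = bodyparts(series),
                       likelihood_rule = colSums(m1),
                       trace_rule = colSums(m2),
                       total = colSums(mask))
  logMsg(sprintf("flagged %.3f%% of samples (likelihood %.3f%%, trace %.3f%%)",
                 100 * mean(mask), 100 * mean(m1), 100 * mean(m2)))
  list(series = out, report = report)
}
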