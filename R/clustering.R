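#' Scaled k-means clustering of neurons
#'
#' Fits the model `x_i = lambda_i * mu_{sigma_i} + noise`: like k-means, but
#' with a per-neuron scalar gain `lambda_i`, so neurons sharing a temporal
#' pattern at different amplitudes (or, on z-scored data, with opposite
#' sign) cluster together. Alternating optimization: given assignments,
#' `lambda_i = (x_i . mu_j) / (mu_j . mu_j)`; assignments minimize the
#' residual `||x_i - lambda_i(j) mu_j||^2`; cluster patterns are the
#' gain-weighted means `mu_j = sum lambda_i x_i / sum lambda_i^2`. The sign
#' of each pattern is fixed by making the majority of member gains positive.
#' Initialization is k-means++-style on row-normalized activity; empty
#' clusters are re-seeded from the worst-fit neuron. The objective is
#' non-increasing and iteration stops at an assignment fixpoint.
#'
#' @param activity neurons x timepoints matrix (z-scored).
#' @param k number of clusters (100 in typical use).
#' @param nIter maximum iterations.
#' @param seed RNG seed.
#' @return a [ClusterModel-class].
#' @export
scaledKMeans <- function(activity, k, nIter = 100L, seed = 1L) {
  X <- as.matrix(activity)
  stopifnot(all(is.finite(X)), k <= nrow(X))
  set.seed(seed)
  n <- nrow(X)
  rn <- sqrt(rowSums(X^2)); rn[rn == 0] <- 1
  Xn <- X / rn
  # k-means++ seeding on normalized rows
  centers <- matrix(0, k, ncol(X))
  first <- sample.int(n, 1L)
  centers[1, ] <- Xn[first, ]
  d2 <- rowSums(sweep(Xn, 2, centers[1, ])^2)
  for (j in seq_len(k)[-1]) {
    p <- d2 / sum(d2)
    nxt <- sample.int(n, 1L, prob = p)
    centers[j, ] <- Xn[nxt, ]
    d2 <- pmin(d2, rowSums(sweep(Xn, 2, centers[j, ])^2))
  }
  xx <- rowSums(X^2)
  assign_prev <- rep(0L, n)
  objective <- numeric(0)
  for (it in seq_len(nIter)) {
    cn <- rowSums(centers^2)
    cn[cn == 0] <- 1e-12
    proj <- X %*% t(centers)               # n x k dot products
    gain2 <- sweep(proj^2, 2, cn, "/")     # ||x||^2 - this = residual
    assign <- max.col(gain2, ties.method = "first")
    lambda <- proj[cbind(seq_len(n), assign)] / cn[assign]
    obj <- sum(xx - gain2[cbind(seq_len(n), assign)])
    # handle empty clusters: re-seed from the worst-fit neuron
    resid <- xx - gain2[cbind(seq_len(n), assign)]
    for (j in which(tabulate(assign, k) == 0L)) {
      worst <- which.max(resid)
      centers[j, ] <- X[worst, ]
      assign[worst] <- j
      lambda[worst] <- 1
      resid[worst] <- 0
      logMsg("scaledKMeans: re-seeded empty cluster ", j)
    }
    objective <- c(objective, obj)
    nObj <- length(objective)
    converged <- identical(assign, assign_prev) && nObj > 1L &&
      objective[nObj - 1L] - obj <= 1e-9 * max(obj, 1e-12)
    assign_prev <- assign
    if (converged) break
    for (j in seq_len(k)) {
      m <- assign == j
      if (!any(m)) next
      lam <- lambda[m]
      centers[j, ] <- colSums(X[m, , drop = FALSE] * lam) / sum(lam^2)
      if (sum(lam > 0) < sum(lam < 0)) {  # majority-positive gains
        centers[j, ] <- -centers[j, ]
      }
    }
  }
  # final gains against final centers
  cn <- rowSums(centers^2); cn[cn == 0] <- 1e-12
  proj <- X %*% t(centers)
  lambda <- proj[cbind(seq_len(n), assign_prev)] / cn[assign_prev]
  traces <- matrix(0, k, ncol(X))
  for (j in seq_len(k)) {
    m <- assign_prev == j
    if (any(m)) traces[j, ] <- colMeans(X[m, , drop = FALSE])
  }
  new("ClusterModel", assignments = assign_prev, lambda = lambda,
      centers = centers, traces = traces, objective = objective)
}

#' Correlation of cluster activity with its prediction
#'
#' Averages the per-neuron model predictions over each cluster's members and
#' correlates this mean prediction with the cluster's mean activity trace on
#' test frames (Pearson r per cluster; NA when a trace is constant).
#'
#' @param model a [ClusterModel-class].
#' @param activity neurons x timepoints matrix used for clustering.
#' @param predictions neurons x timepoints matrix of per-neuron predictions.
#' @param testIdx frames to evaluate on.
#' @return numeric vector of r values, one per cluster.
#' @export
clusterPredictionR <- function(model, activity, predictions, testIdx) {
  k <- nrow(model@centers)
  r <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    m <- model@assignments == j
    if (!any(m)) next
    a <- colMeans(activity[m, testIdx, drop = FALSE])
    p <- colMeans(predictions[m, testIdx, drop = FALSE])
    if (sd(a) == 0 || sd(p) == 0) next
    r[j] <- cor(a, p)
  }
  r
}

#' Spatial locality index of clusters
#'
#' For each cluster, the Kullback-Leibler divergence between the cluster's
#' discretized spatial distribution in the field of view and the discretized
#' distribution of all neurons, with square bins of `binUm` micrometers
#' anchored at the data bounding box. A pseudocount of 0.5 is added to every
#' bin of the all-neuron histogram before normalizing, so the divergence is
#' defined even where the cluster occupies bins with few reference neurons.
#' Low values mean spatially diffuse clusters.
#'
#' @param model a [ClusterModel-class].
#' @param positions neurons x 2 positions in micrometers.
#' @param binUm bin side length (default 200).
#' @return KL divergence (nats) per cluster.
#' @export
localityIndex <- function(model, positions, binUm = 200) {
  stopifnot(all(is.finite(positions)))
  rngx <- range(positions[, 1]); rngy <- range(positions[, 2])
  if (diff(rngx) == 0 || diff(rngy) == 0)
    stop("degenerate field of view: zero spatial extent")
  bx <- pmin(floor((positions[, 1] - rngx[1]) / binUm),
             floor(diff(rngx) / binUm))
  by <- pmin(floor((positions[, 2] - rngy[1]) / binUm),
             floor(diff(rngy) / binUm))
  nbx <- max(bx) + 1L; nby <- max(by) + 1L
  cell <- bx * nby + by + 1L
  ncell <- nbx * nby
  Q <- tabulate(cell, ncell) + 0.5
  Q <- Q / sum(Q)
  k <- nrow(model@centers)
  kl <- rep(NA_real_, k)
  for (j in seq_len(k)) {
    m <- model@assignments == j
    if (!any(m)) next
    P <- tabulate(cell[m], ncell)
    P <- P / sum(P)
    nz <- P > 0
    kl[j] <- sum(P[nz] * log(P[nz] / Q[nz]))
  }
  kl
}
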