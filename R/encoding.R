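#' Single-trace variance explained
#'
#' `VE = 1 - SSE / SST`, where SSE is the squared error between test trace
#' and prediction and SST is the sum of squared deviations of the test trace
#' from its own mean, so a constant mean prediction scores exactly 0 and a
#' perfect prediction scores 1. A zero-variance test trace is undefined and
#' returns `NA` (callers exclude such units).
#'
#' @param test,pred numeric vectors of equal length (>= 2).
#' @export
varianceExplained <- function(test, pred) {
  stopifnot(length(test) == length(pred), length(test) >= 2)
  sst <- sum((test - mean(test))^2)
  if (sst == 0) return(NA_real_)
  1 - sum((test - pred)^2) / sst
}

#' Cumulative variance explained across neural PCs
#'
#' The cumulative explained variance over the first i PCs, normalized by the
#' total variance over all PCs:
#' `cum_i = sum_{k<=i} (SST_k - SSE_k) / sum_k SST_k`.
#'
#' @param Ytest,Ypred timepoints x PCs matrices of test-period PC traces and
#'   their predictions.
#' @return numeric curve of length `ncol(Ytest)`.
#' @export
cumulativeVE <- function(Ytest, Ypred) {
  sst <- colSums(sweep(Ytest, 2, colMeans(Ytest))^2)
  sse <- colSums((Ytest - Ypred)^2)
  cumsum(sst - sse) / sum(sst)
}

# z-score rows; zero-variance rows flagged and left at zero
zscoreRows <- function(A) {
  mu <- rowMeans(A)
  s <- apply(A, 1, sd)
  flagged <- s == 0
  s[flagged] <- 1
  list(z = (A - mu) / s, flagged = flagged)
}

#' Truncated SVD of z-scored neural activity
#'
#' Each neuron is z-scored, then a truncated SVD with `k` components is
#' taken. Returns loadings `U` (neurons x k), singular values `S` and the
#' neural PC traces `Y = V S` (timepoints x k). The sign of each component
#' is fixed by making its largest-magnitude loading positive. Zero-variance
#' neurons are flagged and excluded from downstream VE denominators.
#'
#' @param x a [NeuralRecording-class] or neurons x timepoints matrix.
#' @param k number of components (default 128).
#' @export
neuralSVD <- function(x, k = 128L) {
  A <- if (is(x, "NeuralRecording")) activity(x) else x
  if (k > min(dim(A))) stop("k exceeds matrix dimensions")
  zs <- zscoreRows(A)
  sv <- svd(zs$z, nu = k, nv = k)
  U <- sv$u
  S <- sv$d[seq_len(k)]
  flip <- vapply(seq_len(k), function(j) {
    jj <- which.max(abs(U[, j]))
    if (U[jj, j] < 0) -1 else 1
  }, 0)
  U <- sweep(U, 2, flip, "*")
  V <- sweep(sv$v, 2, flip, "*")
  list(U = U, S = S, Y = sweep(V, 2, S, "*"), flagged = zs$flagged)
}

#' Reduced-rank ridge regression
#'
#' Closed-form reduced-rank regression `Y = X B A'`: a ridge solution
#' (lambda added to the input Gram matrix) followed by rank truncation in the
#' output space, projecting the fitted values onto their top principal
#' directions. At full rank and vanishing lambda this equals ordinary least
#' squares.
#'
#' @param X timepoints x inputs matrix.
#' @param Y timepoints x outputs matrix.
#' @param rank rank constraint (<= min(inputs, outputs)).
#' @param lambda ridge constant added to the input Gram matrix.
#' @param trainIdx rows used for fitting (default all).
#' @return an object of class `"rrrModel"` with elements `B` (inputs x
#'   rank), `A` (outputs x rank), centers and hyperparameters.
#' @export
fitRRR <- function(X, Y, rank, lambda = 1e-6, trainIdx = NULL) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (is.null(trainIdx)) trainIdx <- seq_len(nrow(X))
  if (rank > min(ncol(X), ncol(Y)))
    stop("rank exceeds input/output dimensionality")
  muX <- colMeans(X[trainIdx, , drop = FALSE])
  muY <- colMeans(Y[trainIdx, , drop = FALSE])
  Xc <- sweep(X[trainIdx, , drop = FALSE], 2, muX)
  Yc <- sweep(Y[trainIdx, , drop = FALSE], 2, muY)
  G <- crossprod(Xc)
  diag(G) <- diag(G) + lambda
  Bfull <- tryCatch(solve(G, crossprod(Xc, Yc)), error = function(e)
    stop("singular input covariance; use lambda > 0"))
  fitted <- Xc %*% Bfull
  sv <- svd(fitted, nu = 0, nv = rank)
  A <- sv$v[, seq_len(rank), drop = FALSE]
  structure(list(B = Bfull %*% A, A = A, muX = muX, muY = muY,
                 rank = rank, lambda = lambda), class = "rrrModel")
}

#' @rdname fitRRR
#' @param model an `"rrrModel"`.
#' @param newX matrix of inputs to predict from.
#' @export
predictRRR <- function(model, newX) {
  sweep(sweep(as.matrix(newX), 2, model$muX) %*% model$B %*% t(model$A),
        2, model$muY, "+")
}

#' Deep encoder architecture and training settings
#'
#' The five-layer core: a pure linear layer (inputs to inputs, no bias), a
#' temporal convolution with `conv_filters` filters (kernel `conv_kernel`
#' behavior frames, centered, zero padded), a ReLU, and two fully-connected
#' ReLU layers of widths 50 and 256. The 256-dimensional output is the
#' "deep behavioral features"; a linear readout maps them (subsampled at
#' neural frame times) to the 128 neural PCs, or directly to neurons when
#' fewer than 200 are predicted. Training uses AdamW with learning rate 1e-1,
#' weight decay 1e-4 and 300 epochs, annealed by 10x at 2/3 and 5/6 of
#' training; fits with fewer than 2,000 target neurons divide the learning
#' rate and weight decay by 10, and fits with under 1 h of training data
#' halve them and drop 100 epochs.
#'
#' @param conv_filters temporal convolution output channels.
#' @param conv_kernel convolution kernel length in behavior frames (odd).
#' @param hidden width of the first fully-connected layer.
#' @param n_features deep behavioral feature dimension.
#' @param lr,weight_decay,epochs optimizer settings.
#' @export
encoderSpec <- function(conv_filters = 10L, conv_kernel = 51L, hidden = 50L,
                        n_features = 256L, lr = 1e-1, weight_decay = 1e-4,
                        epochs = 300L) {
  stopifnot(conv_kernel %% 2L == 1L)
  list(conv_filters = as.integer(conv_filters),
       conv_kernel = as.integer(conv_kernel), hidden = as.integer(hidden),
       n_features = as.integer(n_features), lr = lr,
       weight_decay = weight_decay, epochs = as.integer(epochs))
}

# Forward pass evaluated only at the requested output rows: the temporal
# convolution gathers a window of the linear layer's output around each
# row, and the per-timepoint fully-connected layers run on those rows only.
# X covers rows 1..nrow(X); `rows` are 1-based indices into X.
encoderForward <- function(par, X, rows, spec) {
  T <- nrow(X)
  H0 <- X %*% par$W0
  m <- length(rows)
  Cv <- matrix(rep(par$bc, each = m), m)
  for (j in seq_along(par$offsets)) {
    src <- rows + par$offsets[j]
    ok <- src >= 1L & src <= T
    Cv[ok, ] <- Cv[ok, ] + H0[src[ok], , drop = FALSE] %*% par$Wc[[j]]
  }
  R <- reluFwd(Cv)
  H1 <- reluFwd(sweep(R %*% par$W1, 2, par$b1, "+"))
  Z <- reluFwd(sweep(H1 %*% par$W2, 2, par$b2, "+"))
  P <- sweep(Z %*% par$W3, 2, par$b3, "+")
  list(H0 = H0, Cv = Cv, R = R, H1 = H1, Z = Z, P = P)
}

encoderBackward <- function(par, X, rows, fwd, dP) {
  T <- nrow(X)
  g <- list()
  g$W3 <- crossprod(fwd$Z, dP)
  g$b3 <- colSums(dP)
  dZ <- reluBwd(dP %*% t(par$W3), fwd$Z)
  g$W2 <- crossprod(fwd$H1, dZ)
  g$b2 <- colSums(dZ)
  dH1 <- reluBwd(dZ %*% t(par$W2), fwd$H1)
  g$W1 <- crossprod(fwd$R, dH1)
  g$b1 <- colSums(dH1)
  dR <- reluBwd(dH1 %*% t(par$W1), fwd$Cv)
  dH0 <- matrix(0, T, ncol(fwd$H0))
  g$Wc <- vector("list", length(par$offsets))
  for (j in seq_along(par$offsets)) {
    src <- rows + par$offsets[j]
    ok <- src >= 1L & src <= T
    g$Wc[[j]] <- crossprod(fwd$H0[src[ok], , drop = FALSE],
                           dR[ok, , drop = FALSE])
    dH0[src[ok], ] <- dH0[src[ok], ] + dR[ok, , drop = FALSE] %*%
      t(par$Wc[[j]])
  }
  g$bc <- colSums(dR)
  g$W0 <- crossprod(X, dH0)
  g
}

#' Align behavior frames to neural frames
#'
#' Returns, for each neural frame, the index of the nearest behavior frame at
#' or before it (causal alignment). Frame i is taken to occur at time
#' `(i - 1) / rate`.
#'
#' @param nNeural number of neural frames.
#' @param behRate,neuRate sampling rates in Hz.
#' @param nBehavior number of behavior frames (for clamping).
#' @export
alignFrames <- function(nNeural, behRate, neuRate, nBehavior) {
  t_neu <- (seq_len(nNeural) - 1) / neuRate
  pmin(pmax(floor(t_neu * behRate) + 1L, 1L), nBehavior)
}

#' Fit the deep behavior-to-neural encoder
#'
#' Trains the five-layer network end to end with AdamW; each training batch
#' is one training segment of the split. Inputs are behavior-rate traces
#' (e.g. the 22 neural-subset keypoint coordinates); targets are neural-rate
#' traces (neural PCs, or neurons directly when fewer than 200). Small-data
#' adjustments and annealing follow [encoderSpec()]. Deterministic for a
#' given seed.
#'
#' @param X behavior-rate inputs, T_beh x p (finite; filter first).
#' @param Y neural-rate targets, T_neu x q.
#' @param behRate,neuRate sampling rates in Hz.
#' @param split a [SegmentSplit-class] over neural frames.
#' @param spec from [encoderSpec()].
#' @param seed RNG seed.
#' @param nNeurons number of neurons behind the targets (drives the
#'   small-data learning-rate adjustment); defaults to `ncol(Y)`.
#' @return an [EncodingFit-class] with per-target-unit test VE, the deep
#'   behavioral features at behavior rate, and the loss history.
#' @export
fitEncoder <- function(X, Y, behRate, neuRate, split, spec = encoderSpec(),
                       seed = 1L, nNeurons = ncol(Y)) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  if (anyNA(X) || any(!is.finite(X)))
    stop("inputs contain NaN; run filterKeypoints() first")
  set.seed(seed)
  # targets are scaled by the s.d. of the leading output so the readout
  # weights live at order 1; this rescales the loss by a constant only, and
  # predictions are mapped back to the original scale
  yscale <- sd(Y[, 1])
  if (!is.finite(yscale) || yscale == 0) yscale <- 1
  Y <- Y / yscale
  p <- ncol(X); q <- ncol(Y)
  lr <- spec$lr; wd <- spec$weight_decay; epochs <- spec$epochs
  if (nNeurons < 2000) { lr <- lr / 10; wd <- wd / 10 }
  trainHours <- length(split@trainIdx) / neuRate / 3600
  if (trainHours < 1) { lr <- lr / 2; wd <- wd / 2
                        epochs <- max(epochs - 100L, 20L) }
  half <- (spec$conv_kernel - 1L) %/% 2L
  offsets <- (-half):half
  par <- list(
    W0 = heInit(p, p, gain = 1),
    Wc = lapply(offsets, function(k)
      heInit(spec$conv_filters, p, gain = sqrt(2 / spec$conv_kernel))),
    bc = rep(0, spec$conv_filters),
    W1 = heInit(spec$hidden, spec$conv_filters),
    b1 = rep(0, spec$hidden),
    W2 = heInit(spec$n_features, spec$hidden),
    b2 = rep(0, spec$n_features),
    # zero-initialized readout: the first steps fit the readout before any
    # error reaches the core, preventing early ReLU collapse at high lr
    W3 = matrix(0, q, spec$n_features),
    b3 = rep(0, q),
    offsets = offsets)
  # matrices are stored output x input above; transpose to input x output
  par$W0 <- t(par$W0); par$Wc <- lapply(par$Wc, t); par$W1 <- t(par$W1)
  par$W2 <- t(par$W2); par$W3 <- t(par$W3)
  trainable <- c("W0", "bc", "W1", "b1", "W2", "b2", "W3", "b3")
  states <- adamInit(par[trainable])
  statesWc <- lapply(par$Wc, function(w) adamInit(list(w))[[1]])
  sub <- alignFrames(nrow(Y), behRate, neuRate, nrow(X))
  anneal <- round(epochs * c(2, 2.5) / 3)
  history <- numeric(epochs)
  step <- 0L
  segs <- split@segTrain
  for (ep in seq_len(epochs)) {
    lr_ep <- lr / 10^(sum(ep > anneal))
    ord <- sample.int(length(segs))
    epl <- 0
    for (sg in ord) {
      nidx <- segs[[sg]]
      bw <- range(sub[nidx])
      rows <- max(1L, bw[1] - half):min(nrow(X), bw[2] + half)
      subLocal <- sub[nidx] - rows[1] + 1L
      Xw <- X[rows, , drop = FALSE]
      fwd <- encoderForward(par, Xw, subLocal, spec)
      res <- fwd$P - Y[nidx, , drop = FALSE]
      loss <- mean(res^2)
      dP <- 2 * res / length(res)
      g <- encoderBackward(par, Xw, subLocal, fwd, dP)
      step <- step + 1L
      for (nm in trainable) {
        up <- adamStep(par[[nm]], g[[nm]], states[[nm]], lr_ep, step,
                       decay = wd)
        par[[nm]] <- up$p; states[[nm]] <- up$state
      }
      for (m in seq_along(par$Wc)) {
        up <- adamStep(par$Wc[[m]], g$Wc[[m]], statesWc[[m]], lr_ep, step,
                       decay = wd)
        par$Wc[[m]] <- up$p; statesWc[[m]] <- up$state
      }
      epl <- epl + loss
    }
    history[ep] <- epl / length(segs)
  }
  fwd <- encoderForward(par, X, sub, spec)
  te <- split@testIdx
  ve <- vapply(seq_len(q), function(j)
    varianceExplained(Y[te, j], fwd$P[te, j]), 0)
  # deep behavioral features at full behavior rate
  Zfull <- encoderForward(par, X, seq_len(nrow(X)), spec)$Z
  new("EncodingFit", type = "deep",
      model = list(par = par, spec = spec, sub = sub, yscale = yscale,
                   behRate = behRate, neuRate = neuRate),
      split = split,
      ledger = data.frame(unit = seq_len(q), ve = ve),
      features = Zfull, history = history)
}

#' Predictions from a fitted deep encoder
#'
#' @param fit an [EncodingFit-class] of type `"deep"`.
#' @param X behavior-rate inputs (defaults cannot be recovered; supply the
#'   same matrix used for fitting to reproduce training-time predictions).
#' @return neural-rate predictions, T_neu x q.
#' @export
predictEncoder <- function(fit, X) {
  stopifnot(fit@type == "deep")
  m <- fit@model
  encoderForward(m$par, as.matrix(X), m$sub, m$spec)$P * m$yscale
}

#' Explainable variance by peer prediction
#'
#' Splits the population into two spatially segregated groups by assigning
#' neurons in even 200-um-wide strips of x position to one group and odd
#' strips to the other (depth ignored), computes the top-k PCs of each
#' group, predicts one group's PCs from the other's with reduced-rank
#' regression (both directions), projects predictions back to neurons, and
#' scores each neuron's explainable variance (EV) on test frames. EV is the
#' upper bound used to normalize model VE.
#'
#' @param recording a [NeuralRecording-class].
#' @param split a [SegmentSplit-class] over neural frames.
#' @param stripWidth strip width in micrometers (default 200).
#' @param lambda ridge constant (default 1e-1).
#' @param rank RRR rank (default k - 1).
#' @param k PCs per group (default 128).
#' @return per-neuron EV vector (NA for zero-variance neurons).
#' @export
peerPrediction <- function(recording, split, stripWidth = 200,
                           lambda = 1e-1, k = 128L, rank = k - 1L) {
  act <- activity(recording)
  pos <- positions(recording)
  strip <- floor((pos[, 1] - min(pos[, 1])) / stripWidth)
  even <- strip %% 2 == 0
  groups <- list(which(even), which(!even))
  if (any(vapply(groups, length, 0L) < k))
    stop("a parity group has fewer than k = ", k,
         " neurons; use a smaller k")
  ev <- rep(NA_real_, nrow(act))
  zs <- lapply(groups, function(g) zscoreRows(act[g, , drop = FALSE]))
  svds <- lapply(zs, function(z) {
    sv <- svd(z$z, nu = k, nv = k)
    list(U = sv$u, Y = sweep(sv$v, 2, sv$d[seq_len(k)], "*"))
  })
  for (d in 1:2) {
    from <- svds[[d]]; to <- svds[[3 - d]]
    gi <- groups[[3 - d]]
    rr <- fitRRR(from$Y, to$Y, rank = rank, lambda = lambda,
                 trainIdx = split@trainIdx)
    Yhat <- predictRRR(rr, from$Y[split@testIdx, , drop = FALSE])
    predAct <- to$U %*% t(Yhat)
    zTest <- zs[[3 - d]]$z[, split@testIdx, drop = FALSE]
    for (i in seq_along(gi)) {
      if (zs[[3 - d]]$flagged[i]) next
      ev[gi[i]] <- varianceExplained(zTest[i, ], predAct[i, ])
    }
  }
  ev
}

#' Normalized variance explained
#'
#' Neuron-level: VE / EV, reported only where EV > 1e-3. Population-level:
#' mean VE across neurons divided by mean EV across neurons.
#'
#' @param ve,ev per-neuron variance explained and explainable variance.
#' @return list with `per_neuron` (NA where EV <= 1e-3) and `population`.
#' @export
normalizedVE <- function(ve, ev) {
  keep <- is.finite(ev) & ev > 1e-3 & is.finite(ve)
  per <- rep(NA_real_, length(ve))
  per[keep] <- ve[keep] / ev[keep]
  ok <- is.finite(ve) & is.finite(ev)
  list(per_neuron = per,
       population = mean(ve[ok]) / mean(ev[ok]))
}

#' Performance scaling with neurons and training time
#'
#' Refits the linear (RRR) prediction on random neuron subsets or truncated
#' training timepoints (test frames always fixed), reporting VE normalized
#' by the explainable variance averaged over the neurons in each subset.
#'
#' @param recording a [NeuralRecording-class].
#' @param X neural-rate behavioral inputs (T_neu x p).
#' @param split a [SegmentSplit-class].
#' @param ev per-neuron explainable variance (from [peerPrediction()]).
#' @param neuronFracs,timeFracs fractions in (0, 1] to evaluate.
#' @param k SVD components; `rank`, `lambda` passed to [fitRRR()].
#' @param seed RNG seed for neuron subsampling.
#' @return data.frame with `resource`, `fraction`, `nve`.
#' @export
scalingCurves <- function(recording, X, split, ev, neuronFracs = 1,
                          timeFracs = 1, k = 32L, rank = 16L,
                          lambda = 1e-6, seed = 1L) {
  set.seed(seed)
  act <- activity(recording)
  n <- nrow(act)
  res <- data.frame()
  fitOne <- function(nidx, trIdx) {
    kk <- min(k, length(nidx))
    if (kk < 2) { warning("subset too small for SVD; skipped"); return(NA) }
    sv <- neuralSVD(act[nidx, , drop = FALSE], k = kk)
    rr <- fitRRR(X, sv$Y, rank = min(rank, kk), lambda = lambda,
                 trainIdx = trIdx)
    Yhat <- predictRRR(rr, X[split@testIdx, , drop = FALSE])
    predAct <- sv$U %*% t(Yhat)
    z <- zscoreRows(act[nidx, , drop = FALSE])
    veN <- vapply(seq_along(nidx), function(i)
      if (z$flagged[i]) NA_real_ else
        varianceExplained(z$z[i, split@testIdx], predAct[i, ]), 0)
    ok <- is.finite(veN) & is.finite(ev[nidx])
    mean(veN[ok]) / mean(ev[nidx][ok])
  }
  for (f in neuronFracs) {
    nidx <- sort(sample.int(n, max(2L, round(f * n))))
    res <- rbind(res, data.frame(resource = "neurons", fraction = f,
                                 nve = fitOne(nidx, split@trainIdx)))
  }
  for (f in timeFracs) {
    trIdx <- unlist(lapply(split@segTrain, function(s)
      s[seq_len(max(2L, floor(f * length(s))))]))
    res <- rbind(res, data.frame(resource = "timepoints", fraction = f,
                                 nve = fitOne(seq_len(n), trIdx)))
  }
  res
}
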