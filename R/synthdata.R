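# Synthetic fixture generators. Every generator is seed-deterministic and
# returns both data and ground truth, so each analysis module can be tested
# without external downloads.

# discrete Ornstein-Uhlenbeck sample path with unit stationary variance
ouProcess <- function(T, rate, tau, sd = 1) {
  a <- exp(-1 / (tau * rate))
  x <- numeric(T)
  x[1] <- rnorm(1, sd = sd)
  innov <- rnorm(T - 1, sd = sd * sqrt(1 - a^2))
  for (t in 2:T) x[t] <- a * x[t - 1] + innov[t - 1]
  x
}

#' Multi-timescale synthetic keypoint traces
#'
#' Ornstein-Uhlenbeck motion with group-specific timescales emulating the
#' observed ordering of orofacial dynamics: slow eye drift (tau ~ 5 s), fast
#' nose motion (tau ~ 0.5 s), and whisker motion with an added ~10 Hz
#' oscillation whose phase diffuses (pseudo-random whisking). OU processes
#' have a known analytic autocorrelation `exp(-lag/tau)`, giving closed-form
#' targets for the timescale estimator.
#'
#' @param T number of frames.
#' @param rate frame rate in Hz (default 50).
#' @param seed RNG seed.
#' @param taus named group timescales in seconds.
#' @param amplitudes named group motion amplitudes in pixels.
#' @param whiskHz whisking oscillation frequency.
#' @param whiskAmp oscillation amplitude in pixels (0 disables).
#' @param schema keypoint schema (default 13-point).
#' @param center base position of all keypoints.
#' @return a [KeypointSeries-class] around per-keypoint base positions.
#' @export
synthKeypointTraces <- function(T, rate = 50, seed = 1L,
                                taus = c(eye = 5, nose = 0.5,
                                         whisker = 0.5, mouth = 1),
                                amplitudes = c(eye = 4, nose = 8,
                                               whisker = 6, mouth = 4),
                                whiskHz = 10, whiskAmp = 4,
                                schema = defaultSchema(),
                                center = c(64, 64)) {
  set.seed(seed)
  parts <- bodyparts(schema)
  grp <- bodypartGroups(schema)
  co <- array(0, c(T, length(parts), 2))
  base <- cbind(center[1] + stats::runif(length(parts), -20, 20),
                center[2] + stats::runif(length(parts), -20, 20))
  tt <- (seq_len(T) - 1) / rate
  for (p in seq_along(parts)) {
    g <- grp[parts[p]]
    tau <- if (g %in% names(taus)) taus[[g]] else 1
    amp <- if (g %in% names(amplitudes)) amplitudes[[g]] else 4
    for (ax in 1:2) {
      x <- amp * ouProcess(T, rate, tau)
      if (g == "whisker" && whiskAmp > 0) {
        phase <- cumsum(rnorm(T, sd = 0.3)) # diffusing phase
        x <- x + whiskAmp * sin(2 * pi * whiskHz * tt + phase)
      }
      co[, p, ax] <- base[p, ax] + x
    }
  }
  dimnames(co) <- list(NULL, parts, c("x", "y"))
  keypointSeries(co, rate = rate, schema = schema)
}

#' Render a toy face video with known keypoints
#'
#' Each keypoint is drawn as a Gaussian blob with its own amplitude and
#' width on a smooth background; motion comes from [synthKeypointTraces()]
#' scaled to keep every keypoint at least twice its blob width inside the
#' image (reflected at the margin otherwise). Returns frames together with
#' the exact ground-truth keypoint series.
#'
#' @param T number of frames.
#' @param size square frame side in pixels.
#' @param seed RNG seed.
#' @param schema keypoint schema; use a reduced schema for fast tests.
#' @param noise additive Gaussian pixel noise s.d.
#' @param motionScale multiplies the keypoint motion (0 freezes the scene).
#' @param shift constant (x, y) offset of the whole face, for domain-shift
#'   fixtures.
#' @param blobAmp amplitude offset for appearance-shift fixtures.
#' @return list with `frames` (size x size x T) and `series`.
#' @export
synthFaceVideo <- function(T, size = 64L, seed = 1L,
                           schema = defaultSchema(), noise = 0.02,
                           motionScale = 1, shift = c(0, 0),
                           blobAmp = 1) {
  set.seed(seed)
  parts <- bodyparts(schema)
  nP <- length(parts)
  # systematically distinct templates: evenly spaced widths and amplitude
  # magnitudes with alternating sign, so every keypoint is identifiable by
  # appearance (randomly drawn templates can make two same-sign blobs near
  # duplicates, an ill-posed tracking target)
  width <- seq(1.5, 3, length.out = nP)
  amp <- blobAmp * seq(1, 0.6, length.out = nP) *
    rep_len(c(1, -1), nP)          # bright and dark blobs
  margin <- 2 * max(width)
  tr <- synthKeypointTraces(T, seed = seed + 1L, schema = schema,
                            center = c(0, 0))
  co <- coords(tr)
  # each keypoint owns one cell of a grid (like anatomy: landmarks never
  # swap places); its motion is reflected at the cell margins, so blobs
  # can approach but never merge into an unresolvable compound
  g <- ceiling(sqrt(nP))
  cellOf <- seq_len(nP)   # fixed layout: anatomy does not move across videos
  cell <- size / g
  refl <- function(x, lo, hi) {
    span <- hi - lo
    y <- (x - lo) %% (2 * span)
    lo + pmin(y, 2 * span - y)
  }
  for (p in seq_len(nP)) {
    cx <- ((cellOf[p] - 1L) %% g) * cell
    cy <- ((cellOf[p] - 1L) %/% g) * cell
    co[, p, 1] <- refl(cx + cell / 2 + co[, p, 1] * motionScale + shift[1],
                       cx + margin, cx + cell - 1 - margin)
    co[, p, 2] <- refl(cy + cell / 2 + co[, p, 2] * motionScale + shift[2],
                       cy + margin, cy + cell - 1 - margin)
  }
  gx <- matrix(rep(0:(size - 1), each = size), size)   # x varies by column
  gy <- matrix(rep(0:(size - 1), size), size)          # y varies by row
  bgd <- 0.2 + 0.1 * gx / size + 0.05 * gy / size
  frames <- array(0, c(size, size, T))
  for (t in seq_len(T)) {
    img <- bgd
    for (p in seq_len(nP)) {
      img <- img + amp[p] *
        exp(-((gx - co[t, p, 1])^2 + (gy - co[t, p, 2])^2) /
              (2 * width[p]^2))
    }
    frames[, , t] <- img + matrix(rnorm(size * size, sd = noise), size)
  }
  series <- keypointSeries(co, rate = frameRate(tr), schema = schema)
  list(frames = frames, series = series)
}

#' Synthetic neural population driven by behavior
#'
#' Latent signals are a planted nonlinear network (random linear map,
#' ReLU, random linear map) of the keypoint coordinates. Each neuron is
#' assigned one behavioral latent and one shared non-behavioral latent
#' (slow OU processes), and its activity at the neural frame rate is
#' `sqrt(behaviorFrac) * latent + sqrt(sharedFrac) * shared +
#' sqrt(noiseFrac) * iid noise`, all components having unit variance, so the
#' ground-truth explainable variance is `behaviorFrac + sharedFrac` and the
#' behavior-explainable part is `behaviorFrac`. Neuron positions are drawn
#' from per-latent 2-D Gaussians whose spreads are configurable, so some
#' latents are spatially compact and others diffuse.
#'
#' @param series a [KeypointSeries-class] at behavior rate.
#' @param nNeurons population size.
#' @param behaviorFrac,sharedFrac,noiseFrac per-neuron variance fractions
#'   (each summing to 1); scalars apply to all neurons, vectors of length
#'   `nLatents` give each latent group its own profile (e.g. a diffuse
#'   behavior-driven group next to a compact noise-dominated group).
#' @param nLatents behavioral latents from the planted network.
#' @param nonlinearFrac fraction of each latent's variance carried by the
#'   even-symmetric (linearly unrecoverable) part of the planted network.
#' @param latentGroups bodypart groups whose coordinates drive the planted
#'   network (default the slow eye group, emulating arousal-like states);
#'   NULL uses every coordinate.
#' @param latentTau optional extra exponential smoothing of the latents in
#'   seconds (0 disables).
#' @param nShared shared non-behavioral latents.
#' @param neuRate neural frame rate in Hz.
#' @param spreads per-latent spatial spread in micrometers (recycled over
#'   latent groups); mix diffuse and compact values (e.g. `c(400, 50)`) to
#'   build locality fixtures. Note that strongly compact groups confound
#'   peer prediction, since a cluster confined to one 200-um strip is
#'   invisible to the opposite strip parity.
#' @param fovUm field-of-view side in micrometers.
#' @param seed RNG seed.
#' @return list with `recording` ([NeuralRecording-class]), `groups`
#'   (latent of each neuron), `trueEV`, `trueBehaviorVE`, `latents`,
#'   `shared`.
#' @export
synthNeuralFromBehavior <- function(series, nNeurons = 400L,
                                    behaviorFrac = 0.6, sharedFrac = 0.1,
                                    noiseFrac = 0.3, nLatents = 4L,
                                    nonlinearFrac = 0.5,
                                    latentGroups = "eye",
                                    latentTau = 0,
                                    nShared = 8L, neuRate = 3,
                                    spreads = 400, fovUm = 1000,
                                    seed = 1L) {
  behaviorFrac <- rep_len(behaviorFrac, nLatents)
  sharedFrac <- rep_len(sharedFrac, nLatents)
  noiseFrac <- rep_len(noiseFrac, nLatents)
  stopifnot(all(abs(behaviorFrac + sharedFrac + noiseFrac - 1) < 1e-8))
  set.seed(seed)
  co <- coords(series)
  nT <- dim(co)[1]
  # planted-network inputs: coordinates of the slow, arousal-like bodypart
  # groups by default (widespread behavior-driven activity follows slow
  # state variables, not fast movement phases)
  parts <- bodyparts(schema(series))
  grp <- bodypartGroups(schema(series))[parts]
  keep <- if (is.null(latentGroups)) rep(TRUE, length(parts)) else
    grp %in% latentGroups
  if (!any(keep)) keep <- rep(TRUE, length(parts))
  Ks <- scale(cbind(matrix(co[, keep, 1], nT), matrix(co[, keep, 2], nT)))
  p <- ncol(Ks)
  W1 <- matrix(rnorm(p * 16), p, 16)
  W2 <- matrix(rnorm(16 * nLatents), 16, nLatents)
  Wl <- matrix(rnorm(p * nLatents), p, nLatents)
  # Latents mix a linear readout of the keypoints with an even-symmetric
  # one built from paired +/- ReLU units (|u| = relu(u) + relu(-u)); the
  # even part is uncorrelated with every linear function of the keypoints,
  # so a linear decoder can at best recover the linear fraction while a
  # nonlinear encoder can also capture the rest.
  U <- Ks %*% W1
  lat <- sqrt(1 - nonlinearFrac) * scale((Ks %*% Wl)) +
    sqrt(nonlinearFrac) * scale((reluFwd(U) + reluFwd(-U)) %*% W2)
  # behavioral states that drive widespread activity integrate slowly
  # (arousal-like); smooth the latents with an exponential kernel
  if (latentTau > 0) {
    a <- exp(-1 / (latentTau * frameRate(series)))
    lat <- apply(lat, 2, function(v)
      stats::filter(v * (1 - a), a, method = "recursive"))
    lat <- scale(lat)
  }
  Tn <- floor(nT / frameRate(series) * neuRate)
  # neural bins integrate behavior over their whole duration (as calcium
  # imaging at ~3 Hz does), so each latent is bin-averaged, not sampled
  binOf <- pmin(floor((seq_len(nT) - 1) / frameRate(series) * neuRate) + 1L,
                Tn)
  latN <- scale(rowsum(lat, binOf) / as.vector(table(binOf)))
  shared <- scale(vapply(seq_len(nShared), function(j)
    ouProcess(Tn, neuRate, tau = 3), numeric(Tn)))
  groups <- rep_len(seq_len(nLatents), nNeurons)
  sharedOf <- rep_len(seq_len(nShared), nNeurons)
  act <- matrix(0, nNeurons, Tn)
  for (i in seq_len(nNeurons)) {
    g <- groups[i]
    act[i, ] <- sqrt(behaviorFrac[g]) * latN[, g] +
      sqrt(sharedFrac[g]) * shared[, sharedOf[i]] +
      sqrt(noiseFrac[g]) * rnorm(Tn)
  }
  spreadAll <- rep_len(spreads, nLatents)
  centers <- cbind(runif(nLatents, 0.25, 0.75) * fovUm,
                   runif(nLatents, 0.25, 0.75) * fovUm)
  pos <- cbind(rnorm(nNeurons, centers[groups, 1], spreadAll[groups]),
               rnorm(nNeurons, centers[groups, 2], spreadAll[groups]))
  pos <- pmin(pmax(pos, 0), fovUm)
  list(recording = neuralRecording(act, pos, rate = neuRate),
       groups = groups,
       trueEV = (behaviorFrac + sharedFrac)[groups],
       trueBehaviorVE = behaviorFrac[groups],
       latents = latN, shared = shared)
}

#' Synthetic HMM sequence with controllable dwell and asymmetry
#'
#' Builds a K-state transition matrix with self-transition probability
#' `selfP` and off-diagonal mass mixing a symmetric random component with a
#' forward cycle (state i to i+1) weighted by `forwardBias`; at bias 0 the
#' off-diagonal structure is statistically symmetric, at bias 1 it is a pure
#' cycle. Emission means are i.i.d. Gaussian rows scaled by `sep`.
#'
#' @param K states.
#' @param n feature dimensions.
#' @param T timesteps to simulate.
#' @param selfP self-transition probability.
#' @param forwardBias cycle weight in \[0, 1\].
#' @param sep emission mean separation scale.
#' @param sigma2 emission variance.
#' @param seed RNG seed.
#' @return list with the true `model`, simulated `states` and `z`.
#' @export
synthHmmSequence <- function(K, n, T, selfP = 0.9, forwardBias = 0,
                             sep = 2, sigma2 = 1, seed = 1L) {
  set.seed(seed)
  S <- matrix(runif(K * K), K, K)
  S <- (S + t(S)) / 2
  diag(S) <- 0
  cyc <- matrix(0, K, K)
  cyc[cbind(seq_len(K), c(seq_len(K - 1L) + 1L, 1L))] <- 1
  M <- (1 - forwardBias) * S / rowSums(S) + forwardBias * cyc
  A <- (1 - selfP) * M / rowSums(M)
  diag(A) <- selfP
  C <- matrix(rnorm(K * n), K, n) * sep
  model <- hmmModel(A, C, sigma2 = sigma2)
  sim <- hmmSimulate(model, T, seed = seed + 1L)
  list(model = model, states = sim$states, z = sim$z)
}
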