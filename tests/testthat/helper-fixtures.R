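# Shared fixtures, built once per test run and cached. All sizes are chosen
# so the whole suite runs in a reasonable time on one CPU.

options(facekit.verbose = FALSE)

.fx <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (is.null(.fx[[name]])) .fx[[name]] <- builder()
  .fx[[name]]
}

# reduced 4-keypoint schema for fast tracker tests
smallSchema <- function() {
  facekit:::inferSchema(c("eye_top", "nose_tip", "whisker1", "whisker2"))
}

# small tracker config (64 px input, narrow channels)
smallTrackerConfig <- function(n_keypoints = 4L) {
  trackerConfig(input_size = 64L, n_keypoints = n_keypoints,
                channels = c(8L, 12L, 16L, 24L))
}

# 30-minute multi-timescale keypoint traces at 50 Hz
ouTraces30min <- function() {
  fixture("ou30", function()
    synthKeypointTraces(30 * 60 * 50, 50, seed = 21))
}

# planted-encoder neural population on the 30-minute traces
plantedPopulation <- function() {
  fixture("planted", function() {
    syn <- synthNeuralFromBehavior(ouTraces30min(), seed = 22)
    Tn <- ncol(activity(syn$recording))
    syn$split <- makeSplit(Tn, 3, 10, 0.75, 3)
    syn$svd <- neuralSVD(syn$recording, k = 32L)
    co <- coords(ouTraces30min())
    nT <- dim(co)[1]
    syn$X <- scale(cbind(matrix(co[, , 1], nT), matrix(co[, , 2], nT)))
    syn$sub <- alignFrames(Tn, 50, 3, nT)
    syn
  })
}

# deep encoder fit on the planted population (shared by the encoding and
# state-dynamics tests); a shortened conv kernel keeps this under a minute
plantedEncoderFit <- function() {
  fixture("encfit", function() {
    syn <- plantedPopulation()
    fitEncoder(syn$X, syn$svd$Y, 50, 3, syn$split,
               spec = encoderSpec(epochs = 300L, conv_kernel = 25L),
               seed = 5, nNeurons = nrow(activity(syn$recording)))
  })
}

# locality fixture: diffuse behavior-driven latents next to compact
# noise-dominated latents (same keypoint traces)
localityPopulation <- function() {
  fixture("locality", function() {
    syn <- synthNeuralFromBehavior(
      ouTraces30min(), nNeurons = 400L,
      behaviorFrac = c(0.6, 0.05, 0.6, 0.05),
      sharedFrac = 0, noiseFrac = c(0.4, 0.95, 0.4, 0.95),
      spreads = c(400, 50), seed = 29)
    Tn <- ncol(activity(syn$recording))
    syn$split <- makeSplit(Tn, 3, 10, 0.75, 3)
    syn$svd <- neuralSVD(syn$recording, k = 32L)
    co <- coords(ouTraces30min())
    nT <- dim(co)[1]
    syn$X <- scale(cbind(matrix(co[, , 1], nT), matrix(co[, , 2], nT)))
    syn$sub <- alignFrames(Tn, 50, 3, nT)
    syn
  })
}

# per-neuron test VE for predictions given in PC space
neuronVE <- function(recording, svdres, YhatTest, testIdx) {
  z <- facekit:::zscoreRows(activity(recording))$z
  predAct <- svdres$U %*% t(YhatTest)
  vapply(seq_len(nrow(z)), function(i)
    varianceExplained(z[i, testIdx], predAct[i, ]), 0)
}

# adjusted Rand index (Hubert & Arabie), used as the clustering oracle
adjRandIndex <- function(a, b) {
  tab <- table(a, b)
  ch2 <- function(x) x * (x - 1) / 2
  sij <- sum(ch2(tab))
  si <- sum(ch2(rowSums(tab)))
  sj <- sum(ch2(colSums(tab)))
  n <- ch2(sum(tab))
  exp_idx <- si * sj / n
  (sij - exp_idx) / ((si + sj) / 2 - exp_idx)
}
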