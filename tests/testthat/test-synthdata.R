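# Fixture generators: seed determinism, analytic autocorrelations, and the
# statistical structure each downstream module relies on.

test_that("OU keypoint traces have the analytic autocorrelation", {
  T <- 30000; rate <- 50
  tr <- synthKeypointTraces(T, rate, seed = 2, whiskAmp = 0,
                            taus = c(eye = 1, nose = 1, whisker = 1,
                                     mouth = 1))
  co <- coords(tr)
  lag <- rate  # one tau
  acs <- vapply(seq_len(dim(co)[2]), function(p) {
    x <- co[, p, 1]
    cor(x[-(1:lag)], x[seq_len(T - lag)])
  }, 0)
  expect_equal(mean(acs), exp(-1), tolerance = 0.05)
  # seed determinism
  tr2 <- synthKeypointTraces(1000, rate, seed = 2)
  tr3 <- synthKeypointTraces(1000, rate, seed = 2)
  expect_identical(coords(tr2), coords(tr3))
})

test_that("whisker traces oscillate near the configured frequency", {
  rate <- 50; T <- 2^13
  tr <- synthKeypointTraces(T, rate, seed = 3, whiskAmp = 8)
  w <- coords(tr)[, "whisker1", 1]
  w <- w - mean(w)
  spec <- Mod(fft(w))^2
  freqs <- (seq_len(T) - 1) * rate / T
  band <- freqs > 1 & freqs < 25
  peak <- freqs[band][which.max(spec[band])]
  expect_equal(peak, 10, tolerance = 0.2)
})

test_that("rendered face videos carry their exact ground truth", {
  sc <- smallSchema()
  vid <- synthFaceVideo(5, size = 64, seed = 4, schema = sc, noise = 0)
  expect_equal(dim(vid$frames), c(64, 64, 5))
  # zero motion freezes the scene
  vid0 <- synthFaceVideo(4, size = 64, seed = 4, schema = sc, noise = 0,
                         motionScale = 0)
  expect_equal(vid0$frames[, , 1], vid0$frames[, , 4])
  # keypoints stay clear of the borders (reflection rule)
  co <- coords(vid$series)
  expect_true(all(co > 2 & co < 61))
  # target construction and decoding recover the rendered truth
  cfg <- smallTrackerConfig()
  dec <- decodeHeatmaps(makeTargets(co[1, , ], cfg), cfg)
  expect_lt(max(abs(cbind(dec$x, dec$y) - co[1, , ])), 0.5)
})

test_that("planted populations have the designed variance structure", {
  tr <- synthKeypointTraces(30000, 50, seed = 6)
  syn <- synthNeuralFromBehavior(tr, nNeurons = 60L, seed = 7)
  act <- activity(syn$recording)
  expect_equal(nrow(act), 60L)
  expect_equal(frameRate(syn$recording), 3)
  # per-neuron variance is near 1 by construction
  expect_equal(mean(apply(act, 1, var)), 1, tolerance = 0.15)
  expect_equal(syn$trueEV, rep(0.7, 60), tolerance = 1e-12)
  # zero behavior fraction gives behavior-independent neurons
  syn0 <- synthNeuralFromBehavior(tr, nNeurons = 40L, behaviorFrac = 0,
                                  sharedFrac = 0.3, noiseFrac = 0.7,
                                  seed = 8)
  co <- coords(tr)
  Kp <- scale(cbind(matrix(co[, , 1], 30000), matrix(co[, , 2], 30000)))
  Tn <- ncol(activity(syn0$recording))
  sub <- alignFrames(Tn, 50, 3, 30000)
  sp <- makeSplit(Tn, 3, 10, 0.75, 3)
  sv <- neuralSVD(syn0$recording, k = 16L)
  rr <- fitRRR(Kp[sub, ], sv$Y, rank = 8, lambda = 1e-6,
               trainIdx = sp@trainIdx)
  Yhat <- predictRRR(rr, Kp[sub, ][sp@testIdx, ])
  z <- facekit:::zscoreRows(activity(syn0$recording))$z
  predAct <- sv$U %*% t(Yhat)
  ve <- vapply(seq_len(40), function(i)
    varianceExplained(z[i, sp@testIdx], predAct[i, ]), 0)
  expect_lt(abs(mean(ve)), 0.05)
})

test_that("HMM sequences honor dwell and asymmetry settings", {
  # dwell p = 0.9 gives ~10-step mean runs
  syn <- synthHmmSequence(K = 6, n = 4, T = 30000, selfP = 0.9, seed = 9)
  expect_equal(mean(rle(syn$states)$lengths), 10, tolerance = 0.15)
  # zero asymmetry: off-diagonal structure statistically symmetric
  A0 <- transitionMatrix(synthHmmSequence(K = 6, n = 2, T = 10,
                                          forwardBias = 0, seed = 1)$model)
  B0 <- normalizeTransitions(A0)$B
  expect_lt(sum(abs(B0 - t(B0))), 0.2 * sum(B0))
  # full forward bias: pure cycle off the diagonal
  A1 <- transitionMatrix(synthHmmSequence(K = 6, n = 2, T = 10,
                                          forwardBias = 1, seed = 1)$model)
  B1 <- normalizeTransitions(A1)$B
  expect_equal(sum(B1[cbind(1:6, c(2:6, 1))]), 6, tolerance = 1e-9)
  # determinism
  expect_identical(synthHmmSequence(4, 2, 50, seed = 3)$z,
                   synthHmmSequence(4, 2, 50, seed = 3)$z)
})
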