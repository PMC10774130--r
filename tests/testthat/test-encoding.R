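# Behavior-to-neural prediction: VE metrics, SVD, RRR, peer prediction.

test_that("variance explained follows the sum-of-squares convention", {
  expect_equal(varianceExplained(c(1, 2, 3, 4), c(1, 2, 3, 4)), 1)
  expect_equal(varianceExplained(c(1, 2, 3, 4), rep(2.5, 4)), 0)
  # hand arithmetic: SSE = 1, SST = 5
  expect_equal(varianceExplained(c(1, 2, 3, 4), c(1, 2, 3, 5)), 0.8)
  expect_true(is.na(varianceExplained(rep(1, 5), rnorm(5))))
})

test_that("cumulative VE accumulates per-PC explained variance", {
  set.seed(6)
  Y <- matrix(rnorm(200 * 4), 200, 4) %*% diag(c(4, 3, 2, 1))
  # perfect prediction reaches exactly 1
  expect_equal(cumulativeVE(Y, Y)[4], 1)
  # predicting only PC1 exactly: flat at var1 / total afterwards
  pred <- Y
  for (j in 2:4) pred[, j] <- mean(Y[, j])
  cv <- cumulativeVE(Y, pred)
  sst <- colSums(sweep(Y, 2, colMeans(Y))^2)
  expect_equal(cv, rep(sst[1] / sum(sst), 4), tolerance = 1e-12)
  expect_true(all(diff(cv) >= -1e-12))
})

test_that("neural SVD is exact at true rank and sign-deterministic", {
  set.seed(7)
  U0 <- matrix(rnorm(40 * 3), 40, 3)
  V0 <- matrix(rnorm(300 * 3), 300, 3)
  act <- U0 %*% t(V0)
  sv <- neuralSVD(act, k = 3)
  z <- facekit:::zscoreRows(act)$z
  expect_lt(max(abs(z - sv$U %*% t(sv$Y))), 1e-6)
  # sign convention: largest-magnitude loading positive
  for (j in 1:3) expect_gt(sv$U[which.max(abs(sv$U[, j])), j], 0)
  expect_error(neuralSVD(act, k = 100), "exceeds")
  # shuffling time flattens the spectrum
  shuf <- act[, sample(ncol(act))] + matrix(rnorm(40 * 300, sd = 0.1), 40)
  actn <- act + matrix(rnorm(40 * 300, sd = 0.1), 40)
  s1 <- svd(facekit:::zscoreRows(actn)$z)$d[1]
  z2 <- facekit:::zscoreRows(actn)$z
  s2 <- svd(t(apply(z2, 1, sample)))$d[1]
  expect_gt(s1, s2)
})

test_that("reduced-rank regression has the right limits and nesting", {
  set.seed(8)
  X <- matrix(rnorm(300 * 10), 300, 10)
  W <- matrix(rnorm(10 * 6), 10, 6)
  Y <- X %*% W + 0.1 * matrix(rnorm(300 * 6), 300)
  # full rank, tiny lambda: equals OLS
  m <- fitRRR(X, Y, rank = 6, lambda = 1e-12)
  ols <- fitted(lm(Y ~ X))
  expect_lt(max(abs(predictRRR(m, X) - ols)), 1e-6)
  # exact recovery of a noiseless rank-2 map
  B2 <- matrix(rnorm(10 * 2), 10, 2); A2 <- matrix(rnorm(6 * 2), 6, 2)
  Y2 <- X %*% B2 %*% t(A2)
  m2 <- fitRRR(X, Y2, rank = 2, lambda = 1e-9, trainIdx = 1:200)
  pred <- predictRRR(m2, X[201:300, ])
  ve <- vapply(1:6, function(j)
    varianceExplained(Y2[201:300, j], pred[, j]), 0)
  expect_equal(mean(ve), 1, tolerance = 1e-6)
  # training VE is non-decreasing in rank
  ves <- vapply(1:6, function(r) {
    pr <- predictRRR(fitRRR(X, Y, rank = r, lambda = 1e-9), X)
    mean(vapply(1:6, function(j) varianceExplained(Y[, j], pr[, j]), 0))
  }, 0)
  expect_true(all(diff(ves) >= -1e-10))
  expect_error(fitRRR(X, Y, rank = 20), "rank")
})

test_that("peer prediction calibrates to the planted shared variance", {
  # neurons = shared low-rank signal + independent noise
  evFor <- function(noiseFrac, seed) {
    set.seed(seed)
    n <- 260; Tn <- 4000; nl <- 6
    lat <- scale(matrix(rnorm(Tn * nl), Tn, nl))
    act <- t(vapply(seq_len(n), function(i) {
      w <- rnorm(nl); sig <- lat %*% w / sqrt(sum(w^2))
      sqrt(1 - noiseFrac) * as.numeric(sig) +
        sqrt(noiseFrac) * rnorm(Tn)
    }, numeric(Tn)))
    rec <- neuralRecording(act, cbind(runif(n) * 1000, runif(n) * 1000),
                           rate = 3)
    sp <- makeSplit(Tn, 3, 10, 0.75, 3)
    peerPrediction(rec, sp, k = 24L, rank = 23L)
  }
  ev3 <- evFor(0.3, 31)
  ev6 <- evFor(0.6, 32)
  expect_lt(abs(mean(ev3, na.rm = TRUE) - 0.7), 0.05)
  expect_lt(abs(mean(ev6, na.rm = TRUE) - 0.4), 0.05)
  # fully independent neurons: no shared variance
  set.seed(33)
  act0 <- matrix(rnorm(260 * 1600), 260, 1600)
  rec0 <- neuralRecording(act0, cbind(runif(260) * 1000,
                                      runif(260) * 1000), rate = 3)
  sp0 <- makeSplit(1600, 3, 10, 0.75, 3)
  ev0 <- peerPrediction(rec0, sp0, k = 24L, rank = 23L)
  expect_lt(abs(mean(ev0, na.rm = TRUE)), 0.05)
  # strip relabeling symmetry: shifting the strip origin by one strip
  # swaps groups but leaves per-neuron EV nearly unchanged
  rec3 <- neuralRecording(activity(rec0),
                          cbind(positions(rec0)[, 1] + 200,
                                positions(rec0)[, 2]), rate = 3)
  ev0b <- peerPrediction(rec3, sp0, k = 24L, rank = 23L)
  expect_equal(mean(ev0b, na.rm = TRUE), mean(ev0, na.rm = TRUE),
               tolerance = 0.05)
  expect_error(peerPrediction(rec0, sp, k = 200L), "fewer than k")
})

test_that("normalized VE applies the EV floor and scale invariance", {
  ve <- c(0.2, 0.1, 0.05)
  ev <- c(0.4, 0.0005, 0.1)
  nv <- normalizedVE(ve, ev)
  expect_equal(nv$per_neuron, c(0.5, NA, 0.5))
  expect_equal(nv$population, mean(ve) / mean(ev))
})

test_that("deep encoder has null behavior on noise targets", {
  # long enough that overfitting noise cannot push test VE far negative
  set.seed(9)
  Tb <- 120000; Tn <- 7200
  X <- matrix(rnorm(Tb * 4), Tb, 4)
  Y <- matrix(rnorm(Tn * 3), Tn, 3)
  sp <- makeSplit(Tn, 3, 10, 0.75, 3)
  fit <- fitEncoder(X, Y, 50, 3, sp,
                    spec = encoderSpec(epochs = 40L, conv_kernel = 11L,
                                       n_features = 32L, hidden = 16L),
                    seed = 2)
  expect_lt(abs(mean(varianceLedger(fit)$ve)), 0.05)
  expect_lt(max(abs(varianceLedger(fit)$ve)), 0.1)
  # deterministic given the seed
  fit2 <- fitEncoder(X, Y, 50, 3, sp,
                     spec = encoderSpec(epochs = 40L, conv_kernel = 11L,
                                        n_features = 32L, hidden = 16L),
                     seed = 2)
  expect_identical(fit@history, fit2@history)
  expect_identical(varianceLedger(fit)$ve, varianceLedger(fit2)$ve)
  # NaN inputs are rejected with a pointer to filtering
  Xb <- X; Xb[5, 2] <- NaN
  expect_error(fitEncoder(Xb, Y, 50, 3, sp), "filter")
  # deep features are emitted at behavior rate with the configured width
  expect_equal(dim(deepFeatures(fit)), c(Tb, 32L))
})

test_that("scaling analysis is exact at fraction 1 and monotone in time", {
  syn <- plantedPopulation()
  rec <- syn$recording
  Xn <- syn$X[syn$sub, ]
  ev <- peerPrediction(rec, syn$split, k = 32L, rank = 31L)
  sc <- scalingCurves(rec, Xn, syn$split, ev,
                      neuronFracs = c(0.5, 1), timeFracs = c(0.25, 1),
                      k = 32L, rank = 21L, seed = 3)
  full_n <- sc$nve[sc$resource == "neurons" & sc$fraction == 1]
  full_t <- sc$nve[sc$resource == "timepoints" & sc$fraction == 1]
  expect_equal(full_n, full_t, tolerance = 1e-8)
  # more training data cannot hurt on this fixture
  expect_lte(sc$nve[sc$resource == "timepoints" & sc$fraction == 0.25],
             full_t + 0.02)
  # exchangeable population: EV-normalized VE roughly flat in neuron count
  half_n <- sc$nve[sc$resource == "neurons" & sc$fraction == 0.5]
  expect_lt(abs(half_n - full_n), 0.1)
})
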