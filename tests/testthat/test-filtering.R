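# QC filtering of keypoint traces: likelihood rule, jump/deviation rules,
# median-filter imputation.

makeCleanSeries <- function(T = 5000, rate = 50, seed = 3) {
  synthKeypointTraces(T, rate, seed = seed, schema = smallSchema(),
                      whiskAmp = 0)
}

test_that("likelihood rule flags confidence drops and little else", {
  set.seed(1)
  T <- 5000
  tr <- makeCleanSeries(T)
  lk <- matrix(pmin(0.9 + rnorm(T * 4, sd = 0.01), 1), T, 4)
  lk[2500, 2] <- 0   # single occlusion-like drop
  s <- keypointSeries(coords(tr), lk, rate = 50, schema = schema(tr))
  m <- likelihoodOutliers(s)
  expect_true(m[2500, 2])
  # 8-sd threshold: Gaussian noise alone flags (far) under 1% of samples
  expect_lt(mean(m[, -2]), 0.01)
  # constant likelihood: zero residual, zero flags
  s0 <- keypointSeries(coords(tr), matrix(0.9, T, 4), rate = 50,
                       schema = schema(tr))
  expect_equal(sum(likelihoodOutliers(s0)), 0L)
  # series shorter than one baseline s.d. is rejected
  short <- keypointSeries(coords(tr)[1:100, , , drop = FALSE],
                          lk[1:100, ], rate = 50, schema = schema(tr))
  expect_error(likelihoodOutliers(short), "shorter")
})

test_that("trace rules flag jumps and deviations but not smooth motion", {
  T <- 2000
  tt <- seq_len(T) / 50
  co <- array(0, c(T, 1, 2))
  co[, 1, 1] <- 100 + 10 * sin(2 * pi * 0.5 * tt)   # smooth, 10 px
  co[, 1, 2] <- 100 + 10 * cos(2 * pi * 0.5 * tt)
  s <- keypointSeries(co, rate = 50,
                      schema = facekit:::inferSchema("kp"))
  expect_equal(sum(traceOutliers(s)), 0L)

  # single 100 px teleport: arrival frame flagged by both rules, return
  # step flags the next frame by the jump rule
  co2 <- co
  co2[800, 1, 1] <- co2[800, 1, 1] + 100
  s2 <- keypointSeries(co2, rate = 50, schema = schema(s))
  m2 <- traceOutliers(s2)
  expect_true(m2[800, 1])
  expect_true(all(which(m2[, 1]) %in% c(800, 801)))

  # persistent 30 px step: jump rule flags the transition frame only;
  # deviation rule flags at most half a window around it
  co3 <- co
  co3[1000:T, 1, 1] <- co3[1000:T, 1, 1] + 30
  s3 <- keypointSeries(co3, rate = 50, schema = schema(s))
  m3 <- traceOutliers(s3)
  expect_true(m3[1000, 1])
  flagged <- which(m3[, 1])
  win <- 51  # 1 s window at 50 Hz, odd
  expect_true(all(abs(flagged - 1000) <= win %/% 2))
})

test_that("imputation is exact on ramps and leaves clean samples alone", {
  T <- 500
  co <- array(0, c(T, 1, 2))
  co[, 1, 1] <- seq_len(T)          # linear ramp
  co[, 1, 2] <- 2 * seq_len(T) + 5
  s <- keypointSeries(co, rate = 50,
                      schema = facekit:::inferSchema("kp"))
  mask <- matrix(FALSE, T, 1)
  # no outliers: identity
  expect_equal(coords(imputeOutliers(s, mask)), coords(s))
  mask[250, 1] <- TRUE
  imp <- imputeOutliers(s, mask)
  expect_equal(coords(imp)[250, 1, 1], 250, tolerance = 1e-9)
  expect_equal(coords(imp)[-250, 1, ], coords(s)[-250, 1, ])
  expect_true(outlierMask(imp)[250, 1])
  # an all-flagged bodypart is a hard error naming it
  expect_error(imputeOutliers(s, matrix(TRUE, T, 1)), "kp")
})

test_that("planted teleports are detected and repaired on OU traces", {
  T <- 5000
  tr <- makeCleanSeries(T, seed = 8)
  clean <- coords(tr)
  set.seed(9)
  nBad <- round(0.002 * T)
  badf <- sort(sample(10:(T - 10), nBad))
  co <- clean
  # plant on the slow eye part: imputation replaces flagged samples by the
  # median-filtered trace, whose smoothing error on fast large-amplitude
  # motion would dominate the recovery measurement
  co[badf, 1, 1] <- co[badf, 1, 1] + 100
  s <- keypointSeries(co, rate = 50, schema = schema(tr))
  res <- filterKeypoints(s)
  m <- outlierMask(res$series)[, 1]
  # detection: a flag within one frame of a planted artifact counts as true
  hits <- which(m)
  prec <- mean(vapply(hits, function(f)
    any(abs(f - badf) <= 1), TRUE))
  rec <- mean(badf %in% hits)
  expect_gte(prec, 0.9)
  expect_gte(rec, 0.9)
  # repaired trace close to the clean truth
  expect_lt(max(abs(coords(res$series)[, 1, ] - clean[, 1, ])), 5)
  # unflagged samples untouched
  expect_equal(coords(res$series)[!m, 1, 1], co[!m, 1, 1])
})
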