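# Tracker network: shapes, target construction, subpixel decoding, loss
# behaviour. The slow convergence experiments live in the acceptance suite.

test_that("network output follows the shape law", {
  cfg <- smallTrackerConfig()
  net <- buildTracker(cfg, seed = 1)
  x <- array(rnorm(64 * 64 * 2), c(64, 64, 1, 2))
  fw <- facekit:::trackerForward(net, x)
  expect_equal(dim(fw$hm_logit), c(16L, 16L, 4L, 2L))
  expect_equal(dim(fw$ref), c(16L, 16L, 8L, 2L))
  # 256 px input with factor 4 gives 64 x 64 maps
  cfg256 <- trackerConfig(input_size = 256L, n_keypoints = 2L,
                          channels = c(4L, 6L, 8L, 12L))
  fw256 <- facekit:::trackerForward(buildTracker(cfg256, seed = 1),
                                    array(0, c(256, 256, 1, 1)))
  expect_equal(dim(fw256$hm_logit)[1:2], c(64L, 64L))
  # zero input: finite outputs, sigmoid heatmaps in [0, 1]
  hm <- 1 / (1 + exp(-fw256$hm_logit))
  expect_true(all(is.finite(hm)) && all(hm >= 0 & hm <= 1))
  expect_error(trackerConfig(input_size = 63L), "divisible")
  expect_gt(nParams(net), 0)
})

test_that("frame normalization maps the 1st/99th percentiles to 0/1", {
  img <- matrix(seq(0, 100, length.out = 1e4), 100)
  nrm <- normalizeFrame(img)
  q <- quantile(img, c(0.01, 0.99))
  expect_equal(nrm[which.min(abs(img - q[1]))], 0, tolerance = 1e-2)
  expect_equal(nrm[which.min(abs(img - q[2]))], 1, tolerance = 1e-2)
  # affine intensity changes are removed
  expect_equal(normalizeFrame(3 * img + 7), nrm, tolerance = 1e-12)
  # constant image degenerates to zeros
  expect_equal(normalizeFrame(matrix(5, 10, 10)), matrix(0, 10, 10))
})

test_that("targets encode position and offsets per the cell convention", {
  cfg <- trackerConfig(input_size = 256L, n_keypoints = 3L,
                       channels = c(4L, 6L, 8L, 12L))
  tg <- makeTargets(rbind(c(128, 128), c(130, 129), c(NaN, NaN)), cfg)
  expect_equal(attr(tg, "mask"), c(TRUE, TRUE, FALSE))
  # keypoint exactly on a cell center: peak at that cell, zero offset
  h1 <- tg@heatmaps[, , 1]
  am <- which(h1 == max(h1), arr.ind = TRUE)[1, ]
  expect_equal(unname(am), c(33, 33))   # cell (32, 32), 0-based
  expect_equal(tg@refineX[am[1], am[2], 1], 0)
  expect_equal(tg@refineY[am[1], am[2], 1], 0)
  expect_equal(max(h1), 1)
  # keypoint at (130, 129): offset (2, 1) at the decoded cell
  dec <- decodeHeatmaps(tg, cfg)
  expect_equal(dec$x[2], 130)
  expect_equal(dec$y[2], 129)
  expect_equal(dec$likelihood[1:2], c(1, 1))
})

test_that("encode-decode round trip is subpixel-exact away from borders", {
  cfg <- smallTrackerConfig(n_keypoints = 4L)
  set.seed(7)
  worst <- 0
  for (i in 1:100) {
    co <- cbind(runif(4, 8, 55), runif(4, 8, 55))
    dec <- decodeHeatmaps(makeTargets(co, cfg), cfg)
    worst <- max(worst, max(abs(cbind(dec$x, dec$y) - co)))
  }
  expect_lt(worst, 0.5)
})

test_that("decoding breaks ties row-major and flags empty heatmaps", {
  cfg <- smallTrackerConfig(n_keypoints = 1L)
  side <- 16L
  hm <- array(0, c(side, side, 1))
  hm[3, 5, 1] <- 0.7
  hm[9, 2, 1] <- 0.7        # equal maxima; (row 3, col 5) comes first
  bun <- new("HeatmapBundle", heatmaps = hm,
             refineX = array(0, dim(hm)), refineY = array(0, dim(hm)),
             downsample = 4L)
  dec <- decodeHeatmaps(bun, cfg)
  expect_equal(c(dec$y[1], dec$x[1]), c(2 * 4, 4 * 4))
  # all-zero heatmap: likelihood 0, centered, flagged
  bun0 <- new("HeatmapBundle", heatmaps = hm * 0,
              refineX = array(0, dim(hm)), refineY = array(0, dim(hm)),
              downsample = 4L)
  dec0 <- decodeHeatmaps(bun0, cfg)
  expect_true(dec0$degenerate[1])
  expect_equal(dec0$likelihood[1], 0)
})

test_that("a few optimizer steps reduce the loss on a toy set", {
  sc <- smallSchema()
  vid <- synthFaceVideo(12, size = 64, seed = 41, schema = sc)
  co <- aperm(coords(vid$series), c(2, 3, 1))
  cfg <- smallTrackerConfig()
  cfg$train$epochs <- 8L
  cfg$train$schedule_frac <- c(6, 1, 1) / 8
  net <- buildTracker(cfg, seed = 1)
  res <- facekit:::trackerOptimize(net, vid$frames, co, cfg$train, seed = 2,
                                   augment = FALSE)
  expect_lt(tail(res$loss, 1), res$loss[1])
  # deterministic given the seed
  res2 <- facekit:::trackerOptimize(net, vid$frames, co, cfg$train,
                                    seed = 2, augment = FALSE)
  expect_identical(res$loss, res2$loss)
  # a label-free training set is rejected
  expect_error(trainTracker(net, vid$frames, co * NaN, seed = 1),
               "no visible keypoints")
})

test_that("augmentation keeps labels consistent with the warped image", {
  sc <- smallSchema()
  vid <- synthFaceVideo(3, size = 64, seed = 43, schema = sc, noise = 0)
  img <- vid$frames[, , 1]
  co <- coords(vid$series)[1, , ]
  set.seed(5)
  au <- facekit:::augmentSample(img, co, smallTrackerConfig(),
                                flipPairs = NULL)
  ok <- is.finite(au$coords[, 1])
  # a blob center maps to a local intensity extremum in the warped image
  for (p in which(ok)) {
    x <- round(au$coords[p, 1]) + 1L
    y <- round(au$coords[p, 2]) + 1L
    if (x < 3 || y < 3 || x > 62 || y > 62) next
    patch <- au$img[(y - 2):(y + 2), (x - 2):(x + 2)]
    expect_gt(max(abs(patch - mean(au$img))),
              0.5 * max(abs(au$img - mean(au$img))))
  }
  # flips only happen when a left/right pair map is supplied: without one,
  # the keypoint order is always preserved
  set.seed(11)
  for (i in 1:10) {
    auN <- facekit:::augmentSample(img, co, smallTrackerConfig(),
                                   flipPairs = NULL)
    keep <- is.finite(auN$coords[, 1]) & is.finite(co[, 1])
    if (sum(keep) >= 2) {
      expect_equal(order(auN$coords[keep, 1]), order(co[keep, 1]))
    }
  }
})

test_that("fine-tuning with zero frames returns the base model unchanged", {
  cfg <- smallTrackerConfig()
  net <- buildTracker(cfg, seed = 1)
  out <- finetuneTracker(net, array(0, c(64, 64, 0)),
                         array(0, c(4, 2, 0)), seed = 1)
  expect_identical(out$net@layers, net@layers)
  expect_length(out$loss, 0L)
})

test_that("pixel-error evaluation masks NaN and averages by group", {
  truth <- array(0, c(2, 4, 2))
  truth[, , 1] <- matrix(c(10, 20, 30, 40), 2, 4, byrow = TRUE)
  truth[, , 2] <- 5
  pred <- truth
  ev0 <- evalTracker(pred, truth)
  expect_equal(ev0$mean, 0)
  pred[, , 1] <- pred[, , 1] + 3
  pred[, , 2] <- pred[, , 2] + 4
  ev <- evalTracker(pred, truth, schema = smallSchema())
  expect_equal(ev$mean, 5)   # 3-4-5 triangle
  expect_equal(unname(ev$by_group[c("eye", "nose", "whisker")]),
               c(5, 5, 5))
  truth[1, 2, ] <- NaN
  ev2 <- evalTracker(pred, truth)
  expect_equal(ev2$mean, 5)
  expect_true(is.na(ev2$per_label[1, 2]))
  expect_error(evalTracker(pred, truth * NaN), "no present labels")
})

test_that("checkpoints round-trip through disk", {
  net <- buildTracker(smallTrackerConfig(), seed = 3)
  path <- tempfile(fileext = ".rds")
  saveTracker(net, path)
  net2 <- loadTracker(path)
  expect_identical(net@layers, net2@layers)
  expect_identical(net@config, net2@config)
})
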