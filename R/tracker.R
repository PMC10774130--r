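#' Tracker configuration
#'
#' Hyperparameters of the U-Net-style keypoint tracker. Defaults follow the
#' published training recipe: Adam, base learning rate 4e-4, 36 epochs, batch
#' size 8, zero weight decay, with the learning rate held for 30 epochs then
#' divided by 10 for 3 epochs and by 25 for the final 3. Fine-tuning uses
#' learning rate 1e-4 and weight decay 1e-3 for 36 epochs. A 256 px input
#' with downsampling factor 4 yields 64 x 64 heatmaps; the convolutional
#' widths `(16, 32, 64, 128)` are configurable since only the architecture
#' family is prescribed.
#'
#' @param input_size square input image side in pixels.
#' @param downsample_factor integer ratio between image and heatmap side.
#' @param n_keypoints number of tracked bodyparts.
#' @param channels convolutional widths of the four network levels.
#' @param heatmap_sigma Gaussian target width in heatmap cells.
#' @param refine_radius cells around the target included in the
#'   location-refinement loss.
#' @param train,finetune optimizer settings (lists with `lr`, `epochs`,
#'   `batch`, `weight_decay`, `schedule` fractions and factors).
#' @return a config list used by [buildTracker()].
#' @export
trackerConfig <- function(input_size = 256L, downsample_factor = 4L,
                          n_keypoints = 13L,
                          channels = c(16L, 32L, 64L, 128L),
                          heatmap_sigma = 2, refine_radius = 2L,
                          train = list(), finetune = list()) {
  if (input_size %% (2L * downsample_factor) != 0L)
    stop("input_size must be divisible by 2 * downsample_factor")
  tr <- utils::modifyList(list(
    lr = 4e-4, epochs = 36L, batch = 8L, weight_decay = 0,
    schedule_frac = c(30, 3, 3) / 36, schedule_div = c(1, 10, 25)), train)
  ft <- utils::modifyList(list(
    lr = 1e-4, epochs = 36L, batch = 8L, weight_decay = 1e-3,
    schedule_frac = c(30, 3, 3) / 36, schedule_div = c(1, 10, 25)), finetune)
  list(input_size = as.integer(input_size),
       downsample_factor = as.integer(downsample_factor),
       n_keypoints = as.integer(n_keypoints),
       channels = as.integer(channels), heatmap_sigma = heatmap_sigma,
       refine_radius = as.integer(refine_radius), train = tr, finetune = ft)
}

#' Build an untrained tracker network
#'
#' Constructs the U-Net-style network: three stride-2 downsampling levels
#' with 3x3 convolutions and ReLU, a bottleneck, one nearest-neighbour
#' upsampling step with a skip connection back to the quarter-resolution
#' level, and two 1x1 heads emitting per-keypoint probability heatmaps
#' (sigmoid) and x/y location-refinement maps at `input_size /
#' downsample_factor` resolution.
#'
#' @param config from [trackerConfig()].
#' @param seed RNG seed for weight initialization.
#' @return a [TrackerNet-class].
#' @export
buildTracker <- function(config, seed = 1L) {
  set.seed(seed)
  ch <- config$channels
  K <- config$n_keypoints
  mk <- function(cout, cin, k) list(W = heInit(cout, cin * k * k),
                                    b = rep(0, cout), k = k)
  layers <- list(
    enc1 = mk(ch[1], 1L, 3L),
    enc2 = mk(ch[2], ch[1], 3L),
    enc3 = mk(ch[3], ch[2], 3L),
    bott = mk(ch[4], ch[3], 3L),
    dec = mk(ch[3], ch[4] + ch[3], 3L),
    head_hm = mk(K, ch[3], 1L),
    head_ref = mk(2L * K, ch[3], 1L))
  new("TrackerNet", config = config, layers = layers)
}

#' Total number of trainable parameters of a tracker network
#' @param net a [TrackerNet-class].
#' @export
nParams <- function(net) {
  sum(vapply(net@layers, function(l) length(l$W) + length(l$b), 0))
}

#' Percentile-normalize a grayscale frame
#'
#' Maps the 1st intensity percentile to 0.0 and the 99th to 1.0 with a linear
#' ramp in between; values outside the range are not clipped. A constant
#' image (degenerate percentiles) returns all zeros.
#'
#' @param image numeric matrix.
#' @export
normalizeFrame <- function(image) {
  q <- quantile(image, c(0.01, 0.99), names = FALSE)
  if (q[2] <= q[1]) return(image * 0)
  (image - q[1]) / (q[2] - q[1])
}

# forward pass; returns heads and, when train = TRUE, cached activations
trackerForward <- function(net, x, train = FALSE) {
  L <- net@layers
  a1 <- reluFwd(conv2d_fwd_cpp(x, L$enc1$W, L$enc1$b, 3L))
  p1 <- maxpool2_fwd_cpp(a1)
  a2 <- reluFwd(conv2d_fwd_cpp(p1$y, L$enc2$W, L$enc2$b, 3L))
  p2 <- maxpool2_fwd_cpp(a2)
  a3 <- reluFwd(conv2d_fwd_cpp(p2$y, L$enc3$W, L$enc3$b, 3L))
  p3 <- maxpool2_fwd_cpp(a3)
  a4 <- reluFwd(conv2d_fwd_cpp(p3$y, L$bott$W, L$bott$b, 3L))
  up <- upsample2_fwd_cpp(a4)
  cat5 <- bindChannels(up, a3)
  a5 <- reluFwd(conv2d_fwd_cpp(cat5, L$dec$W, L$dec$b, 3L))
  hm_logit <- conv2d_fwd_cpp(a5, L$head_hm$W, L$head_hm$b, 1L)
  ref <- conv2d_fwd_cpp(a5, L$head_ref$W, L$head_ref$b, 1L)
  out <- list(hm_logit = hm_logit, ref = ref)
  if (train)
    out$cache <- list(x = x, a1 = a1, p1 = p1, a2 = a2, p2 = p2, a3 = a3,
                      p3 = p3, a4 = a4, up = up, cat5 = cat5, a5 = a5)
  out
}

# backward pass: gradients for all layer parameters given head gradients
trackerBackward <- function(net, fwd, d_hm, d_ref) {
  L <- net@layers; cc <- fwd$cache
  g <- list()
  bw_hm <- conv2d_bwd_cpp(cc$a5, L$head_hm$W, d_hm, 1L)
  bw_rf <- conv2d_bwd_cpp(cc$a5, L$head_ref$W, d_ref, 1L)
  g$head_hm <- list(W = bw_hm$dw, b = as.numeric(bw_hm$db))
  g$head_ref <- list(W = bw_rf$dw, b = as.numeric(bw_rf$db))
  da5 <- reluBwd(bw_hm$dx + bw_rf$dx, cc$a5)
  bw5 <- conv2d_bwd_cpp(cc$cat5, L$dec$W, da5, 3L)
  g$dec <- list(W = bw5$dw, b = as.numeric(bw5$db))
  c4 <- dim(cc$up)[3]
  dup <- cc$up * 0; dup[] <- bw5$dx[, , seq_len(c4), , drop = FALSE]
  da3cat <- bw5$dx[, , c4 + seq_len(dim(cc$a3)[3]), , drop = FALSE]
  da4 <- reluBwd(upsample2_bwd_cpp(dup), cc$a4)
  bw4 <- conv2d_bwd_cpp(cc$p3$y, L$bott$W, da4, 3L)
  g$bott <- list(W = bw4$dw, b = as.numeric(bw4$db))
  da3 <- maxpool2_bwd_cpp(bw4$dx, cc$p3$argmax, dim(cc$a3)[1], dim(cc$a3)[2])
  da3 <- reluBwd(da3 + da3cat, cc$a3)
  bw3 <- conv2d_bwd_cpp(cc$p2$y, L$enc3$W, da3, 3L)
  g$enc3 <- list(W = bw3$dw, b = as.numeric(bw3$db))
  da2 <- maxpool2_bwd_cpp(bw3$dx, cc$p2$argmax, dim(cc$a2)[1], dim(cc$a2)[2])
  da2 <- reluBwd(da2, cc$a2)
  bw2 <- conv2d_bwd_cpp(cc$p1$y, L$enc2$W, da2, 3L)
  g$enc2 <- list(W = bw2$dw, b = as.numeric(bw2$db))
  da1 <- maxpool2_bwd_cpp(bw2$dx, cc$p1$argmax, dim(cc$a1)[1], dim(cc$a1)[2])
  da1 <- reluBwd(da1, cc$a1)
  bw1 <- conv2d_bwd_cpp(cc$x, L$enc1$W, da1, 3L)
  g$enc1 <- list(W = bw1$dw, b = as.numeric(bw1$db))
  g
}

#' Build training targets for one frame
#'
#' For each keypoint with finite coordinates, the heatmap target is a
#' Gaussian bump with peak value 1 centered at `coords / downsample_factor`
#' on the heatmap grid; the refinement targets hold the full-resolution x and
#' y offsets from each cell's full-image center (`cell index *
#' downsample_factor`, 0-based) to the keypoint. Keypoints with NaN
#' coordinates (missing labels) yield an all-masked target, never a (0, 0)
#' label.
#'
#' @param coords n_keypoints x 2 matrix of (x, y) full-image pixel
#'   coordinates; NaN marks a missing label.
#' @param config from [trackerConfig()].
#' @return a [HeatmapBundle-class]; attribute `"mask"` is the per-keypoint
#'   presence vector.
#' @export
makeTargets <- function(coords, config) {
  df <- config$downsample_factor
  side <- config$input_size %/% df
  K <- nrow(coords)
  hm <- array(0, c(side, side, K))
  rx <- array(0, c(side, side, K))
  ry <- array(0, c(side, side, K))
  mask <- is.finite(coords[, 1]) & is.finite(coords[, 2])
  gx <- coords[, 1] / df
  gy <- coords[, 2] / df
  cells <- seq_len(side) - 1L
  for (kk in which(mask)) {
    dx2 <- (cells - gx[kk])^2
    dy2 <- (cells - gy[kk])^2
    H <- exp(-(outer(dy2, dx2, "+")) / (2 * config$heatmap_sigma^2))
    hm[, , kk] <- H / max(H)
    rx[, , kk] <- matrix(coords[kk, 1] - cells * df, side, side,
                         byrow = TRUE)
    ry[, , kk] <- matrix(coords[kk, 2] - cells * df, side, side)
  }
  out <- new("HeatmapBundle", heatmaps = hm, refineX = rx, refineY = ry,
             downsample = df)
  attr(out, "mask") <- mask
  out
}

#' Decode keypoint coordinates from heatmaps and refinement maps
#'
#' Per keypoint: the heatmap argmax cell is found (ties broken toward the
#' first cell in row-major order), the coordinate is the cell's full-image
#' center plus the refinement offsets read at that cell, and the likelihood
#' is the heatmap value at the argmax. An all-zero heatmap yields likelihood
#' 0 and the image center, flagged in the result.
#'
#' @param bundle a [HeatmapBundle-class].
#' @param config from [trackerConfig()].
#' @return data.frame with `x`, `y`, `likelihood`, `degenerate`.
#' @export
decodeHeatmaps <- function(bundle, config) {
  df <- bundle@downsample
  side <- dim(bundle@heatmaps)[1]
  K <- dim(bundle@heatmaps)[3]
  out <- data.frame(x = numeric(K), y = numeric(K), likelihood = numeric(K),
                    degenerate = logical(K))
  for (kk in seq_len(K)) {
    H <- bundle@heatmaps[, , kk]
    pk <- max(H)
    if (pk <= 0) {
      out$x[kk] <- (side * df) / 2; out$y[kk] <- (side * df) / 2
      out$likelihood[kk] <- 0; out$degenerate[kk] <- TRUE
      next
    }
    # row-major first: scan rows (y) then columns; R arrays are col-major so
    # transpose to get row-major linear order
    Ht <- t(H)
    lin <- which.max(Ht)  # first maximum in row-major order
    i <- (lin - 1L) %/% side   # row (y cell)
    j <- (lin - 1L) %% side    # col (x cell)
    out$x[kk] <- j * df + bundle@refineX[i + 1L, j + 1L, kk]
    out$y[kk] <- i * df + bundle@refineY[i + 1L, j + 1L, kk]
    out$likelihood[kk] <- pk
  }
  out
}

# loss + head gradients for a batch.
# hm_t, rx_t, ry_t: (side, side, K, N) targets; kpmask: K x N presence.
trackerLoss <- function(fwd, hm_t, rx_t, ry_t, refmask, kpmask) {
  z <- fwd$hm_logit
  p <- 1 / (1 + exp(-z))
  K <- dim(hm_t)[3]; N <- dim(hm_t)[4]; side <- dim(hm_t)[1]
  wk <- array(rep(kpmask, each = side * side), dim(hm_t))
  neff <- max(sum(wk), 1)
  eps <- 1e-7
  bce <- -sum(wk * (hm_t * log(p + eps) + (1 - hm_t) * log(1 - p + eps))) /
    neff
  d_hm <- wk * (p - hm_t) / neff
  rx_p <- fwd$ref[, , seq_len(K), , drop = FALSE]
  ry_p <- fwd$ref[, , K + seq_len(K), , drop = FALSE]
  wr <- refmask * wk
  nref <- max(sum(wr), 1)
  hub <- function(r) ifelse(abs(r) <= 1, 0.5 * r * r, abs(r) - 0.5)
  dhub <- function(r) pmax(pmin(r, 1), -1)
  rr_x <- rx_p - rx_t; rr_y <- ry_p - ry_t
  ref_loss <- sum(wr * (hub(rr_x) + hub(rr_y))) / nref
  d_ref <- array(0, dim(fwd$ref))
  d_ref[, , seq_len(K), ] <- wr * dhub(rr_x) / nref
  d_ref[, , K + seq_len(K), ] <- wr * dhub(rr_y) / nref
  list(loss = bce + 0.02 * ref_loss, d_hm = d_hm, d_ref = 0.02 * d_ref)
}

# sample augmentation: random crop + resize, optional flip, contrast gain.
# img: S x S matrix, coords: K x 2. Returns transformed pair.
augmentSample <- function(img, coords, config, flipPairs = NULL) {
  S <- config$input_size
  sc <- runif(1, 0.8, 1.0)
  cs <- max(2L, as.integer(round(sc * S)))
  oy <- sample.int(S - cs + 1L, 1L) - 1L
  ox <- sample.int(S - cs + 1L, 1L) - 1L
  img2 <- resizeBilinear(img[oy + seq_len(cs), ox + seq_len(cs),
                             drop = FALSE], S)
  f <- S / cs
  co <- coords
  co[, 1] <- (coords[, 1] - ox + 0.5) * f - 0.5
  co[, 2] <- (coords[, 2] - oy + 0.5) * f - 0.5
  out <- co[, 1] < 0 | co[, 1] > S - 1 | co[, 2] < 0 | co[, 2] > S - 1
  co[out & !is.na(out), ] <- NaN
  if (!is.null(flipPairs) && runif(1) < 0.5) {
    img2 <- img2[, rev(seq_len(S))]
    co[, 1] <- S - 1 - co[, 1]
    co <- co[flipPairs, , drop = FALSE]
  }
  gain <- runif(1, 0.7, 1.3)
  img2 <- (img2 - mean(img2)) * gain + mean(img2)
  list(img = img2, coords = co)
}

# shared optimization loop for training and fine-tuning
trackerOptimize <- function(net, frames, coords, opt, seed, augment = TRUE,
                            flipPairs = NULL) {
  set.seed(seed)
  S <- net@config$input_size
  N <- dim(frames)[3]
  if (!any(is.finite(coords)))
    stop("no visible keypoints in the training set")
  params <- net@layers
  states <- lapply(params, function(l) adamInit(l[c("W", "b")]))
  ep_bounds <- cumsum(round(opt$schedule_frac * opt$epochs))
  losses <- numeric(opt$epochs)
  step <- 0L
  for (ep in seq_len(opt$epochs)) {
    phase <- findInterval(ep, c(0, ep_bounds[-length(ep_bounds)] + 1L))
    lr <- opt$lr / opt$schedule_div[min(phase, length(opt$schedule_div))]
    ord <- sample.int(N)
    epl <- 0; nb <- 0L
    for (bstart in seq(1L, N, by = opt$batch)) {
      idx <- ord[bstart:min(bstart + opt$batch - 1L, N)]
      nB <- length(idx)
      xb <- array(0, c(S, S, 1L, nB))
      side <- S %/% net@config$downsample_factor
      K <- net@config$n_keypoints
      hm_t <- array(0, c(side, side, K, nB))
      rx_t <- array(0, c(side, side, K, nB))
      ry_t <- array(0, c(side, side, K, nB))
      refm <- array(0, c(side, side, K, nB))
      kpm <- matrix(0, K, nB)
      for (b in seq_len(nB)) {
        img <- normalizeFrame(frames[, , idx[b]])
        co <- coords[, , idx[b]]
        if (augment) {
          au <- augmentSample(img, co, net@config, flipPairs)
          img <- au$img; co <- au$coords
        }
        tg <- makeTargets(co, net@config)
        xb[, , 1L, b] <- img
        hm_t[, , , b] <- tg@heatmaps
        rx_t[, , , b] <- tg@refineX
        ry_t[, , , b] <- tg@refineY
        refm[, , , b] <- tg@heatmaps > exp(-net@config$refine_radius^2 /
                                           (2 * net@config$heatmap_sigma^2))
        kpm[, b] <- attr(tg, "mask")
      }
      netb <- new("TrackerNet", config = net@config, layers = params)
      fwd <- trackerForward(netb, xb, train = TRUE)
      ls <- trackerLoss(fwd, hm_t, rx_t, ry_t, refm, kpm)
      grads <- trackerBackward(netb, fwd, ls$d_hm, ls$d_ref)
      step <- step + 1L
      for (nm in names(params)) {
        for (pp in c("W", "b")) {
          up <- adamStep(params[[nm]][[pp]], grads[[nm]][[pp]],
                         states[[nm]][[pp]], lr, step,
                         decay = opt$weight_decay)
          params[[nm]][[pp]] <- up$p
          states[[nm]][[pp]] <- up$state
        }
      }
      epl <- epl + ls$loss; nb <- nb + 1L
    }
    losses[ep] <- epl / nb
  }
  list(net = new("TrackerNet", config = net@config, layers = params),
       loss = losses)
}

#' Train the tracker
#'
#' Runs the Adam optimizer with the staged learning-rate schedule over
#' augmented labeled frames (random crop + resize, optional horizontal flip
#' when a left/right pair map is given, contrast gain). Missing keypoint
#' labels (NaN) are masked out of the loss. Training is deterministic for a
#' given seed.
#'
#' @param net a [TrackerNet-class] from [buildTracker()].
#' @param frames H x W x N array of grayscale frames (H = W = input size).
#' @param coords n_keypoints x 2 x N label array, NaN for missing labels.
#' @param seed RNG seed.
#' @param epochs override the configured number of epochs.
#' @param augment apply training augmentations.
#' @param flipPairs integer permutation mapping each keypoint to its
#'   left/right mirror partner; when NULL horizontal flips are disabled.
#' @return list with the trained `net` and per-epoch `loss`.
#' @export
trainTracker <- function(net, frames, coords, seed = 1L, epochs = NULL,
                         augment = TRUE, flipPairs = NULL) {
  opt <- net@config$train
  if (!is.null(epochs)) opt$epochs <- as.integer(epochs)
  trackerOptimize(net, frames, coords, opt, seed, augment, flipPairs)
}

#' Fine-tune a trained tracker on a small set of refined frames
#'
#' Runs the same optimization loop as [trainTracker()] with the fine-tuning
#' hyperparameters (learning rate 1e-4, weight decay 1e-3, 36 epochs).
#' Fine-tuning with zero frames returns the base network unchanged. This is
#' the programmatic core of the human-in-the-loop refinement workflow:
#' predict, refine a handful of frames (1 to 50), retrain.
#'
#' @inheritParams trainTracker
#' @export
finetuneTracker <- function(net, frames, coords, seed = 1L, epochs = NULL,
                            augment = TRUE, flipPairs = NULL) {
  if (is.null(frames) || length(frames) == 0L || dim(frames)[3] == 0L)
    return(list(net = net, loss = numeric(0)))
  opt <- net@config$finetune
  if (!is.null(epochs)) opt$epochs <- as.integer(epochs)
  trackerOptimize(net, frames, coords, opt, seed, augment, flipPairs)
}

#' Predict keypoints for a stack of frames
#'
#' Frames are percentile-normalized, resized to the network input size if
#' needed, passed through the network and decoded to subpixel coordinates in
#' the original image resolution.
#'
#' @param net a trained [TrackerNet-class].
#' @param frames H x W x N array.
#' @param rate video frame rate in Hz.
#' @param batch frames per forward pass.
#' @return a [KeypointSeries-class] with tracker likelihoods.
#' @export
predictKeypoints <- function(net, frames, rate = 50, batch = 8L) {
  S <- net@config$input_size
  N <- dim(frames)[3]
  K <- net@config$n_keypoints
  scale <- dim(frames)[1] / S
  co <- array(NA_real_, c(N, K, 2))
  lk <- matrix(0, N, K)
  for (bstart in seq(1L, N, by = batch)) {
    idx <- bstart:min(bstart + batch - 1L, N)
    xb <- array(0, c(S, S, 1L, length(idx)))
    for (b in seq_along(idx)) {
      img <- frames[, , idx[b]]
      if (scale != 1) img <- resizeBilinear(img, S)
      xb[, , 1L, b] <- normalizeFrame(img)
    }
    fwd <- trackerForward(net, xb)
    hm <- 1 / (1 + exp(-fwd$hm_logit))
    for (b in seq_along(idx)) {
      bun <- new("HeatmapBundle",
                 heatmaps = hm[, , , b, drop = TRUE],
                 refineX = fwd$ref[, , seq_len(K), b, drop = TRUE],
                 refineY = fwd$ref[, , K + seq_len(K), b, drop = TRUE],
                 downsample = net@config$downsample_factor)
      dec <- decodeHeatmaps(bun, net@config)
      co[idx[b], , 1] <- dec$x * scale
      co[idx[b], , 2] <- dec$y * scale
      lk[idx[b], ] <- dec$likelihood
    }
  }
  sc <- if (K == 13L) defaultSchema() else
    inferSchema(paste0("kp", seq_len(K)))
  keypointSeries(co, lk, rate = rate, schema = sc)
}

#' Pixel-error evaluation of keypoint predictions
#'
#' Euclidean error per (frame, bodypart); ground-truth NaNs are skipped.
#' Reports the mean over all present labels and per face-region means.
#'
#' @param pred,truth N x K x 2 coordinate arrays.
#' @param schema optional [KeypointSchema-class] for group-wise means.
#' @return list with `per_label` error matrix, `mean`, and `by_group`.
#' @export
evalTracker <- function(pred, truth, schema = NULL) {
  err <- sqrt((pred[, , 1] - truth[, , 1])^2 +
              (pred[, , 2] - truth[, , 2])^2)
  err <- matrix(err, dim(pred)[1], dim(pred)[2])
  if (all(!is.finite(err))) stop("no present labels to evaluate")
  by_group <- NULL
  if (!is.null(schema)) {
    grp <- schema@groups[schema@bodyparts]
    by_group <- c(tapply(colMeans(err, na.rm = TRUE), grp, mean,
                         na.rm = TRUE))
  }
  list(per_label = err, mean = mean(err, na.rm = TRUE), by_group = by_group)
}

#' Save / load a tracker checkpoint (binary, with embedded config)
#' @param net a [TrackerNet-class].
#' @param path checkpoint file path.
#' @export
saveTracker <- function(net, path) {
  saveRDS(list(config = net@config, layers = net@layers), path)
  invisible(path)
}

#' @rdname saveTracker
#' @export
loadTracker <- function(path) {
  ck <- readRDS(path)
  new("TrackerNet", config = ck$config, layers = ck$layers)
}
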