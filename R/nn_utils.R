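# Small shared pieces for the hand-rolled networks: parameter init, Adam
# updates and image resizing. All randomness goes through R's RNG so that a
# single set.seed() makes training bit-reproducible.

heInit <- function(nout, nin, gain = sqrt(2)) {
  matrix(rnorm(nout * nin, sd = gain / sqrt(nin)), nout, nin)
}

adamInit <- function(params) {
  lapply(params, function(p) list(m = p * 0, v = p * 0))
}

# decoupled weight decay (AdamW); decay = 0 recovers plain Adam
adamStep <- function(p, g, state, lr, t, beta1 = 0.9, beta2 = 0.999,
                     eps = 1e-8, decay = 0) {
  state$m <- beta1 * state$m + (1 - beta1) * g
  state$v <- beta2 * state$v + (1 - beta2) * g * g
  mhat <- state$m / (1 - beta1^t)
  vhat <- state$v / (1 - beta2^t)
  p <- p - lr * (mhat / (sqrt(vhat) + eps) + decay * p)
  list(p = p, state = state)
}

# bilinear resize of a 2-D matrix to sout x sout
resizeBilinear <- function(img, sout) {
  interpMat <- function(nin, nout) {
    pos <- (seq_len(nout) - 0.5) * nin / nout - 0.5
    pos <- pmin(pmax(pos, 0), nin - 1)
    lo <- floor(pos); hi <- pmin(lo + 1, nin - 1); w <- pos - lo
    M <- matrix(0, nout, nin)
    M[cbind(seq_len(nout), lo + 1)] <- 1 - w
    M[cbind(seq_len(nout), hi + 1)] <- M[cbind(seq_len(nout), hi + 1)] + w
    M
  }
  interpMat(nrow(img), sout) %*% img %*% t(interpMat(ncol(img), sout))
}

# concatenate two (H,W,C,N) tensors along the channel dimension
bindChannels <- function(x, y) {
  dx <- dim(x); dy <- dim(y)
  out <- array(0, c(dx[1], dx[2], dx[3] + dy[3], dx[4]))
  out[, , seq_len(dx[3]), ] <- x
  out[, , dx[3] + seq_len(dy[3]), ] <- y
  out
}

reluFwd <- function(x) {
  x[x < 0] <- 0
  x
}

# `a` is the post-activation tensor
reluBwd <- function(da, a) da * (a > 0)
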