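# Discrete Gaussian-emission HMM over deep behavioral features (or keypoints
# or neural cluster traces): exact log-likelihood via the log-space forward
# recursion, direct gradient ascent on it, Viterbi inference, simulation and
# the transition-structure statistics.

# column z-scoring tolerant of constant columns (left centered at zero)
zscoreCols <- function(z) {
  mu <- colMeans(z)
  s <- apply(z, 2, sd)
  s[s == 0 | !is.finite(s)] <- 1
  sweep(sweep(z, 2, mu), 2, s, "/")
}

# T x K matrix of log emission densities
hmmEmissionLog <- function(z, C, sigma2) {
  n <- ncol(z)
  sq <- outer(rowSums(z^2), rowSums(C^2), "+") - 2 * z %*% t(C)
  -0.5 * sq / sigma2 - 0.5 * n * log(2 * pi * sigma2)
}

#' Construct an HmmModel from explicit parameters
#'
#' @param A K x K row-stochastic transition matrix.
#' @param C K x n emission means.
#' @param b initial-state probabilities (default uniform).
#' @param sigma2 fixed emission variance.
#' @return an [HmmModel-class].
#' @export
hmmModel <- function(A, C, b = NULL, sigma2 = 1) {
  K <- nrow(A)
  if (is.null(b)) b <- rep(1 / K, K)
  new("HmmModel", K = as.integer(K), Q = log(pmax(A, 1e-300)),
      means = as.matrix(C), blogits = log(pmax(b, 1e-300)), sigma2 = sigma2)
}

#' Emission variance policy
#'
#' The emission variance is never learned; it is fixed proportional to the
#' summed variance of the features, scaled so that 256-dimensional deep
#' behavioral features get exactly 1 (and keypoint features get their summed
#' variance over 256). This keeps the weight of the observation term in the
#' likelihood comparable across feature spaces of different dimensionality.
#'
#' @param z time x features matrix.
#' @export
sigmaPolicy <- function(z) {
  sum(apply(z, 2, var)) / 256
}

#' Exact HMM log-likelihood
#'
#' Computes `log P(z_1..z_T)` with the log-space forward recursion
#' (`logsumexp` over predecessor states at every step), numerically stable
#' for long sequences.
#'
#' @param model an [HmmModel-class].
#' @param z time x features matrix.
#' @export
hmmLogLik <- function(model, z) {
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z))) stop("z contains non-finite values")
  emis <- hmmEmissionLog(z, model@means, model@sigma2)
  A <- transitionMatrix(model)
  logb <- log(initialProbs(model))
  hmm_forward_cpp(emis, A, rbind(logb))$loglik
}

# shared initialization: Q_ii = 3 off-diagonal 0, emission means from random
# data samples, uniform initial logits
hmmInit <- function(z, K, seed) {
  set.seed(seed)
  Q <- matrix(0, K, K)
  diag(Q) <- 3
  C <- z[sample.int(nrow(z), K), , drop = FALSE]
  list(Q = Q, C = C, blogits = rep(0, K))
}

#' Fit the HMM by direct gradient ascent on the exact log-likelihood
#'
#' The transition matrix is reparametrized through a log-transition matrix Q
#' with `A = softmax(Q)` row-wise (initialized to `Q_ii = 3`, 0 off the
#' diagonal) and the initial distribution through logits; emission means are
#' initialized at random data samples and the emission variance is fixed by
#' [sigmaPolicy()] (never learned). Each iteration evaluates the exact
#' forward log-likelihood and its analytic gradient (via forward-backward
#' posteriors) over the full sequence, and takes an Adam ascent step.
#'
#' @param z time x features matrix. Columns are standardized internally so
#'   the variance policy is well defined (disable with `standardize =
#'   FALSE`).
#' @param K number of states (50 in typical use).
#' @param sigma2 fixed emission variance; default from [sigmaPolicy()]
#'   applied to the standardized features.
#' @param iters gradient iterations.
#' @param lr Adam learning rate.
#' @param seed RNG seed.
#' @param standardize z-score feature columns first.
#' @param restarts independent runs from fresh random-sample
#'   initializations; the run with the best final training log-likelihood
#'   is returned (emission-mean inits occasionally split one true state
#'   and merge two others, a local optimum with clearly lower likelihood).
#' @return list with the fitted `model` and the per-iteration log-likelihood
#'   `trace` of the winning run.
#' @export
hmmFit <- function(z, K, sigma2 = NULL, iters = 400L, lr = 0.05, seed = 1L,
                   standardize = TRUE, restarts = 1L) {
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z))) stop("z contains non-finite values")
  if (standardize) z <- zscoreCols(z)
  if (is.null(sigma2)) sigma2 <- sigmaPolicy(z)
  if (restarts > 1L) {
    runs <- lapply(seq_len(restarts) - 1L, function(r)
      hmmFit(z, K, sigma2 = sigma2, iters = iters, lr = lr,
             seed = seed + r, standardize = FALSE, restarts = 1L))
    return(runs[[which.max(vapply(runs, function(x)
      x$trace[length(x$trace)], 0))]])
  }
  par <- hmmInit(z, K, seed)
  states <- adamInit(par)
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    A <- softmaxRows(par$Q)
    b <- exp(par$blogits - max(par$blogits)); b <- b / sum(b)
    emis <- hmmEmissionLog(z, par$C, sigma2)
    post <- hmm_posteriors_cpp(emis, A, rbind(log(b)))
    if (!is.finite(post$loglik))
      stop("non-finite log-likelihood at iteration ", it,
           " (sigma2 = ", sigma2, ")")
    trace[it] <- post$loglik
    gamma <- post$gamma
    xi <- post$xi_sum
    gQ <- xi - rowSums(xi) * A
    gb <- gamma[1, ] - b
    gC <- (crossprod(gamma, z) - colSums(gamma) * par$C) / sigma2
    grads <- list(Q = gQ, C = gC, blogits = gb)
    for (nm in names(par)) {
      up <- adamStep(par[[nm]], -grads[[nm]], states[[nm]], lr, it)
      par[[nm]] <- up$p; states[[nm]] <- up$state
    }
  }
  model <- new("HmmModel", K = as.integer(K), Q = par$Q,
               means = par$C, blogits = par$blogits, sigma2 = sigma2)
  list(model = model, trace = trace)
}

#' Expectation-maximization baseline for the HMM
#'
#' Classic Baum-Welch with the emission variance held fixed, run from the
#' same initialization scheme as [hmmFit()]. Used as the reference that
#' gradient optimization should match or beat in held-out log-likelihood.
#'
#' @inheritParams hmmFit
#' @export
hmmFitEM <- function(z, K, sigma2 = NULL, iters = 100L, seed = 1L,
                     standardize = TRUE) {
  z <- as.matrix(z)
  if (standardize) z <- zscoreCols(z)
  if (is.null(sigma2)) sigma2 <- sigmaPolicy(z)
  par <- hmmInit(z, K, seed)
  A <- softmaxRows(par$Q)
  b <- rep(1 / K, K)
  C <- par$C
  trace <- numeric(iters)
  for (it in seq_len(iters)) {
    emis <- hmmEmissionLog(z, C, sigma2)
    post <- hmm_posteriors_cpp(emis, A, rbind(log(b)))
    trace[it] <- post$loglik
    gamma <- post$gamma
    xi <- post$xi_sum
    A <- xi + 1e-12
    A <- A / rowSums(A)
    b <- gamma[1, ] + 1e-12
    b <- b / sum(b)
    w <- colSums(gamma)
    C <- crossprod(gamma, z) / w
  }
  model <- hmmModel(A, C, b, sigma2)
  list(model = model, trace = trace)
}

#' Most likely state path (Viterbi)
#'
#' Log-space max-product recursion with backtracking; ties are broken toward
#' the lowest state index. The initial distribution `b` is used at t = 1.
#'
#' @inheritParams hmmLogLik
#' @return integer state path of length `nrow(z)`.
#' @export
hmmViterbi <- function(model, z) {
  z <- as.matrix(z)
  if (anyNA(z) || any(!is.finite(z))) stop("z contains non-finite values")
  emis <- hmmEmissionLog(z, model@means, model@sigma2)
  as.integer(hmm_viterbi_cpp(emis, transitionMatrix(model),
                             rbind(log(initialProbs(model)))))
}

#' Simulate states and features from an HMM
#'
#' Draws the initial state from `b`, runs the Markov chain forward, and
#' emits `z_t ~ N(C_{h_t}, sigma2 I)`.
#'
#' @param model an [HmmModel-class].
#' @param T number of timesteps.
#' @param seed RNG seed.
#' @return list with integer `states` and `z` (T x n).
#' @export
hmmSimulate <- function(model, T, seed = 1L) {
  set.seed(seed)
  A <- transitionMatrix(model)
  b <- initialProbs(model)
  K <- model@K
  h <- integer(T)
  h[1] <- sample.int(K, 1L, prob = b)
  for (t in seq_len(T - 1L))
    h[t + 1L] <- sample.int(K, 1L, prob = A[h[t], ])
  n <- ncol(model@means)
  z <- model@means[h, , drop = FALSE] +
    matrix(rnorm(T * n, sd = sqrt(model@sigma2)), T, n)
  list(states = h, z = z)
}

#' State lifetimes
#'
#' `-log(1 - A_ii)` per state: the mean dwell time (in model timesteps, up
#' to the log scale used in the source analyses) implied by the
#' self-transition probability.
#'
#' @param model an [HmmModel-class] or a transition matrix.
#' @export
stateLifetimes <- function(model) {
  A <- if (is(model, "HmmModel")) transitionMatrix(model) else model
  -log(pmax(1 - diag(A), 1e-300))
}

#' Off-diagonal-normalized transition matrix
#'
#' Sets self-transitions to zero and renormalizes each row to sum to 1.
#' Absorbing states (self-transition ~1) get an all-zero row and are
#' flagged.
#'
#' @param model an [HmmModel-class] or a transition matrix.
#' @return list with `B`, logical `absorbing`, and `lifetimes`.
#' @export
normalizeTransitions <- function(model) {
  A <- if (is(model, "HmmModel")) transitionMatrix(model) else model
  B <- A
  diag(B) <- 0
  rs <- rowSums(B)
  absorbing <- rs <= 1e-12
  rs[absorbing] <- 1
  B <- B / rs
  B[absorbing, ] <- 0
  list(B = B, absorbing = absorbing, lifetimes = stateLifetimes(A))
}

#' Sort states to concentrate transition mass just above the diagonal
#'
#' Finds the permutation maximizing the similarity of the reordered
#' off-diagonal transition matrix to the target `F_ji = -log((i - j)^2)` for
#' j < i (0 elsewhere), so high-probability transitions land on or near the
#' first superdiagonal. Exhaustive enumeration for K <= 8; otherwise a
#' seeded stochastic local search (greedy insertion construction plus
#' pairwise-swap hill climbing over restarts). Deterministic per seed.
#'
#' @param B off-diagonal-normalized transition matrix.
#' @param restarts local-search restarts.
#' @param seed search seed.
#' @return list with `perm` (state order), `objective`, `exact`.
#' @export
sortStates <- function(B, restarts = 200L, seed = 1L) {
  K <- nrow(B)
  F <- matrix(0, K, K)
  for (j in seq_len(K))
    for (i in seq_len(K))
      if (j < i) F[j, i] <- -log((i - j)^2)
  sort_states_cpp(B, F, as.integer(restarts), as.integer(seed))
}

#' Transition sparsity and asymmetry statistics
#'
#' Per state, the cumulative probability of transitioning to its n most
#' probable successor states (n = 1..K-1), averaged over states; and for
#' each "near" pair (j, i) - i among the `nNear` most probable successors of
#' j - the reverse probability `B_ij`, the two-step forward probability
#' `max_k B_jk B_ki` and the two-step backward probability
#' `max_k B_ik B_kj`. The baseline is the mean off-diagonal transition
#' probability.
#'
#' @param B off-diagonal-normalized transition matrix.
#' @param nNear number of near states per state (default 5).
#' @return list with `nearest_curve`, `reverse`, `twostep_forward`,
#'   `twostep_backward`, `baseline`, and the near `pairs`.
#' @export
transitionStats <- function(B, nNear = 5L) {
  K <- nrow(B)
  sorted <- t(apply(B, 1, sort, decreasing = TRUE))
  cums <- apply(sorted[, seq_len(K - 1L), drop = FALSE], 1, cumsum)
  curve <- if (K == 2L) mean(cums) else rowMeans(cums)
  pairs <- do.call(rbind, lapply(seq_len(K), function(j) {
    ord <- order(B[j, ], decreasing = TRUE)
    ord <- ord[seq_len(min(nNear, K - 1L))]
    ord <- ord[B[j, ord] > 0]    # degenerate zero-probability "near"
    if (!length(ord)) return(NULL)
    cbind(j = j, i = ord)
  }))
  rev_p <- B[pairs[, c(2, 1), drop = FALSE]]
  two_f <- apply(pairs, 1, function(p)
    max(B[p[1], ] * B[, p[2]]))
  two_b <- apply(pairs, 1, function(p)
    max(B[p[2], ] * B[, p[1]]))
  offdiag <- B[row(B) != col(B)]
  list(nearest_curve = as.numeric(curve), reverse = mean(rev_p),
       twostep_forward = mean(two_f), twostep_backward = mean(two_b),
       baseline = mean(offdiag), pairs = pairs)
}

#' Forward sequence length distribution
#'
#' Collapses consecutive duplicate states in a path, maps states to their
#' rank in the sorted state order, and counts maximal strictly increasing
#' runs of each length.
#'
#' @param path integer state path (e.g. from [hmmViterbi()]).
#' @param perm state order from [sortStates()].
#' @return table of run lengths.
#' @export
forwardSequences <- function(path, perm) {
  pos <- match(path, perm)
  pos <- pos[c(TRUE, diff(pos) != 0)]  # collapse consecutive duplicates
  if (length(pos) == 1L) return(table(factor(1, levels = 1)))
  runs <- integer(0)
  cur <- 1L
  for (t in 2:length(pos)) {
    if (pos[t] > pos[t - 1]) cur <- cur + 1L
    else { runs <- c(runs, cur); cur <- 1L }
  }
  runs <- c(runs, cur)
  table(factor(runs, levels = seq_len(max(runs))))
}

#' Joint time shuffle of a feature matrix
#'
#' Randomly permutes timepoints (jointly across features), preserving every
#' feature's marginal distribution while destroying temporal structure. The
#' control used to show that fitted state lifetimes reflect real dynamics.
#'
#' @param z time x features matrix.
#' @param seed RNG seed.
#' @export
shuffleTime <- function(z, seed = 1L) {
  set.seed(seed)
  z[sample.int(nrow(z)), , drop = FALSE]
}

#' Neural populations tuned to HMM states
#'
#' A "trial" is an uninterrupted run of the same state in the (neural-rate)
#' state path. Each neuron's trial response is its mean activity over the
#' trial. Trials of each state are split into train and test halves; the
#' `topN` neurons with the highest train-trial mean response are selected
#' per state and their test-trial averages reported. States with fewer than
#' 2 trials are excluded with a warning.
#'
#' @param states integer state path at neural frame times.
#' @param recording a [NeuralRecording-class] (or neurons x timepoints
#'   matrix).
#' @param topN neurons to select per state (300 in typical use).
#' @param trainFrac fraction of trials used for selection.
#' @param seed RNG seed for the trial split.
#' @return list per retained state with `neurons`, `test_mean`,
#'   `train_mean`, `n_trials`.
#' @export
stateTunedPopulations <- function(states, recording, topN = 300L,
                                  trainFrac = 0.5, seed = 1L) {
  act <- if (is(recording, "NeuralRecording")) activity(recording)
         else as.matrix(recording)
  stopifnot(length(states) == ncol(act))
  set.seed(seed)
  r <- rle(states)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  out <- list()
  for (s in sort(unique(states))) {
    tri <- which(r$values == s)
    if (length(tri) < 2L) {
      warning("state ", s, " has fewer than 2 trials; excluded")
      next
    }
    resp <- vapply(tri, function(tt)
      rowMeans(act[, starts[tt]:ends[tt], drop = FALSE]), numeric(nrow(act)))
    ord <- sample.int(length(tri))
    ntr <- max(1L, floor(trainFrac * length(tri)))
    trI <- ord[seq_len(ntr)]
    teI <- ord[-seq_len(ntr)]
    trainMean <- rowMeans(resp[, trI, drop = FALSE])
    sel <- order(trainMean, decreasing = TRUE)[seq_len(min(topN,
                                                           nrow(act)))]
    out[[as.character(s)]] <- list(
      neurons = sel,
      train_mean = trainMean[sel],
      test_mean = rowMeans(resp[sel, teI, drop = FALSE]),
      n_trials = length(tri))
  }
  out
}
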