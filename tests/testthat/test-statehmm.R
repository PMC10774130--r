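# Discrete Gaussian-emission HMM: exact-likelihood oracles, gradient
# fitting, Viterbi, simulation and transition statistics.

# brute-force path enumeration oracle for tiny instances
bruteLogLik <- function(model, z) {
  K <- model@K; T <- nrow(z)
  A <- transitionMatrix(model)
  b <- initialProbs(model)
  emis <- facekit:::hmmEmissionLog(z, emissionMeans(model), model@sigma2)
  paths <- as.matrix(expand.grid(rep(list(seq_len(K)), T)))
  lp <- apply(paths, 1, function(h) {
    v <- log(b[h[1]]) + emis[1, h[1]]
    for (t in seq_len(T)[-1]) v <- v + log(A[h[t - 1], h[t]]) + emis[t, h[t]]
    v
  })
  m <- max(lp)
  list(loglik = m + log(sum(exp(lp - m))),
       best = paths[which.max(lp), ])
}

randomModel <- function(K, n, seed) {
  set.seed(seed)
  A <- matrix(runif(K * K) + 0.05, K)
  A <- A / rowSums(A)
  b <- runif(K) + 0.05; b <- b / sum(b)
  hmmModel(A, matrix(rnorm(K * n), K, n), b, sigma2 = runif(1, 0.5, 2))
}

test_that("forward log-likelihood and Viterbi match path enumeration", {
  for (seed in 1:20) {
    K <- 3; T <- sample(3:6, 1)
    m <- randomModel(K, 2, seed)
    set.seed(seed + 100)
    z <- matrix(rnorm(T * 2), T, 2)
    oracle <- bruteLogLik(m, z)
    expect_equal(hmmLogLik(m, z), oracle$loglik, tolerance = 1e-8)
    expect_equal(hmmViterbi(m, z), unname(as.integer(oracle$best)))
  }
})

test_that("single-state and single-frame limits are closed form", {
  set.seed(2)
  z <- matrix(rnorm(20), 10, 2)
  m1 <- hmmModel(matrix(1, 1, 1), matrix(0, 1, 2), sigma2 = 1)
  expect_equal(hmmLogLik(m1, z), sum(dnorm(z, log = TRUE)),
               tolerance = 1e-10)
  m <- randomModel(3, 2, 3)
  z1 <- z[1, , drop = FALSE]
  emis <- facekit:::hmmEmissionLog(z1, emissionMeans(m), m@sigma2)
  expect_equal(hmmLogLik(m, z1),
               log(sum(initialProbs(m) * exp(emis[1, ]))),
               tolerance = 1e-10)
  zb <- z; zb[3, 1] <- NaN
  expect_error(hmmLogLik(m, zb), "non-finite")
})

test_that("forward recursion is stable on long sequences", {
  m <- randomModel(4, 3, 7)
  sim <- hmmSimulate(m, 1e5, seed = 8)
  ll <- hmmLogLik(m, sim$z)
  expect_true(is.finite(ll))
})

test_that("gradient fit recovers a planted 5-state model and beats EM", {
  syn <- synthHmmSequence(K = 5, n = 16, T = 20000, selfP = 0.9,
                          forwardBias = 0.3, sep = 1.5, seed = 11)
  sp <- makeSplit(20000, 1, 10, 0.75, 0)
  ztr <- syn$z[sp@trainIdx, ]
  zte <- syn$z[sp@testIdx, ]
  fit <- hmmFit(ztr, K = 5, iters = 400, seed = 2, restarts = 3L)
  em <- hmmFitEM(ztr, K = 5, iters = 100, seed = 2)
  llg <- hmmLogLik(fit$model, zte) / nrow(zte)
  lle <- hmmLogLik(em$model, zte) / nrow(zte)
  expect_gte(llg, lle - 1e-3)
  # match states to truth through the emission means (exhaustive over 5!)
  zs <- facekit:::zscoreCols(ztr)
  mu <- colMeans(ztr); sdv <- apply(ztr, 2, sd)
  CtrueS <- sweep(sweep(emissionMeans(syn$model), 2, mu), 2, sdv, "/")
  Cfit <- emissionMeans(fit$model)
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(p) length(unique(p)) == 5), ]
  cost <- apply(perms, 1, function(p) sum((Cfit[p, ] - CtrueS)^2))
  p <- perms[which.min(cost), ]
  tv <- 0.5 * rowSums(abs(transitionMatrix(fit$model)[p, p] -
                            transitionMatrix(syn$model)))
  expect_lt(max(tv), 0.05)
})

test_that("time-shuffling collapses fitted lifetimes", {
  syn <- synthHmmSequence(K = 8, n = 8, T = 6000, selfP = 0.9, seed = 5)
  fit <- hmmFit(syn$z, 8, iters = 150, seed = 2)
  fitS <- hmmFit(shuffleTime(syn$z, seed = 9), 8, iters = 150, seed = 2)
  expect_lt(median(stateLifetimes(fitS$model)),
            median(stateLifetimes(fit$model)))
})

test_that("K = 1 fit converges to the data mean", {
  set.seed(6)
  z <- matrix(rnorm(4000, mean = 3), 2000, 2)
  fit <- hmmFit(z, 1, iters = 300, seed = 1, standardize = FALSE,
                sigma2 = 1)
  expect_lt(max(abs(emissionMeans(fit$model) - colMeans(z))), 1e-3)
})

test_that("simulation follows the transition law and dwell statistics", {
  m <- randomModel(4, 2, 9)
  sim <- hmmSimulate(m, 1e5, seed = 5)
  emp <- table(factor(head(sim$states, -1), 1:4),
               factor(tail(sim$states, -1), 1:4))
  emp <- emp / rowSums(emp)
  expect_lt(max(abs(emp - transitionMatrix(m))), 0.02)
  # identity-dominated chain dwells ~ 1/(1-p)
  mp <- hmmModel(matrix(c(0.99, 0.01, 0.01, 0.99), 2, byrow = TRUE),
                 matrix(c(0, 5), 2, 1), sigma2 = 1)
  simp <- hmmSimulate(mp, 1e5, seed = 6)
  expect_equal(mean(rle(simp$states)$lengths), 100, tolerance = 0.15)
  # determinism
  expect_identical(hmmSimulate(m, 100, seed = 3)$states,
                   hmmSimulate(m, 100, seed = 3)$states)
})

test_that("lifetime formula matches geometric dwell times", {
  p <- c(0.5, 1 - exp(-1), 0.9, 0.99)
  lt <- -log(1 - p)
  expect_true(all(diff(lt) > 0))           # monotone in p
  expect_equal(lt[2], 1)                   # equals 1 at p = 1 - 1/e
  A <- diag(0.9, 3); A[A == 0] <- 0.05
  expect_equal(stateLifetimes(A), rep(-log(0.1), 3))
})

test_that("off-diagonal normalization and its edge cases", {
  A <- matrix(c(0.8, 0.15, 0.05,
                0.1, 0.8, 0.1,
                0.0, 0.0, 1.0), 3, byrow = TRUE)
  nt <- normalizeTransitions(A)
  expect_equal(nt$B[1, ], c(0, 0.75, 0.25))
  expect_equal(rowSums(nt$B)[1:2], c(1, 1))
  expect_true(nt$absorbing[3])
  expect_equal(nt$B[3, ], rep(0, 3))
  # uniform A gives uniform off-diagonal B
  Au <- matrix(1 / 4, 4, 4)
  expect_true(all(abs(normalizeTransitions(Au)$B[row(Au) != col(Au)] -
                        1 / 3) < 1e-12))
})

test_that("state sorting finds the planted cyclic order", {
  # perfect cycle: exhaustive search at K = 6 puts all mass on the first
  # superdiagonal plus the wrap-around corner
  K <- 6
  B <- matrix(0, K, K)
  B[cbind(1:K, c(2:K, 1))] <- 1
  set.seed(9)
  sh <- sample(K)
  ss <- sortStates(B[sh, sh])
  expect_true(ss$exact)
  Bs <- B[sh, sh][ss$perm, ss$perm]
  expect_equal(sum(Bs[cbind(1:(K - 1), 2:K)]) + Bs[K, 1], K)
  # local search recovers a strongly forward-biased chain at K = 12
  syn <- synthHmmSequence(K = 12, n = 8, T = 2000, selfP = 0.85,
                          forwardBias = 0.9, seed = 3)
  nt <- normalizeTransitions(syn$model)
  set.seed(1); sh2 <- sample(12)
  ss2 <- sortStates(nt$B[sh2, sh2], restarts = 60, seed = 4)
  B2 <- nt$B[sh2, sh2][ss2$perm, ss2$perm]
  expect_gt(mean(B2[cbind(1:11, 2:12)]), 0.6)
  # deterministic per seed
  ss3 <- sortStates(nt$B[sh2, sh2], restarts = 60, seed = 4)
  expect_identical(ss2$perm, ss3$perm)
})

test_that("transition statistics have their closed-form extremes", {
  K <- 8
  Bu <- matrix(1 / (K - 1), K, K); diag(Bu) <- 0
  st <- transitionStats(Bu)
  expect_equal(st$nearest_curve, (1:(K - 1)) / (K - 1), tolerance = 1e-12)
  expect_equal(st$baseline, 1 / (K - 1))
  # deterministic chain saturates at n = 1
  Bd <- matrix(0, K, K); Bd[cbind(1:K, c(2:K, 1))] <- 1
  expect_equal(transitionStats(Bd)$nearest_curve[1], 1)
  # an asymmetric cycle has reverse probability at baseline, a symmetric
  # random walk far above it
  Brw <- matrix(0, K, K)
  Brw[cbind(1:K, c(2:K, 1))] <- 0.5
  Brw[cbind(1:K, c(K, 1:(K - 1)))] <- 0.5
  expect_gt(transitionStats(Brw)$reverse,
            transitionStats(Brw)$baseline * 2)
  expect_lte(transitionStats(Bd)$reverse, transitionStats(Bd)$baseline)
})

test_that("forward sequences count maximal increasing runs", {
  fs <- forwardSequences(c(1, 1, 2, 3, 3, 1, 2), perm = 1:3)
  expect_equal(as.integer(fs[c("2", "3")]), c(1L, 1L))
  expect_equal(sum(fs), 2L)
  # single state: one run of length 1
  fs1 <- forwardSequences(c(2, 2, 2), perm = 1:3)
  expect_equal(sum(fs1), 1L)
  expect_equal(as.integer(fs1["1"]), 1L)
  # a forward-biased chain has longer runs than an i.i.d. sequence
  syn <- synthHmmSequence(K = 10, n = 4, T = 4000, selfP = 0.3,
                          forwardBias = 0.9, seed = 7)
  set.seed(8)
  iid <- sample.int(10, 4000, replace = TRUE)
  runLen <- function(f) sum(as.integer(names(f)) * as.integer(f)) / sum(f)
  expect_gt(runLen(forwardSequences(syn$states, 1:10)),
            runLen(forwardSequences(iid, 1:10)))
})

test_that("time shuffling preserves marginals and kills autocorrelation", {
  set.seed(4)
  z <- matrix(cumsum(rnorm(3000)), 1500, 2)
  zs <- shuffleTime(z, seed = 5)
  expect_equal(apply(zs, 2, mean), apply(z, 2, mean))
  expect_equal(apply(zs, 2, sort), apply(z, 2, sort))
  ac <- cor(zs[-1, 1], zs[-nrow(zs), 1])
  expect_lt(abs(ac), 0.1)
  expect_identical(shuffleTime(z, seed = 5), shuffleTime(z, seed = 5))
})

test_that("state-tuned populations select planted gated neurons", {
  set.seed(10)
  K <- 4
  syn <- synthHmmSequence(K = K, n = 3, T = 1500, selfP = 0.85, seed = 12)
  states <- syn$states
  n <- 120
  gatedOn <- rep(1:K, length.out = n)   # neuron i fires in state gatedOn[i]
  act <- matrix(rnorm(n * 1500, sd = 0.5), n, 1500)
  for (i in seq_len(n))
    act[i, states == gatedOn[i]] <- act[i, states == gatedOn[i]] + 3
  rec <- neuralRecording(act, cbind(runif(n), runif(n)), rate = 3)
  pops <- stateTunedPopulations(states, rec, topN = 30L, seed = 2)
  for (s in names(pops)) {
    sel <- pops[[s]]$neurons
    expect_gte(mean(gatedOn[sel] == as.integer(s)), 0.95)
    expect_gt(mean(pops[[s]]$test_mean), 1)   # selectivity holds on test
  }
  # trial definition: s,s,t,s gives two s-trials and one t-trial
  r <- rle(c(1, 1, 2, 1))
  expect_equal(sum(r$values == 1), 2L)
  expect_equal(sum(r$values == 2), 1L)
  # shuffled labels: no test-trial selectivity beyond noise
  set.seed(3)
  popsS <- stateTunedPopulations(sample(states), rec, topN = 30L, seed = 2)
  selS <- vapply(popsS, function(p) mean(p$test_mean), 0)
  base <- mean(act)
  expect_lt(mean(selS) - base, 1)
})
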