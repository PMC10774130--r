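# facekit

Tools for quantifying mouse orofacial behavior from videos and for
modeling how behavior drives large-scale neural activity. The package
provides, as tested R functions with S4 data classes:

* a compact **U-Net-style keypoint tracker** for 13 orofacial landmarks
  (eye, mouth, nose, whiskers), trained on probability heatmaps plus
  location-refinement maps and decoded to subpixel coordinates, with a
  fine-tuning workflow that adapts the tracker to new recording setups
  from a handful of refined frames;
* **quality-control filtering** of keypoint traces (likelihood,
  jump and deviation rules; median-filter imputation);
* an **autoregressive timescale estimator**: ridge regression on causal
  exponential-decay basis features predicts each keypoint into the
  future, and the lag at which test variance explained halves is the
  keypoint's predictability timescale;
* a **deep encoding model** of neural population activity from behavior
  (linear layer, temporal convolution, two fully-connected ReLU layers
  producing 256 "deep behavioral features", linear readout to the top
  neural PCs), with a reduced-rank regression baseline, peer-prediction
  **explainable variance** to normalize what a model could at best
  explain, and cumulative variance explained across neural PCs;
* **scaled k-means** clustering of neurons (a per-neuron gain times a
  cluster pattern) and a KL-divergence **spatial locality index** linking
  a cluster's predictability to its spatial spread;
* a **discrete Gaussian-emission HMM** over deep behavioral features (or
  keypoints), fit by direct gradient ascent on the exact forward
  log-likelihood with a softmax-reparameterized transition matrix and a
  fixed emission variance, plus Viterbi decoding, simulation, and a full
  battery of state-transition statistics (lifetimes `-log(1 - A_ii)`,
  off-diagonal-normalized transitions, transition-sorted state orders,
  n-nearest transition curves, reverse/two-step probabilities, forward
  sequence lengths, state-tuned neural populations);
* **synthetic-data generators** (toy face videos with known keypoints,
  multi-timescale Ornstein-Uhlenbeck keypoint traces, planted-encoder
  neural populations with known explainable variance, HMM-sampled
  sequences) so every component can be exercised end-to-end with known
  ground truth and no external downloads.

The core model relating behavior to activity is the variance-explained
ledger: for each neuron, test-set `VE = 1 - SSE/SST` from a model, divided
by the explainable variance `EV` estimated by predicting the neuron from a
spatially disjoint peer population — `VE/EV` is the fraction of the
explainable signal the model captures.

## Worked example

```r
library(facekit)

## 1. simulate a 5-state behavioral HMM and refit it from scratch
syn <- synthHmmSequence(K = 5, n = 16, T = 20000, selfP = 0.9,
                        forwardBias = 0.3, sep = 1.5, seed = 11)
split <- makeSplit(20000, rate = 1, gapSec = 0)
fit <- hmmFit(syn$z[split@trainIdx, ], K = 5, seed = 2)
fit$model
#> HmmModel: 5 states, 16 feature dimensions, sigma2 = 0.0625
#>   mean self-transition: 0.8831
round(hmmLogLik(fit$model, syn$z[split@testIdx, ]) / length(split@testIdx), 2)
#> [1] -194.18

## 2. state-dynamics statistics from the fitted transition matrix
nt <- normalizeTransitions(fit$model)
round(median(nt$lifetimes), 2)
#> [1] 2.13
st <- transitionStats(nt$B)
round(c(reverse = st$reverse, baseline = st$baseline), 3)
#>  reverse baseline
#>     0.25     0.25
```

The fitted self-transitions (0.88 on average, close to the planted 0.9)
give a median state lifetime of 2.13 timesteps on the `-log(1 - p)`
scale, and with the planted forward bias of 0.3 the reverse-transition
probability sits at the off-diagonal baseline, as expected for a weakly
cyclic chain.

```r
## 3. QC on keypoint traces with planted 100 px teleports
tr <- synthKeypointTraces(5000, rate = 50, seed = 8)
co <- coords(tr)
set.seed(9); bad <- sample(10:4990, 10)
co[bad, 2, 1] <- co[bad, 2, 1] + 100
res <- filterKeypoints(keypointSeries(co, rate = 50, schema = schema(tr)))
res$series
#> KeypointSeries: 5000 frames x 13 bodyparts @ 50 Hz
#>   flagged outliers: 20 (0.031% of samples)
```

The jump rule flags the teleport frame and the return step (two flags per
planted artifact: 20 flags for 10 teleports), and the flagged samples are
replaced by interpolation of the median-filtered trace.

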