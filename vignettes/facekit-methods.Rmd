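---
title: "Models and methods in facekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in facekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(facekit)
```

facekit is a toolkit for quantifying mouse orofacial behavior from videos
and for modeling how that behavior drives large-scale neural activity. This
vignette explains the models the package implements, the parameters that
matter, the design decisions taken where a choice was genuinely open, and
what the synthetic fixtures used throughout the test suite do and do not
establish about real data.

## The keypoint tracker

### Model

The tracker is a compact U-Net-style convolutional network. A grayscale
square frame (nominally 256 x 256 px, percentile-normalized so the 1st
percentile maps to 0 and the 99th to 1) passes through three stride-2
downsampling levels with 3 x 3 convolutions and ReLU activations, a
bottleneck, and one nearest-neighbour upsampling step with a skip
connection back to the quarter-resolution level. Two 1 x 1 heads emit, at
1/4 of the input resolution,

* per-keypoint **heatmaps** (sigmoid per cell), read as the probability
  that the keypoint lies in that cell, and
* **location-refinement maps**: the x and y offsets, in full-image pixels,
  from each cell's full-resolution center to the keypoint.

Decoding takes the heatmap argmax cell (ties broken toward the first cell
in row-major order, for determinism), adds the refinement offsets read at
that cell, and reports the heatmap peak value as the prediction
*likelihood*. Coordinates are 0-based pixel centers, x = column, y = row,
origin top-left; heatmap cell j has its full-resolution center at
`j * downsample_factor`. With exact refinement targets this decoding is
lossless, which the tests verify as a sub-0.5 px encode/decode round trip.

### Training

Targets for a labeled frame are Gaussian bumps (peak exactly 1, width
`heatmap_sigma = 2` cells - about the downsampling scale) plus the exact
offset maps. The loss is binary cross-entropy on the heatmaps plus a
smooth-L1 penalty on the refinement maps evaluated only near the target
cell; frames with a missing keypoint label (NaN) contribute nothing for
that keypoint. This loss family is standard for heatmap-plus-refinement
heads; the publication this design follows does not state its loss, so the
choice is ours. The refinement term is weighted by 0.02 so both terms have
comparable magnitude at the default target widths.

Optimization is Adam with base learning rate 4e-4, batch size 8, zero
weight decay, for 36 epochs: the rate is held for 30 epochs, divided by 10
for 3, and by 25 for the final 3. Fine-tuning on a handful of refined
frames uses the same loop with learning rate 1e-4 and weight decay 1e-3.
Augmentations are a random crop (scale 0.8-1.0) with resize back to the
input size, a contrast gain in 0.7-1.3, and a horizontal flip with
probability 0.5 *only when* a left/right keypoint pair map is supplied,
since flipping without relabeling mirrored bodyparts corrupts the labels.
All randomness flows through R's RNG, so a fixed seed makes training
bit-reproducible.

The convolutional widths default to (16, 32, 64, 128) but are
configurable; the tests use 64 px inputs with widths (8, 12, 16, 24) so a
full training run on a rendered toy-face video converges in a few minutes
on one CPU while still reaching sub-2 px test error.

## Keypoint trace quality control

Tracker outputs occasionally fail (occlusion, grooming). Three rules flag
samples:

* **likelihood rule** - the likelihood trace is baselined with a Gaussian
  filter of s.d. 4 s (reflective padding at the edges, which the source
  does not specify); samples more than 8 residual standard deviations
  *below* baseline are outliers;
* **jump rule** - a Euclidean step of more than 25 px from the previous
  frame ("moved more than 25 pixels" is read as a 2-D step length);
* **deviation rule** - either coordinate more than 25 px from its
  1 s median-filtered trace (applied per axis, then OR-ed, since this rule
  is defined per trace).

Flagged samples are replaced by linear interpolation of a 300 ms
median-filtered trace computed over the non-flagged samples only;
non-flagged samples are never modified. Median windows are rounded to the
nearest odd frame count. Note that a one-frame teleport makes *two* steps
exceed the jump threshold (arrival and return), so the artifact frame and
its successor are both flagged; the detection metrics in the tests count a
flag within one frame of a planted artifact as a true positive for this
reason.

## Predictability timescales of keypoints

How far into the future is each keypoint predictable? All keypoint
coordinates are convolved with ten causal exponential kernels
(`exp(-t/tau)`, unit sum, timescales log-spaced from 40 ms to 5 s; the
count is our choice, the range is prescribed), and a joint multi-output
ridge regression maps the features at time t to all coordinates at
t + lag, separately per lag. The split is ten equal segments, first 75%
train, a 2.6 s exclusion gap, remainder test. The ridge penalty (1e-4 per
sample on standardized features) only stabilizes the collinear basis. A
joint fit over all coordinates is used; the alternative (one fit per
keypoint) is statistically equivalent for least squares and slower.

The reported timescale is the first lag at which test variance explained
falls to half its value at the 20 ms lag (linear interpolation between lag
grid points; `Inf` if never reached). For an Ornstein-Uhlenbeck process
with timescale tau the optimal predictor gives `VE(lag) =
exp(-2 lag / tau)`, so the half-decay has the closed form
`0.02 + tau * log(2) / 2` seconds - the oracle the tests check against.
Test runs use a thinned lag grid and a training-row stride of 3 (training
rows are strongly autocorrelated, so striding costs little accuracy);
problem sizes are stated in the test code.

## Behavior-to-neural encoding

### Variance accounting

All predictions are scored with `VE = 1 - SSE / SST` on held-out test
frames, where SST is the sum of squared deviations of the test trace from
its own mean. The source formula for single-neuron variance explained
mixes a quadratic-form numerator with a variance denominator; reading the
denominator as a sum of squares makes a constant mean prediction score
exactly 0 and a perfect prediction 1 (ordinary R-squared), which is the
only internally consistent choice and is what we implement. Zero-variance
neurons are excluded. The cumulative VE across neural PCs accumulates
per-PC explained variance, normalized by the total over all PCs.

Because single neurons contain unexplainable independent noise, model VE
is normalized by the **explainable variance** (EV) from peer prediction:
the field of view is cut into 200-um-wide strips by x position, neurons in
even strips form one group and odd strips the other, the top k PCs of each
group predict the other group's PCs by reduced-rank regression
(lambda = 0.1, rank k-1), predictions are projected back to neurons, and
each neuron's EV is its VE under this peer model. Neuron-level normalized
VE is reported only where EV > 1e-3; the population-level figure is mean
VE divided by mean EV. EV estimated this way is biased slightly downward
at short recording lengths (regression shrinkage); the calibration checks
therefore run on a one-hour synthetic fixture, where the bias is well
inside the tolerance. Strongly spatially compact subpopulations would also
bias EV low - a cluster confined to one strip parity is invisible to its
peers - so calibration fixtures use spatially diffuse populations.

### Reduced-rank regression

The linear baseline is `Y = X B A'` with rank r: a ridge solution (lambda
added to the input Gram matrix) followed by projection of the fitted
values onto their top r principal directions (the classical closed-form
construction). At full rank and vanishing lambda this equals ordinary
least squares, which is tested to 1e-6. Rank 21 is used when predicting
from the 22 keypoint coordinates and lambda 1e-6 for the behavior
regression, as published.

### The deep encoder

The five-layer core: a pure linear layer (inputs to inputs, no bias - the
source leaves this layer's details open), a temporal convolution with 10
filters (centered, zero-padded; kernel 51 behavior frames by default,
about 1 s at 50 Hz), a ReLU, and two fully-connected ReLU layers of widths
50 and 256. The 256-dimensional output is the **deep behavioral
features**; a linear readout maps them, subsampled at the nearest behavior
frame at or before each neural frame (a causal alignment), to the 128
neural PCs - or directly to neurons when fewer than 200 are predicted.

Training is AdamW (learning rate 1e-1, weight decay 1e-4, 300 epochs,
annealed by 10x at 2/3 and 5/6 of training), each batch being one training
segment. With fewer than 2,000 target neurons the learning rate and weight
decay are divided by 10; with under one hour of training data they are
halved and 100 epochs are dropped. Two numerical choices of ours matter in
practice: targets are internally rescaled by the leading PC's standard
deviation (a constant factor on the loss; predictions are mapped back), so
the readout weights live at order 1 and remain reachable within the Adam
step budget; and the readout is zero-initialized, so the first steps fit
the readout before any error signal reaches the core, which prevents early
ReLU collapse at high learning rates. Backpropagation is hand-derived and
verified against numerical gradients; the per-timepoint layers are only
evaluated at the rows the loss needs, which makes CPU training of the
synthetic fixtures take tens of seconds rather than hours.

## Clustering and the locality index

Scaled k-means models each neuron as a scalar gain times its cluster's
temporal pattern. Alternating updates (gain by least squares given the
pattern, assignment by residual, pattern by gain-weighted average) are run
to an assignment fixpoint with a k-means++-style seeding on normalized
activity; empty clusters are reseeded from the worst-fit neuron, and the
objective is non-increasing by construction. Gains are unconstrained in
sign (z-scored activity can anti-correlate with its cluster); each
pattern's sign is fixed by making the majority of member gains positive.
At k = 1 the procedure is alternating least squares for a rank-1 fit and
reproduces the SVD solution, which is used as an oracle.

The locality index of a cluster is the KL divergence between its
discretized spatial distribution and that of all neurons, in 200-um square
bins anchored at the data bounding box. A pseudocount of 0.5 is added to
every background bin before normalizing, so the divergence is defined
wherever the cluster has members. A cluster drawn uniformly from the
population scores near 0; a cluster confined to one bin against a uniform
background scores near log of the bin count, up to the closed-form
pseudocount correction the tests compute exactly.

## The discrete behavioral HMM

States evolve with transition matrix `A = softmax(Q)` row-wise; the
log-transition parameterization removes the positivity and row-sum
constraints. Emissions are isotropic Gaussians around per-state means with
a **fixed** variance chosen proportional to the summed feature variance
(1 for 256-dimensional deep features, n/256 after per-column
standardization in general), so the observation term carries comparable
weight across feature spaces of different dimensionality; the variance is
never learned. The emission density is the standard normalized Gaussian -
the printed recursion's constant term appears typographic, and likelihood
comparisons only require consistency between fitting and evaluation.

The exact log-likelihood is computed by the log-space forward recursion
with logsumexp over predecessor states, stable for sequences of 1e5 steps.
Fitting ascends this likelihood directly with Adam (learning rate 0.05,
400 iterations, full-sequence gradients); the gradient is analytic - by
Fisher's identity it is the forward-backward posterior statistics
(expected transition counts for Q through the softmax chain rule, expected
occupancies for the means and initial logits) - which is exactly what
automatic differentiation of the forward recursion would produce.
Initialization: `Q_ii = 3`, 0 off-diagonal; emission means at random data
samples; uniform initial logits. Random-sample emission inits occasionally
land in a local optimum that splits one true state and merges two others;
an optional restart scheme reruns the fit from fresh initializations and
keeps the best training likelihood (the bad optima are clearly worse), and
the parameter-recovery experiments use three restarts. A Baum-Welch EM baseline with the same
initialization and fixed variance is provided; on the synthetic fixtures
gradient ascent matches or beats its held-out likelihood. Viterbi decoding
uses the max-product recursion with ties broken toward the lowest state
index, and uses the initial distribution b at t = 1.

### Transition-structure statistics

From the fitted A: state lifetimes `-log(1 - A_ii)`; the off-diagonal
matrix B (self-transitions zeroed, rows renormalized; absorbing rows
flagged and zeroed); a state order maximizing similarity of the reordered
B to `F_ji = -log((i - j)^2)` above the diagonal (exhaustive enumeration
for K <= 8, otherwise greedy insertion plus pairwise-swap hill climbing
with O(K) move evaluation over seeded restarts); cumulative transition
probability to the n most probable successors; and, for each "near" pair
(the 5 most probable successors per state), the reverse probability, the
two-step forward probability (maximum over intermediate states of
`B_jk B_ki` - the source describes this only schematically) and its
backward analog, against the mean off-diagonal baseline. Forward sequences
are maximal strictly increasing runs in the reordered, duplicate-collapsed
Viterbi path. Deep features are downsampled from 50 to 5 Hz by striding
before HMM fitting, as published.

## Synthetic fixtures: what they emulate, and what they do not

Every generator is seed-deterministic and returns ground truth alongside
data.

* **Keypoint traces** are Ornstein-Uhlenbeck processes with
  group-specific timescales (eye 5 s, nose and whiskers 0.5 s) plus a
  ~10 Hz whisker oscillation with diffusing phase. OU processes have
  closed-form autocorrelation, giving exact targets for the timescale
  estimator.
* **Face videos** render each keypoint as a Gaussian blob on a smooth
  background, with evenly spaced widths and amplitude magnitudes
  (alternating bright/dark) so every keypoint is identifiable by
  appearance, and with each keypoint confined to its own grid cell by
  reflection - as with real anatomy, landmarks never swap places, and two
  same-polarity blobs can never merge into an unresolvable compound.
  Appearance or position shifts produce domain-shift fixtures for the
  fine-tuning experiments.
* **Planted neural populations**: latent signals are a planted
  random network of the keypoint coordinates - by default of the *slow eye
  group only*, emulating arousal-like state variables, which is also why
  deep features fit to these populations inherit slow dynamics. Each
  latent mixes a linear readout with an even-symmetric part built from
  paired +/-ReLU units (`|u| = relu(u) + relu(-u)`); the even part is
  uncorrelated with every linear function of the inputs, so a linear
  decoder can recover at most the linear half while a nonlinear encoder
  can also capture the rest - this is what makes the deep-versus-linear
  comparison a sharp test of nonlinearity rather than of optimizer luck.
  Latents are averaged over each 300 ms neural bin (as calcium imaging
  integrates), and each neuron adds a shared non-behavioral latent and
  independent Gaussian noise with unit-variance components, so the
  explainable variance and its behavioral part are known exactly per
  neuron. Default fractions are 0.6 behavior / 0.1 shared / 0.3 noise
  across 400 neurons - a deliberately high signal-to-noise regime chosen
  so that 30-minute desk-scale fits are informative; real recordings have
  far lower per-neuron EV and compensate with hours of data and tens of
  thousands of neurons.
* **HMM sequences** use a transition matrix with controllable
  self-transition probability and a forward-cycle bias interpolating
  between a statistically symmetric chain and a pure cycle.

Passing tests on these fixtures show that the algorithms are implemented
correctly and behave as designed where ground truth is known. They do not
show that a 30-minute, 400-neuron synthetic fit attains the accuracy of
the published multi-hour, 50,000-neuron recordings, and the fixtures make
no attempt to emulate photorealistic appearance, calcium-indicator
dynamics, or deconvolution artifacts.

## Known limitations

* CPU-only: the networks are small by design; there is no GPU path.
* The movie-PC input to the encoder is a plain truncated SVD of flattened
  frames; the blockwise video-SVD algorithm of prior work is out of scope.
* Keypoint files are supported as long-format CSV (and neural data as
  CSV triplets); binary container formats are not read.
* The deep encoder trained at desk scale retains a residue of its random
  initialization in the feature layer; its state dynamics are therefore a
  conservative version of what long training on large recordings yields.
* HMM state count selection is deliberately out of scope; K is a user
  choice (50 in typical use).
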