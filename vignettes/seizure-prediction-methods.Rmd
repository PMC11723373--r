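---
title: "Methods: spectral-image seizure prediction with a contractive spike-and-slab convolutional DBN"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: spectral-image seizure prediction with a contractive spike-and-slab convolutional DBN}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(seizcast)
```

## The problem and the model

Scalp EEG in epilepsy moves through distinguishable regimes: the baseline
*interictal* state, the *preictal* hour before a seizure onset, and the
*ictal* (seizure) period itself. Predicting a seizure means recognizing the
preictal state early; detecting one means separating all four stages
(interictal, the earlier and later halves of the preictal hour — PreI and
PreII — and ictal). seizcast implements a full pipeline for both tasks:

1. **Spectral imaging.** Multichannel EEG (23 bipolar channels at 256 Hz)
   is cut into non-overlapping 2-second windows. Each window is Fourier
   transformed per channel, low-passed at 30 Hz, and summarized by band
   power in theta (4–7 Hz), alpha (8–13 Hz) and beta (13–30 Hz). Each
   band's 23 channel powers are placed on a 5×5 scalp grid (a bundled
   layout table maps the standard bipolar montage to grid cells, so spatial
   adjacency on the scalp is preserved) and interpolated to 64×64 pixels,
   giving one 3×64×64 image per window.
2. **Normalization and ZCA whitening** fitted on the training split.
3. **A contractive spike-and-slab convolutional RBM (CssCRBM)** per layer,
   trained greedily by contrastive divergence and stacked into a deep
   belief network.
4. **A transformer-encoder attention head** over tokens taken from the
   final hybrid feature maps, with a linear softmax classifier.
5. **Dual-task fine-tuning**: classification cross-entropy plus a Siamese
   contrastive verification loss that pulls same-class feature vectors
   together and pushes different-class ones at least a margin apart.

## The CssCRBM

The layer couples real-valued visible maps $v$ (L channels) to K feature
maps of binary *spike* units $h$ and continuous *slab* units $s$ through
shared convolution kernels $w$:

$$E(v,s,h) = -\sum_{l,k,ij}(v^l \ast w^{l,k})_{ij} h^k_{ij} s^k_{ij}
             -\sum_k b^k \sum_{ij} h^k_{ij}
             +\sum_{l,mn}\frac{(v^l_{mn}-c^l)^2}{2\sigma^2}
             +\frac12\sum_{k,ij} a^k (s^k_{ij})^2 .$$

The spike gates whether a feature is present; the slab carries its
magnitude; their product $h\odot s$ is the layer's hybrid feature map.
The conditionals are exact and closed-form: spikes are logistic in
$z = C^2/(2a) + b$ where $C$ is the convolutional response (note the
*squared* response — the activation is sign-invariant and responds to
oriented energy), slabs are Gaussian with mean $Ch/a$ and variance $1/a$,
and visible units are Gaussian around the transposed convolution of
$h \odot s$.

**Dual-variable probabilistic max-pooling** constrains each non-overlapping
pool×pool block of a spike map to at most one active unit. The block-level
conditional is a categorical distribution over block positions plus an
"off" state; the pooled spike indicates whether any unit fired, the pooled
slab is Gaussian around the maximum of the block's slab means, and the
pooled output is their elementwise product. `enumerate_spike_conditional()`
verifies these closed forms against brute-force enumeration (with slabs
integrated analytically) on tiny models; the package's test suite pins them
to 1e-8.

When `pool` does not divide the detection grid the trailing remainder is
dropped (floor division). That convention is what reproduces the
configured stack's spatial chain 64 → 31 → 15 → 7 → 3 on 3×64×64 input.

## Training by contrastive divergence

`cd_update()` runs CD-k (default k = 5): alternating Gibbs sweeps
v → (h, s) → v, with the likelihood gradient estimated as the difference of
data-phase and model-phase expected energy gradients. Both phases use
expected sufficient statistics (spike probabilities and conditional slab
means) rather than raw samples at their endpoints, which lowers estimator
variance without changing the estimand; intermediate sweeps are sampled.
The exact-enumeration gradient on tiny models (`exact_nll_grad()`) is the
reference: averaged CD estimates sign-agree with it on essentially all
parameters.

Three numerical choices matter in practice and are deliberate:

* **Per-unit gradient normalization.** Energy gradients sum over all
  contributing units (all hidden positions for a shared kernel, all pixels
  for the visible bias). Updates divide by those counts; otherwise the
  visible-bias step is effectively multiplied by the image area and
  oscillates divergently at any useful learning rate.
* **Kernel-norm projection** (`max_w_norm`, default 0.3 per feature map).
  The spike-and-slab joint density is normalizable only while the slab
  precision dominates the visible–slab coupling; past that point the Gibbs
  reconstruction gain exceeds one and the chain diverges exponentially.
  Projection after each update keeps training inside the proper region.
* **Slab precision `a` is learned in log-space** (positivity), the noise
  scale `sigma` is fixed at 1 after input standardization, and a per-map
  (broadcast) `a` is the default — the full per-unit tensor is supported
  but rarely warranted under convolutional weight sharing.

The **contractive penalty** is the squared Frobenius norm of the Jacobian
of the spike activation probabilities with respect to the visible input.
For this activation it reduces to
$\sum_k \lVert w_k\rVert_F^2 \sum_{ij} (\sigma'(z_{ij}) C_{ij}/a)^2$,
applied to the kernels only, with per-layer coefficients 0.1, 0.1, 0.2,
0.2 (bottom to top) in the default stack. Its analytic gradient is checked
against finite differences at 1e-4.

An optional sparsity drive (`sparsity_target`) nudges each map's mean
activation toward a target, the usual convolutional-DBN facility; it is
off by default.

## Stacking and the fine-tuning forward pass

`pretrain_stack()` trains layers bottom-up, feeding each layer's
deterministic pooled hybrid maps to the next. Two bridges connect the
generative parameters to the discriminative forward pass:

* each layer's training input is standardized to unit scale for CD (the
  Gaussian visible units assume unit noise) and the scale is absorbed into
  the kernels afterwards, so the assembled stack operates on raw inputs;
* after CD, each map's spike bias is shifted so the median spike
  pre-activation over training data is zero. CD's sparse bias start
  (b = −1) keeps logistic activations low, which is fine generatively, but
  the fine-tuning forward replaces the logistic with a relu — without the
  shift every relu is dead and no gradient flows.

The fine-tuned network is a special CNN: spikes $h = \mathrm{relu}(z)$,
slabs $s = (C h + \varepsilon)/a$, hybrid maps $h \odot s$, block-max
pooling. The model's stated fine-tuning rule includes an additive noise term
$\varepsilon \sim N(0,1)$ scaled by $1/a$; the package exposes it
(`forward_deterministic(mode = "train")`, with `noise_scale` switching to
the probabilistic conditional's $1/\sqrt{a}$), but `finetune()` optimizes
the *deterministic* pass by default. The reason is practical and
reproducible at small scale: with whitened inputs the noise (sd ≈ 1)
dominates the hybrid signal through max-pooling, so a classifier trained on
noisy passes does not transfer to the noise-free pass used at prediction
time — training accuracy is high while held-out sensitivity collapses.
Training the same function that is evaluated removes the mismatch.

## Attention head and dual-task objective

Each spatial position of the final hybrid map becomes a token (row-major;
9 tokens of width 128 in the default stack) plus a learned positional
embedding. One pre-norm transformer-encoder block follows: single-head
scaled dot-product self-attention with softmax row normalization, then a
two-layer perceptron, each with a residual connection. With all transform
weights zero the head is exactly the identity on tokens. The classifier
mean-pools tokens through a linear softmax layer. A raw (softmax-free)
attention variant is available for ablation (`norm = "none"`), since
softmax is the only fully specified and numerically stable choice for the
default.

Fine-tuning minimizes, per minibatch of 20 images split into 10 pairs,

$$\mathcal{L} = \frac{1}{|P|}\sum_{(i,j)\in P}
  \big[\ell_{\mathrm{CE}}(i) + \ell_{\mathrm{CE}}(j)
  + c_{\mathrm{ver}}\,\ell_{\mathrm{ver}}(i,j)\big],$$

with $c_{\mathrm{ver}} = 0.11$ and the contrastive verification loss
$\tfrac12 D^2$ for same-class pairs and $\tfrac12\max(0, \delta - D)^2$
otherwise. $D$ is the Euclidean distance between L2-normalized pooled token
representations, which makes the margin scale-free; $\delta = 1$ by
default (the margin value is otherwise unconstrained). The mean over pairs
(rather than the bare sum) only rescales the learning rate and keeps it
comparable across batch sizes. Both Siamese branches are literally the same
parameter set. Optimization is Adam (lr 0.01, β = 0.9/0.999, ε = 1e-8);
all of backpropagation through pooling, the stack nonlinearities, layer
normalization and attention is hand-derived and pinned to finite
differences in the tests. The categorical cross-entropy generalizes the
binary main loss exactly at two classes, which the four-class detection
task needs.

## Evaluation

Binary prediction uses sensitivity TP/(TP+FN) and the false-positive rate.
The per-sample FPR is FP/(TN+FP); the reported per-hour rate counts
false-alarm *events* — consecutive positive interictal samples within a
2-minute refractory window merge into one event — divided by monitored
interictal hours. (A per-sample ratio cannot exceed 1 and does not have
per-hour units; the event-rate reading is the only one consistent with
alarm-rate reporting.) An onset counts as predicted iff at least one of its
preictal samples is classified positive; the prediction time is the span
from the first positive sample to the onset, undefined (and excluded from
means, flagged in the report) for missed events. Cross-validation uses
stratified folds; preictal samples of one seizure event are kept within a
fold (leakage guard).

## The synthetic generator

`gen_eeg()` synthesizes multichannel EEG in the frequency domain: a 1/f
Gaussian background (exponent 1.0, synthesized up to 45 Hz — everything
above the 30 Hz analysis low-pass is irrelevant downstream) plus
band-limited oscillation components in theta/alpha/beta whose power is a
per-class multiple of the in-band background power (`band_strength` 1.5 at
gain 1; background RMS 30 µV). Class gains default to interictal (1,1,1),
preictal (3,2,1.5) and ictal (4,1.5,2); the ictal class additionally
carries 3–5 Hz rhythmic bursts (narrowband noise at 3× background RMS,
5 s on / 3 s off with smooth half-second shoulders so burst energy stays in
band at analysis time). For the four-class task the preictal record's band
gains ramp linearly from interictal levels to the full preictal signature
over the 60-minute window, which is what makes PreI and PreII separable in
principle and hard in practice. Everything is seed-deterministic, with
per-patient, per-record sub-seeds.

Cohorts mirror the two study designs: per patient, 180 min preictal (three
60-minute event windows) plus 180 min interictal for prediction — 10,800
two-second images per patient, 108,000 for ten patients — and 30 min per
class for detection (9,000 images per class over ten patients). These are
exactly the counts the construction arithmetic implies, and the test suite
reproduces them at full scale. What passing on synthetic data does *not*
show: robustness to artifacts, electrode drift, inter-patient variability
beyond seeded gain differences, or genuinely non-stationary seizure
morphology — the generator makes classes separable by band-power design,
so end-to-end results certify the pipeline's mechanics, not clinical
performance.

## Numerical and design notes

* Grid-to-image interpolation uses natural cubic splines (exact at knots,
  exact for constant and linear fields). A clamped convolution kernel
  would distort linear ramps at the image border, which the interpolation
  contract here forbids.
* ZCA whitening is stored in thin eigenbasis form (the 12,288-dimensional
  pixel covariance is never materialized); eigenvalues are regularized by
  `epsilon` (default 1e-5). With fewer fitting images than pixels the
  covariance is rank-deficient; directions outside its span pass through
  unscaled rather than being multiplied by $\varepsilon^{-1/2}$, which
  would amplify out-of-span components of new data by ~300×.
* The tiny-model oracle rescales kernels when a random draw would make the
  joint density unnormalizable (the exact integrals require a positive
  definite joint precision).
* Filter-recovery experiments (two orthogonal 3×3 generators, K = 2) use
  images that each carry sparse activations of a *single* generator at
  amplitudes well above the noise floor. When both generators are
  superimposed weakly in every image, the squared-response model recovers
  the correct two-dimensional filter *subspace* but individual kernels may
  be rotated mixtures (absolute cosine ≈ 0.7) — the usual identifiability
  limit of covariance-style models without a strong sparsity cue.
* Reduced problem sizes used by the checks, chosen as the package's own
  test design: tiny oracles at 3×3 visible/2×2 kernels; filter recovery at
  200 12×12 images × 40 epochs × 5 seeds; the end-to-end synthetic run at
  200 images, one 8-kernel layer (pool 8), 3 CD epochs and 10 fine-tuning
  epochs with a 30% held-out split. The full-scale dataset-count checks use
  the complete ten-patient cohorts.

## Known limitations

* CD-k with a shallow chain is a biased likelihood estimator; no persistent
  chains or tempering are provided (out of scope).
* The four-layer default stack is sized for the full 108,000-image setting;
  at reduced scale a one-layer stack both trains faster and generalizes
  better, which is what the bundled pipeline uses.
* PreI/PreII confusion is intrinsic: adjacent 30-minute halves of a ramped
  preictal hour differ only in degree.
* Only the verification auxiliary task contributes to the objective; the
  configuration constant c_ide = 0.07 associated with an identification
  auxiliary task in related setups is recorded for completeness and unused.
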