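---
title: "Detecting pulse from short ECG segments: models and methods"
author: "pulsegate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting pulse from short ECG segments: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pulsegate)
```

## The problem

During out-of-hospital cardiac arrest, rescuers must repeatedly decide
whether the patient has regained a pulse. Manual pulse checks are slow and
unreliable, and the one signal every defibrillator records through its pads
is the ECG. The hard case is separating two *organized* rhythms that can
look superficially similar: pulse-generating rhythm (PR), where electrical
activity drives effective contraction, and pulseless electrical activity
(PEA), where it does not. Clinically, PR tends to show faster rates,
narrower QRS complexes and less beat-to-beat variability than PEA.

`pulsegate` classifies 5-s single-lead ECG segments into PR vs PEA with two
compact neural networks, and surrounds them with the full workflow needed
to use and assess such a classifier: preprocessing, patient-equalized
training, Monte-Carlo-dropout uncertainty gating, classical
feature-engineering baselines, Bayesian hyper-parameter search, and
patient-weighted evaluation. Clinical OHCA recordings are not
redistributable, so the package ships a synthetic generator that reproduces
the *structure* of such data; all quantitative results in the test suite
are statements about this synthetic family, not about clinical data.

## Preprocessing

Raw segments are sampled at 250 Hz in mV. The network input `s[n]` is
obtained by:

1. **Band-pass 0.5–30 Hz** — the usual AED analysis bandwidth. The band is
   the specification; the realization is a design choice: a 4th-order
   Butterworth (2nd-order design run forward–backward with `filtfilt`),
   chosen because zero-phase filtering leaves QRS morphology undistorted.
2. **Resampling to 100 Hz** by rational polyphase resampling (upsample 2,
   FIR anti-alias low-pass, downsample 5). The FIR is a 100-tap windowed
   design with DC gain normalized exactly; edge transients are suppressed
   by edge-sample replication. A 5-s segment thus becomes N = 500 samples.
3. Optional **truncation** keeps the *first* `floor(seconds * 100)`
   samples, used when probing how short a segment the models can handle
   (2–5 s).

## The two architectures

**S1 (fully convolutional).** λ blocks of (valid temporal convolution with
M kernels of length L → max-pooling with K = 2 → dropout α), then global
max pooling over time, then a single sigmoid unit giving
`p_PR ∈ (0, 1)`. Valid convolution means an input of N samples leaves
N − L + 1; pooling halves it (odd remainders dropped, consistent with the
pooling index running to ⌊N/K⌋).

**S2 (convolutional–recurrent).** The same convolutional stack, but the
global pooling is replaced by a bidirectional GRU with ϑ units per
direction:

- update gate `z_n = σ(W_z d_n + U_z h_{n−1} + b_z)`
- reset gate  `r_n = σ(W_r d_n + U_r h_{n−1} + b_r)`
- candidate   `h'_n = tanh(W d_n + r_n ⊙ (U h_{n−1}) + b)`
- state       `h_n = z_n ⊙ h_{n−1} + (1 − z_n) ⊙ h'_n`

The final states of the forward and time-reversed passes are concatenated
(2ϑ features), passed through one more dropout layer, then the sigmoid
unit. A recurrent-dropout fraction of 0.15 is applied to the recurrent
state inside the gates during training.

Two bookkeeping conventions are deliberate and pinned by tests: one bias
per convolution kernel (not per tap), and one bias vector per GRU gate
(not separate input/recurrent biases). These are the standard conventions
and the only ones that reproduce the reference parameter totals of 1441
(S1 with λ=4, M=8, L=7) and 4777 (S2 with λ=2, M=24, L=6, ϑ=6), which
`countParameters()` verifies both in closed form and by enumerating the
built model's arrays.

Because convolution and pooling only shorten the time axis and the GRU
walks whatever length it receives, a trained model accepts any input of at
least `minLength(model)` samples — the property the duration sweep relies
on. The decision threshold on `p_PR` is 0.5.

## Training recipe

`trainModel()` implements ADAM (learning rate 0.001, decay rates 0.9 and
0.999, ε = 1e-8) on the patient-weighted binary cross-entropy

L(p) = − Σᵢ ηᵢ [ yᵢ ln pᵢ + (1 − yᵢ) ln(1 − pᵢ) ],

with mini-batches of 8 for 75 epochs and epoch-level shuffling. The weights
ηᵢ equalize patients: each segment of a patient with k segments gets 1/k,
so the weights of one patient sum to 1 and the total equals the number of
patients. We write the loss in its negated, uniformly weighted form — a
cost to *minimize*, with η applied to both label terms — since per-patient
equalization of the whole per-sample term is the stated intent of the
weighting. Probabilities are clamped to [1e-7, 1 − 1e-7] before the
logarithms.

Each mini-batch is augmented on the fly: amplitudes scaled by a fresh
uniform factor in [0.98, 1.02] per segment, plus i.i.d. Gaussian noise with
SD 1e-4. After every optimizer step, constrained weight vectors are
projected onto the ball ‖w‖ ≤ γ = 3.5: convolution kernels column-wise,
and (for S2) each per-unit gate vector of the GRU input and recurrent
matrices. The dense output unit is left unconstrained. The last short
mini-batch is used rather than dropped; there is no early stopping or
schedule. All stochasticity (shuffling, augmentation, dropout) is driven by
one seeded stream, so training is bit-reproducible.

No deep-learning framework is involved: the forward passes, backpropagation
(including BPTT through the bidirectional GRU) and ADAM are implemented in
the package and verified against loop-based evaluations of the layer
equations and against numerical gradients.

## Uncertainty and selective prediction

`mcPredict()` repeats the forward pass N = 100 times with dropout left
active and fresh white noise (SD 1e-4, the training augmentation scale —
the test-time amplitude is not separately specified, so the training value
is reused; amplitude jitter is *not* applied at test time) added to the
input. The mean of the N likelihoods is the prediction; their population
(1/n) variance is the uncertainty. A feedback policy is calibrated on
training data: the threshold is the nearest-rank quantile of training
uncertainties at the target feedback fraction, and test decisions with
uncertainty at or below it (ties retained) are emitted. An empty retained
set is reported as an explicit "no feedback" result.

## Baselines

Nine hand-crafted features summarize each segment: QRS rate from a
threshold beat detector; median QRS width at half peak; mean absolute
first difference; three band-energy fractions (0.5–4, 4–12, 12–30 Hz);
fuzzy entropy (m = 2, r = 0.2·SD, Gaussian membership on locally demeaned
templates); and two RR-regularity measures (CV and normalized RMSSD). The
allocation of slots across the named domains, and each formula, is a
standard-definition reimplementation documented in `extractFeatures()`;
flat signals get defined fallbacks instead of errors. The classifiers are
a 300-tree random forest (resample fraction φ, ψ features per node), an
RBF-kernel SVM (cost C, width γs per `K(v, vᵢ) = exp(−γs‖v − vᵢ‖²)`), and
kernel logistic regression solved by penalized IRLS (ridge weight λl on
aᵀKa, tolerance 1e-8, ≤ 100 iterations). Kernel-based fits standardize
features with training-set statistics. The same classifiers also accept the
networks' learned feature vectors (`dnnFeatures()`: M values from S1's
global pooling, 2ϑ from S2's BGRU).

## Hyper-parameter optimization

`tuneModel()` minimizes the 4-fold patient-wise cross-validated balanced
error rate. Folds assign whole patients, stratified by patient label, with
sizes differing by at most one. Two surrogate strategies are provided:
a tree-structured Parzen estimator (used for S1/S2; quantile split at 25%,
Gaussian/categorical Parzen mixtures with a width floor of 5% of the range,
24 candidates per trial scored by the good/bad density ratio) and a
Gaussian-process surrogate with expected improvement (used for RF/SVM/KLR;
RBF kernel on the unit cube, lengthscale 0.25, nugget 1e-4, 256 uniform
candidates, Latin-hypercube start). The number of trials defaults to 50 —
the reference method prescribes only the strategy, not an iteration count.
Search spaces follow the reference table (S1: λ∈1..5, M∈{8,16,24}, L∈5..8,
α∼U(0.05,0.5); S2 adds ϑ∈4..8; RF: φ∼U(0.5,1), ψ∈1..9; SVM: C,γs∼U(0.001,
10⁴); KLR: λl∼U(10⁻⁴,0.2), γs∼U(10⁻⁴,15)).

## Evaluation

Sensitivity is the probability of correctly recognizing PR, specificity of
PEA, BAC their mean, BER = 1 − BAC (reported in percent). Patients are
weighted equally: per-patient class accuracies are averaged over the
patients that *have* segments of that class. In the clinical design every
patient is single-class, where this reduces to the plain per-patient
weighting; for mixed-class patients (possible in principle) the per-class
averaging is the only consistent extension, which is why it was adopted.
Metrics are undefined — and the package says so — when a class is absent
altogether.

## The synthetic generator

`generatePatient()` synthesizes a segment as a train of Gaussian-shaped
QRS pulses (width = QRS width, ±3σ support) at RR intervals jittered with a
given coefficient of variation (truncated to stay strictly positive), with
optional wide inverted ectopic beats, slow sinusoidal baseline wander (5%
of the QRS amplitude, 0.15–0.35 Hz) and white noise truncated at ±6 SD so
every sample is provably bounded by `amplitudeMv + 6 * noiseSdMv`.
`generateDataset()` draws per-patient parameters from class-conditional
priors — PR: rate U(70, 130) bpm, RR CV U(0.01, 0.05), QRS width
U(60, 100) ms, ectopy ≤ 0.05; PEA: rate U(20, 70) bpm, CV U(0.08, 0.25),
width U(120, 220) ms, ectopy ≤ 0.2; both: amplitude U(0.5, 1.5) mV, noise
SD U(0.01, 0.03) mV — and a per-patient segment count uniform in a given
range (2–6 by default). The per-segment mean rate wanders in proportion to
the patient's RR variability, twice as strongly for PEA, so PEA segments
within a patient are more variable than PR segments. These priors are
plausible clinical ranges consistent with the qualitative PR/PEA contrast;
they are stand-ins, not estimates of any study's distributions.

What the generator does **not** emulate: P and T waves, conduction
morphology, chest-compression artefacts, power-line interference, electrode
motion, or thoracic impedance. Passing tests on this family therefore shows
that the pipeline learns and evaluates correctly on patient-structured data
with the right class contrasts — it does not certify clinical performance.

## Problem sizes and numerical choices

The end-to-end checks train S1 (λ=2, M=8, L=5, α=0.1) for the full 75
epochs on 100 synthetic patients (50 PR / 50 PEA, 2–6 segments each,
roughly 400 segments) and test on 40 disjoint patients, repeated over ten
seeds; uncertainty gating uses N = 100 Monte-Carlo passes with thresholds
calibrated on the training set at feedback fractions 1.0/0.95/0.9/0.8.
These sizes were chosen as the smallest at which the class structure, the
patient weighting and the uncertainty calibration all have room to show
their intended behaviour. Realized feedback fractions are compared to their
targets as means over the ten seeds, and the accuracy-versus-feedback trend
likewise — single-seed fractions on a 40-patient test set carry a few
points of sampling noise by themselves.

Other numerical conventions collected in one place: cross-correlation
rather than flipped convolution (equivalent for learned kernels); pooling
ties broken toward the earlier sample; dropout implemented as inverted
dropout; Glorot-uniform initialization with orthogonal recurrent matrices;
sigmoid outputs clamped away from 0/1; nearest-rank quantiles for
thresholds.

## Limitations

The models are trained and validated here only on synthetic data; clinical
deployment would require the original (private) recordings or a comparable
annotated corpus. The hand-crafted features are standard-definition
reconstructions, so their absolute values are not comparable to any
specific published implementation. The optimizers implement the standard
TPE/GP-EI ideas compactly and are suitable for the tens-of-trials regime
used here, not for large parallel searches.
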