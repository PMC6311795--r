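---
title: "Glia-chain deep belief networks for EEG emotion recognition: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Glia-chain deep belief networks for EEG emotion recognition: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# Overview

`gliadbn` implements an ensemble deep-learning pipeline for classifying
binary arousal and valence states from multichannel EEG. The pipeline has
four stages:

1. **Preprocessing and feature extraction** — each trial (32 channels,
   128 Hz) is band-passed 4–45 Hz and summarised by a 664-dimensional
   multi-domain feature vector.
2. **Five parallel deep belief networks (DBNs)** — one per physiological
   feature subset — pretrained with *glia chains* modulating hidden-unit
   outputs, then fine-tuned with a two-neuron softmax head.
3. **Fusion** — the five last-hidden-layer abstractions (350 values in the
   default configuration) are concatenated and classified by a
   discriminative restricted Boltzmann machine (RBM).
4. **Evaluation** — participant-specific 10-fold cross-validation with
   accuracy and positive-class F1.

A synthetic labelled-EEG generator makes the whole stack trainable and
testable without access to gated recording datasets.

# The feature vector

For each trial the package computes, per channel: mean, variance
(population convention, configurable), zero-crossing rate of the
mean-removed signal (sign changes over $N-1$), and approximate entropy
ApEn($m=2$, $r=0.2\,\mathrm{SD}$) — subset **F1**, 128 values. Welch band
power (2 s Hann segments, 50% overlap, mean PSD over in-band bins) in
theta (4–8 Hz), slow-alpha (8–10), alpha (8–12), beta (12–30) and gamma
(30–45) gives **F2**, 160 values. Right-minus-left band-power differences
over the 14 homologous electrode pairs (theta, alpha, beta, gamma — the
four-band set, so $4 \times 14 = 56$) give **F3**. The Hilbert–Huang
spectrum — empirical mode decomposition followed by per-IMF analytic-signal
amplitude $a(t)$ and instantaneous frequency $f(t)$ — yields, per channel
and band (delta through gamma), the mean of $a(t)^2$ over samples whose
$f(t)$ falls in the band (**F4**) and the $a^2$-weighted mean frequency
(**F5**), 160 values each. The total is 664, partitioned
$(128, 160, 56, 160, 160)$.

Two deliberate conventions are worth flagging. "Average PSD" is the mean
over in-band frequency bins (not integrated band power); the two differ by
a constant bandwidth factor per band, which standardization removes anyway.
The delta-band HHS slots are retained even though preprocessing removes
content below 4 Hz; they carry whatever residual low-frequency energy the
filter leaves and keep the printed 664-wide layout intact. Relaxing the
high-pass for the HHS stage is possible in principle but is not done here,
keeping a single preprocessing path.

## Numerical choices in the HHS stage

EMD uses standard sifting: cubic-spline envelopes through local extrema, a
Cauchy-type stop criterion (relative squared change per sift below 0.2), a
cap of 10 IMFs, and a stop when the residue has fewer than two maxima or
minima or its energy falls below $10^{-8}$ of the signal's. Envelope
splines mirror the outermost extrema across both trial ends; clamping the
envelopes to the endpoint values instead was measured to inject spurious
low-frequency IMFs carrying up to 30% of the squared-amplitude mass of a
pure tone, while mirroring keeps over 99% of a tone's mass in its own band.
Instantaneous frequency is the central-difference derivative of the
unwrapped analytic phase; the first and last 5% of samples are excluded
from band averages to suppress edge effects. Approximate entropy is
computed in compiled code (Chebyshev distance, self-matches included) and
is cross-checked in the test suite against an independent R implementation.

# RBMs, glia chains and the learning rule

Each RBM layer computes hidden pre-activations
$h_j^* = \sum_i W_{ij} v_i + c_j$ and uses activation *probabilities*
$\sigma(h_j^*)$ as hidden outputs rather than Bernoulli samples, which
reduces sampling noise during greedy pretraining. The first layer treats
its visible units as Gaussian with unit variance — appropriate because
features are z-scored per subject — and layers above are binary-probability
units. Training is CD-1: hidden states are sampled once, the visible layer
is reconstructed as means, and hidden probabilities are reused; gradients
are batch means with momentum 0.5 and weight decay $10^{-4}$.

Each hidden layer is paired, during pretraining only, with a **glia
chain**: one auxiliary cell per hidden unit, linked in a line. At each
chain step, cell $j$ *fires* — its glia effect $g_j$ jumps to 1 — when
either its hidden unit's activation probability $\sigma(h_j^*)$ exceeds a
threshold $\theta$, or its predecessor on the chain fired at the previous
step; a cell that fired cannot fire again for $T$ steps (refractory
period), and silent cells decay $g_j \leftarrow \beta g_j$. While the chain
is active, hidden outputs become $\sigma(h_j^* + \alpha g_j)$, letting
locally strong activity excite neighbouring hidden units along the chain —
a mechanism for propagating correlation information across units within a
layer. Inference after pretraining always uses the plain $\sigma(h^*)$, so
trained models are pure functions of their weights.

Three semantic choices resolve ambiguities in the glia rule:

* **Threshold operand.** The firing test compares $\sigma(h_j^*)$ — a
  probability in $(0,1)$ — against $\theta$, so the standard $[0,1]$ sweep
  range for $\theta$ is meaningful. Comparing the unbounded $h_j^*$ itself
  would make most of that range degenerate.
* **Timing.** The refractory reading is used: a cell may fire only if at
  least $T$ steps have passed since its last firing. The alternative
  literal reading (fire only while a global clock is below $T$) would
  permanently silence chains after $T$ quiet steps, which contradicts the
  decay-and-recover behaviour the mechanism is meant to produce.
* **Step granularity.** The chain advances once per mini-batch, driven by
  the batch-mean pre-activations. Per-sample stepping would make the glia
  trajectory depend on the ordering of samples inside a batch; the
  batch-mean drive is deterministic given the seed and is cheap. A direct
  consequence, verified bitwise in the tests: with $\alpha = 0$ (or a
  chain that never fires) glia pretraining is identical to plain CD-1
  pretraining under the same seed.

Default glia parameters are $\alpha = 0.8$, $\beta = 0.4$,
$\theta = 0.75$, $T = 5$ — the mid-points of the ranges that behave well
in the parameter sweeps this framework supports; all four are exposed in
every configuration object, and `sweep_glia_params()` evaluates the
standard 20-point grid $0.05, 0.10, \ldots, 1.00$ for any one of
$\alpha, \beta, \theta$.

## Weight initialisation

Weights start Gaussian $N(0, \texttt{init\_sd}^2)$ with zero biases. The
default `init_sd = 0.1` was chosen after measuring that $\mathrm{SD} =
0.01$ leaves a three-hidden-layer sigmoid stack emitting essentially
constant activations (abstraction SD $\sim 10^{-5}$ on 36-instance
training folds), which stalls fine-tuning at chance no matter the head:
the classifier then sees a constant input. With 0.1 the stack passes
signal from the start and short CD pretraining suffices. `init_sd` is a
parameter of `rbm_new()` and `dbn_new()` for users who want the smaller
classical value together with much longer pretraining.

# The discriminative RBM

The fusion classifier is an RBM whose visible layer is augmented with a
one-hot two-state label group. With two label states the class posterior
is closed-form: $p(y\,|\,x) \propto \exp\big(d_y + \sum_j
\mathrm{softplus}(c_j + U_{yj} + (W^\top x)_j)\big)$, a free-energy
comparison that needs no sampling. Training maximises the conditional
log-likelihood $\sum_i \log p(y_i | x_i)$ directly (purely discriminative
objective) by mini-batch gradient ascent with momentum. A zero-initialised
model predicts exactly 0.5 for both classes, and the trained model is
checked in the tests against an independent logistic-regression oracle on
a verified-separable toy problem.

# Fine-tuning and the ensemble

After greedy pretraining, each branch DBN receives a two-neuron softmax
head and the whole stack is fine-tuned by mini-batch SGD on the
cross-entropy (learning rate 0.5, momentum 0.9 by default — smaller rates
were measured to leave the near-saturated stack at its symmetric starting
point on folds of 8–36 instances; optional early stopping monitors the
training-loss plateau). Glia terms play no role in fine-tuning. The branch
heads are then discarded; the branch's contribution to the ensemble is its
last-hidden-layer abstraction. One model is trained per emotion dimension,
since arousal and valence are reported separately.

The default branch widths are, per subset: F1 $110/105/90$,
F2 $145/145/120$, F3 $55/55/45$, F4 $120/55/45$, F5 $155/80/50$, so the
concatenated abstraction is $90+120+45+45+50 = 350$ wide — a reduction
from 664 — and feeds the discriminative RBM. All five branches share one
set of glia parameters, matching the sweep design that varies a single
global value. The abstractions enter the fusion RBM as probabilities
(values in $(0,1)$), not binarized; binarization would discard the very
confidence information the probabilities carry. Training is strictly
stagewise — branches first, fusion second — and fusion training never
mutates branch weights.

# The synthetic EEG generator

The generator emulates the statistical structure the feature pipeline
measures, under the standard acquisition conditions (32 subjects, 40
trials each, 32 named channels at 128 Hz, one-minute trials by default).
Each channel is a sum of four band-limited oscillators (theta 6 Hz, alpha
10 Hz, beta 20 Hz, gamma 35 Hz) with per-trial random phases, plus
$1/f$-shaped noise, mixed across channels by a fixed per-subject random
matrix $(1-m)I + mS$ with row-stochastic $S$. Class structure enters
through the oscillator amplitudes: high arousal adds
$0.25\,d$ to the beta and gamma amplitudes of every channel; pleasant
valence adds $0.25\,d$ to alpha on left-hemisphere channels and subtracts
it on the right (and conversely), creating a hemispheric alpha asymmetry.
Here $d$ is the configured `effect_size`; amplitude jitter (SD 0.1) and
the noise level `noise_sd` are separate knobs. Labels are drawn as
balanced assignments — not i.i.d. coin flips — so that 10-fold
participant-specific folds at 40 trials remain meaningful.

What the generator does *not* emulate: ocular and muscular artifacts,
volume-conduction physics, non-stationarity across a session, or any
stimulus structure. Passing end-to-end tests on this generator therefore
demonstrates that the pipeline recovers class-conditional band-power and
asymmetry structure through the full feature–DBN–fusion–CV stack; it does
not certify performance on real recordings.

# Evaluation protocol

`run_cv()` follows the participant-specific protocol: each subject's
$40 \times 664$ feature matrix is standardized column-wise using that
subject's own statistics, then split into 10 stratified folds (36 train /
4 test), one model trained per fold and dimension. Standardizing the full
per-subject matrix *before* splitting leaks test-fold statistics into
training; it is nevertheless the protocol's convention and therefore the
default. `strict_cv = TRUE` standardizes with training-fold statistics
only and applies them to the held-out fold — the methodologically clean
variant, provided for comparison. F1 is reported for the positive (high)
class, 0 by convention when there are neither true nor predicted
positives; fold assignment is stratified whenever every class has at
least $k$ members.

On real recordings the same harness computes per-subject accuracy and F1
for the full 32-subject protocol; `read_subject_trials()` accepts any
per-subject container with the layout
`data [trials x channels x samples], fs, channels, labels`.

# Problem sizes used in the shipped checks

The test suite and the acceptance script exercise the pipeline at desk
scale, chosen once as the smallest sizes at which every stage is
meaningfully exercised: 6-second trials (768 samples — three half-
overlapping Welch windows, stable EMD), one subject with 40 trials per
end-to-end run, effect size 3 with noise SD 0.2 for the recovery runs and
effect size 0 for the null runs, reduced branch widths
(32/24/16-scale) suited to 36-instance folds, exact-enumeration RBM
oracles at $4 \times 3$ and $3 \times 2$, and $10^5$ Gibbs sweeps for the
sampling check. The glia-parameter sweep check runs the full 20-point grid
with a single-branch model on the frequency-domain subset at $k = 2$.

# Known limitations

* CD-1 only; no persistent CD or tempering. These matter for generative
  quality, much less for the discriminative use made of the pretrained
  weights here.
* The EMD implementation is univariate, cap-limited sifting; it is
  adequate for band-limited oscillatory mixtures but, like all EMD
  variants, has no uniqueness guarantees and can split or merge modes on
  broadband signals.
* The discriminative RBM optimises the purely discriminative objective;
  no generative/hybrid weighting is implemented.
* Cross-subject (leave-subject-out) evaluation and significance testing
  between variants are out of scope; the harness is participant-specific
  by design.
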