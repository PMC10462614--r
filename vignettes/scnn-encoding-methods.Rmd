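---
title: "Spiking convolutional encoding models: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spiking convolutional encoding models: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of the model it implements:
the spiking feature extractor, the receptive-field encoding model, the
decoders built on top of it, the noise-ceiling machinery, and the design
choices taken where the method leaves room. It states no empirical
result that the test suite does not itself compute.

## The model

`scnnenc` predicts per-voxel fMRI response amplitudes from grayscale
visual stimuli. The pipeline has two stages.

**Spiking feature extraction.** Images (intensities in $[0,255]$) are
filtered with a bank of ON/OFF difference-of-Gaussians (DoG) kernels —
the retinal center–surround stage. Two presets exist: the
character/natural regime (ON+OFF at sizes $3,7,13$ with $\sigma$ pairs
$(3/9,6/9)$, $(7/9,14/9)$, $(13/9,26/9)$, padding 6) and the digit
regime (ON+OFF at size 7, $\sigma=(1,2)$, padding 3). DoG activations
above 50 are converted to a temporal code by intensity-to-latency
coding: eligible sites are sorted by activation (descending) and split
into $T=30$ equal rank bins; bin index is spike time, so stronger
activations spike earlier and each site spikes at most once. Spike maps
are max-pooled ($2\times2$, stride 2) by keeping the earliest spike per
window. The pooled spike wave drives a convolutional layer of 64
Integrate-and-Fire kernels ($5\times5$, padding 2, threshold
$v_{th}=10$): the voltage at step $t$ accumulates the weighted input
spikes of step $t-1$,
$$v_i(t) = v_i(t-1) + \sum_j w_{ij}\, s_j(t-1),$$
and a neuron fires once per stimulus when $v_i \ge v_{th}$, resetting
to zero. Synapses learn by simplified, soft-bounded STDP: for each
selected winner with spike time $t_i$,
$$\Delta w_{ij} = \begin{cases} a^+ \, w_{ij}(1-w_{ij}) & t_j \le t_i\\
a^- \, w_{ij}(1-w_{ij}) & \text{otherwise,}\end{cases}$$
with $a^+=0.004$, $a^-=-0.003$; presynaptic sites that never spike
(including the zero padding) are depressed. Learning is monitored by
$C=\sum_{ij} w_{ij}(1-w_{ij})/N$ and stops when $C<0.01$, at which
point the kernels carry near-binary selectivity. For feature read-out
the threshold is set to infinity: no neuron fires or resets, so the
final-step voltage equals the convolution of the weights with the
spike-count map, a real-valued volume $F \in \mathbb{R}^{64\times h
\times w}$.

**Voxel-wise encoding.** Each voxel $v$ is a linear readout of the
feature vector at one map location,
$$y_v = w_v \cdot f_{ij} + b_v + \epsilon,$$
with the location chosen by exhaustively scanning all $h\times w$
positions and scoring each by threefold cross-validated $R^2$ on the
training trials; the winning location's readout is then refitted on all
training trials. This receptive-field constraint is the model's
overfitting control: each voxel sees 64 features rather than
$64\,h\,w$.

**Decoding.** Identification predicts responses for every candidate
image and picks the candidate whose prediction correlates best with the
observed response (over the best-encoded 500 voxels by convention).
Reconstruction scores a large prior image set by the Gaussian
log-likelihood
$$\log p(r\mid s) \propto -(r-\hat r(s))\,\Sigma^{-1}(r-\hat r(s))',
\qquad \Sigma = \mathrm{cov}(r - \hat r)$$
over the top 200 voxels and averages the pixels of the best 15 prior
images.

**Noise ceiling.** From repeated test presentations, the noise sd is
$\hat\sigma_N = \sqrt{\mathrm{mean}(\sigma^2_R)}$ (mean over images of
the across-repeat variance) and the response variance is
$\hat\sigma^2_R = \mathrm{var}(\mu_R) - \hat\sigma^2_N$. 1000
simulations draw response and noise from these distributions and
correlate signal with response; the mean correlation is the ceiling.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `spike_threshold` | 50 | DoG activation needed to emit a spike (0–255 intensity scale) |
| `T` | 30 | latency-coding time steps (bins) |
| `v_th` | 10 | IF firing threshold during training |
| `a_plus`, `a_minus` | 0.004, −0.003 | STDP learning rates |
| `convergence_stop` | 0.01 | stop training when $C$ falls below this |
| `winners_per_image` | one per channel | STDP winners allowed per stimulus |
| `inhibition_radius` | 2 | same-channel suppression radius around a winner |
| `max_epochs` | 64 | training sweep budget |
| `folds` | 3 | cross-validation folds in the location scan |
| `shrinkage` | 0.1 | diagonal shrinkage of the noise covariance |
| `top_n` | 15 | prior images averaged in a reconstruction |

## Design choices in the open corners

**Winner policy.** The winner count per stimulus is not pinned down by
the method's description; what is pinned down is that training
converges ($C<0.01$). The arithmetic of the soft-bounded rule makes a
single global winner per image insufficient for a 64-kernel layer:
each update moves one kernel's $\sim$150 weights by at most
$|a|\cdot 0.25$, so driving all $\sim$9600 weights to saturation needs
far more kernel-updates than one-per-image provides within any
reasonable epoch budget — in our training runs a single-winner policy
plateaus near $C\approx0.18$ while one-winner-per-channel converges in
tens of epochs. The default is therefore one winner per output channel
per image (the k-winners-take-all convention of the simplified-STDP
literature), configurable via `winners_per_image`.

**Tie-breaks.** Lateral inhibition keeps, at each position, the
earliest event across channels, ties resolved to the lowest channel
index; winner selection ranks by time, then potential at firing, then
channel, then row-major position. All orderings are total, making
training bit-reproducible for a fixed seed.

**Weight initialisation.** Independent draws from a normal with mean
0.8 and sd 0.05, clipped to $[0,1]$ — high enough that untrained
neurons fire readily and compete for plasticity, the usual starting
point for this learning rule. Configurable in `if_layer()`.

**Time indexing.** Spike times are 1-based steps $1..T$; the voltage
at step $t$ integrates input spikes of step $t-1$, so firing can occur
at steps $2..T$. Feature read-out integrates *all* input spikes
(equivalently, the voltage one step past the last input), which is
what makes the infinite-threshold read-out exactly the weighted
spike-count convolution.

**DoG normalisation and canvas.** Each Gaussian is normalised by its
grid sum (unit discrete mass), so every kernel's coefficients sum to
exactly zero. All kernels of a preset are embedded centered in the
largest kernel's canvas before convolving with the preset's single
padding; that is the only reading under which one padding value yields
spatially aligned, equally sized channels for all three kernel sizes.
Grayscale conversion uses Rec. 601 weights; resizing is center-aligned
bilinear — the common defaults.

**Regression conventions.** The readout includes an intercept by
default (fMRI response amplitudes are not zero-mean); disable with
`intercept = FALSE` for the strict form. CV folds are contiguous
blocks of a seeded shuffle; $R^2$ is computed on pooled out-of-fold
predictions; a zero-variance target scores 0. Voxel selection for
decoding always uses training-set CV $R^2$, never test-set accuracy,
to avoid circular selection. Rank-deficient designs are detected by
pivoted Cholesky and refitted with a tiny ridge penalty
($10^{-8}\,\overline{\mathrm{diag}(X'X)}$), flagged per voxel.

**Noise covariance.** The sample covariance of training residuals is
shrunk toward its diagonal (default $\lambda=0.1$) because with
hundreds of voxels and a few hundred trials it is ill-conditioned; the
likelihood is evaluated via a Cholesky solve, never an explicit
inverse. Rankings are unchanged by these numerical choices wherever
the raw covariance is solvable.

**Eq.-10-style response variance.** The conventional formula subtracts
the full noise variance from the variance of the per-image mean
response, although that mean (over $m$ repeats) only carries
$\sigma^2_N/m$ of noise; the subtraction therefore over-corrects and
can go negative for noisy voxels (clipped to 0 with a warning). The
package implements the conventional formula verbatim and exposes the
corrected subtraction behind `correct_repeats = TRUE` without guessing
which was intended; the recovery tests use the corrected variant, and
the conventional one is asserted to be conservative (never higher).

## What the synthetic data does and does not show

`generate_stimuli()` produces oriented bars (high-contrast strokes at
0/45/90/135° with jitter), Gaussian blobs, and glyphs (2–4 jittered
strokes), standing in for handwritten characters and natural images.
Default dataset scale mirrors the handwritten-character regime: 270
train / 90 test trials of 56×56 images. `generate_voxels()` +
`simulate_responses()` generate responses that are *exactly* the
linear-readout-plus-Gaussian-noise process the encoding model assumes.
Passing tests on these data therefore validate the estimation
machinery — location search, regression, selection, decoding,
ceilings — not the biological claim that real voxels are linear
readouts of spiking-network features. Real fMRI data add HRF dynamics,
correlated noise, nonlinearity, and voxel covariance that the
generator deliberately omits.

## Numerical and degenerate-input conventions

- Latency-coding ties (equal activations) break by row-major site
  index; remainder spikes go to the earliest bins.
- Location-scan ties break to the smallest row, then column.
- Identification ties break to the lowest candidate index; a
  zero-variance predicted response scores $-\infty$.
- A constant measured or predicted series gets encoding accuracy 0
  with a warning (Pearson correlation is undefined there).
- The spiking simulator and trainer are implemented in C++ (event
  driven); a scalar R reference implementation of every step is kept
  and the two are tested for event-for-event equivalence.

## Problem sizes used in the checks

The convergence study trains the full 64-kernel layer on 400 bar/glyph
stimuli at 56×56 (training typically stops within ~30 epochs, well
under a minute of CPU in the compiled path). The receptive-field
recovery study runs on a 16×16 → 8×8 map with a fixed 32-kernel bank
and 240 mixed stimuli: a corner of the map only sees $3\times3$ valid
input positions × 6 DoG channels = 54 presynaptic sites through the
zero padding, so a readout wider than that is unidentifiable at the
border *by construction*; 32 channels keep the design full rank at
every location (measured condition numbers ~10³) and make exact
noiseless recovery a fair test. Decoding and ceiling checks use small
synthetic sets (tens of trials, ≤50 voxels, 1000 ceiling simulations).

## Known limitations

- Single convolutional spiking layer; no deep SCNN, leaky-IF or
  reward-modulated variants.
- Color is discarded at preprocessing; color decoding is out of scope.
- No HRF/BOLD time-series modelling: inputs are per-trial response
  amplitudes (e.g. GLM betas).
- Reconstruction is selection-and-averaging over a prior set; it
  cannot synthesise content absent from the prior images.
- Model persistence uses R's native serialisation (RDS) with a format
  tag; response matrices travel as CSV.
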