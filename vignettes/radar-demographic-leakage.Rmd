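---
title: "Demographic leakage from radar cardiac signals: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Demographic leakage from radar cardiac signals: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(radarleak)
```

## The question the package answers

A continuous-wave radar pointed at a person's chest measures sub-millimetre
thoracic motion without any contact. That motion carries respiration and the
mechanical signature of every heartbeat. `radarleak` implements the full
analysis chain needed to ask a privacy question: *can a classifier recover
demographic attributes — sex, age group — from nothing but the radar's
cardiac channel?* Because the clinical recordings that motivated the chain
cannot be redistributed, the package ships a first-class synthetic cohort
generator, so every stage is testable end to end from a seed.

The chain is:

1. **Simulation** (`cohort_config()`, `sample_cohort()`, `simulate_cohort()`,
   `generate_dataset()`): labeled I/Q radar recordings at 2 kHz.
2. **Demodulation** (`segment_windows()`, `fit_ellipse()`, `compensate()`,
   `arctan_demodulate()`): chest displacement from the I/Q locus.
3. **Cardiac isolation** (`resample_working_rate()`, `modwt_mra()`,
   `select_cardiac()`): the heartbeat component, respiration removed.
4. **Scalograms** (`segment_frames()`, `cwt_scalogram()`): 4 s frames as
   200x200 time-frequency images.
5. **Augmentation** (`train_cwgan()`, `synthesize()`,
   `augment_training_set()`): a label-conditioned Wasserstein GAN with
   gradient penalty, trained on training-subject scalograms only.
6. **Classification and evaluation** (`train_classifier()`,
   `predict_frames()`, `vote_windows()`, `compute_metrics()`,
   `welch_test()`, `temporal_aggregation()`, `grad_cam()`,
   `run_experiment()`, `run_pipeline()`).

## The radar signal model

Chest displacement $d(t)$ (mm) phase-modulates the received carrier over the
two-way path: $\Phi(t) = 4\pi d(t)/\lambda + \Phi_0$. The receiver's
quadrature channels are

$$I = c_I + A_I \cos\Phi, \qquad Q = c_Q + A_Q \sin(\Phi + \psi),$$

with DC offsets $(c_I, c_Q)$, amplitude imbalance $(A_I, A_Q)$ and
quadrature phase error $\psi$ — together the "ellipse distortion", because
they turn the ideal circular I/Q locus into an ellipse. The carrier
wavelength defaults to 12.4 mm (a 24 GHz vital-sign radar); the source
system's carrier is not documented, so the wavelength is an explicit
parameter throughout, and it cancels out of every classification result
(it only scales displacement).

**Demodulation.** A direct least-squares conic fit (the numerically stable
partitioned-eigen formulation, constrained to an ellipse) is fitted per 10 s
window; the points are then centred, rotated, axis-normalized and passed to
`atan2`. A useful fact makes this exact: for $|\psi| < \pi/2$ the distortion
map has positive determinant, so whitening the fitted ellipse back to a
circle is a pure rotation of the phase — there is no reflection ambiguity,
and the recovered phase equals the true phase up to an additive constant.
The constant is resolved by anchoring each window's first sample to zero
displacement. Degenerate inputs (fewer than 6 points, collinear clouds,
coincident points, a zero-magnitude I/Q sample) raise errors rather than
produce silent nonsense.

## Cardiac isolation

Respiration (0.15-0.35 Hz, millimetres) dwarfs the heartbeat
(~1-1.7 Hz fundamental, tenths of a millimetre), so the cardiac band must be
isolated before imaging. The package uses the maximal overlap discrete
wavelet transform (MODWT): undecimated, therefore shift-equivariant, with an
additive multiresolution analysis whose detail $D_j$ occupies the octave
$[f_s/2^{j+1}, f_s/2^j]$.

Numerical choices, each of which mattered in practice:

* **Working rate 200 Hz.** At 2 kHz the cardiac band sits at decomposition
  levels 9-11; at 200 Hz it sits at levels 6-7, keeping filters short. The
  decimator is a zero-phase FIR low-pass (order 200, Hamming, cutoff 90 % of
  the target Nyquist, forward-backward) over an odd-reflection padding that
  suppresses the filter's startup transients.
* **Wavelet.** Least-asymmetric order-4 ("sym4"), the common toolbox
  default; `sym8`, `haar` and `d4` are selectable. The MRA invariants
  (additivity, coefficient-energy preservation, circular-shift
  equivariance) hold for all of them and are asserted in the tests.
* **Boundary handling.** The transform itself is circular. For a 10 s
  window dominated by an aperiodic respiration sweep, both circular wrap
  and mirror reflection create a slope discontinuity whose broadband
  leakage lands squarely in the cardiac octaves — measured at roughly the
  same RMS as the cardiac component itself, which destroys the separation.
  `modwt_mra(boundary = "bridge")` therefore appends a 4 s cubic Hermite
  segment joining the window's final value and slope back to its initial
  value and slope. The circularized signal is C1-continuous, the leakage
  drops by an order of magnitude, and the periodic mode (with its exactly
  assertable shift-equivariance) remains available.
* **Band selection.** A detail level is kept when its octave midpoint lies
  inside the cardiac band. The default band is (0.8, 3.5) Hz: the octave
  below (0.39-0.78 Hz at 200 Hz) contains almost no pulse-train energy —
  the slowest spectral line of a periodic pulse train is its fundamental,
  >= 0.8 Hz for heart rates >= 48 bpm — but it receives the bulk of the
  residual respiration leakage, so including it costs far more than it
  buys. The band is a parameter; `select_cardiac(decomp, band = c(0.5, 3.5))`
  reproduces the wider three-octave selection if wanted.

## Scalogram images

Each 10 s cardiac window is cut into overlapping 4 s frames with a 0.5 s
stride (13 frames per full window) and rendered as the magnitude of an
analytic Morlet CWT ($\omega_0 = 6$) on `size` log-spaced frequencies over
0.3-20 Hz, time-reduced to `size` columns by bin averaging and min-max
normalized to [0, 1] (a constant frame maps to zeros). The product size is
200x200; smaller sizes exist for desk-scale experiments only.

A 4 s frame is short relative to the slowest wavelets, and naive circular
FFT evaluation smears the frame edges enough to bias ridge positions by
several bins. The implementation zero-pads (no wrap), divides each
coefficient by the fraction of the wavelet's envelope mass that lies inside
the frame (an exact edge-gain compensation for a steady tone), and zeroes
positions where that fraction falls below one half — those positions simply
do not contain the information. With this scheme a pure tone's ridge falls
within one frequency bin of the tone from about 0.6 Hz upward; below that
the frame is resolution-limited and no estimator could do better.

Images are stored as 8-bit grayscale PNGs with a CSV manifest; the loader
replicates the single channel to three at batch assembly for the
classifier, reconciling grayscale storage with a 3-channel network input.

## The networks

No deep-learning framework is attached: the convolutional layers, batch
normalization, transposed convolutions, pooling, Adam/RMSprop and full
backpropagation are implemented in the package (with C++ im2col/pooling
kernels), because the networks *are* the method under study and every
gradient had to be auditable. All layer gradients are verified against
central finite differences in the test suite.

**Frame classifier.** Five convolution stages with kernel sizes 5, 3, 13,
5, 2 (stride 1, no padding), each followed by batch normalization, ReLU and
max pooling, then fully connected layers 1024, 256, 64, 1 with dropout 0.5.
The published description fixes the kernels and the flattened width (2048)
but not the channel progression; the package uses 16, 32, 64, 128, 512 with
2x2 pooling after stages 1-4 and 3x3 after stage 5, giving the spatial
trace 200 -> 98 -> 48 -> 18 -> 7 -> 2 and exactly 512 x 2 x 2 = 2048
flattened features. Any progression satisfying the printed constraints
would be admissible; the 2048 width is enforced as a hard check. Training
uses binary cross-entropy on a sigmoid of the single logit, Adam at 0.001.

**Conditional WGAN-GP.** The generator's five transposed-convolution stages
(102 -> 256 -> 128 -> 64 -> 32 -> 16 channels, kernel/stride pairs (3,2),
(3,2), (5,3), (3,3), (3,2), batch norm + ReLU on stages 1-4, tanh on stage
5) trace from a 1x1 latent input to a 139x139 16-channel map — which is not
a 200x200 single-channel image, so an output head follows: a 1x1 projection
convolution, an affine map of the saturating output onto [0, 1], and
bilinear resizing to the target size. The critic applies two strided
convolutions (1 -> 128 -> 256, kernel 4, stride 2, batch norm + LeakyReLU);
since those two stages cannot flatten to 1024 from a 200x200 input on their
own, an adaptive average pool to a 2x2 grid precedes flattening, meeting
the published 1024 + 2 linear width exactly for any image size. Labels are
one-hot, concatenated as constant channels to the latent and as two extra
features at the critic's flatten stage.

Training follows the published schedule by default — 151 epochs, batch 32,
five critic steps (RMSprop, 6.7e-6) per generator step (Adam, 8e-5),
latent dimension 100, gradient-penalty coefficient 10, no early stopping —
with per-step losses retained in the checkpoint.

**Gradient penalty.** For interpolates $\hat x = \epsilon x_r +
(1-\epsilon) x_f$, the penalty is $\lambda\,\mathrm{mean}\big(
(\lVert\nabla_{\hat x} D(\hat x)\rVert_2 - 1)^2\big)$. Its gradient with
respect to the critic parameters is a double backward; the package computes
it exactly for the piecewise-linear critic by treating the LeakyReLU
activation masks as locally constant (true almost everywhere) and
evaluating batch normalization inside the penalty with its running
statistics, which makes the penalty a deterministic function of the
interpolates. The construction — backward pass for $\nabla_{\hat x} D$,
tangent (Jacobian-vector) propagation of the penalty's upstream vector, and
a weight-gradient contraction of recorded deltas against tangents — is
checked against finite differences of the penalty itself to 1e-4 in the
tests (observed agreement is ~1e-10).

## Evaluation protocol

Splits are always at the subject level, optionally stratified (the
reference protocol holds out 6 of 30 subjects, 3 per sex). Leakage guards
are hard errors: a held-out subject's scalogram in a GAN or classifier
training set aborts the run; synthetic scalograms carry no subject identity
and are always admissible.

Frame probabilities are thresholded at 0.5 (inclusive: a logit of exactly 0
votes class 1) and aggregated per 10 s window by hard majority voting; a
tie is broken by the mean frame probability. For independent frames with
per-frame accuracy $p$, the 13-frame vote follows the binomial law
$\sum_{i \ge 7}\binom{13}{i} p^i (1-p)^{13-i}$, which the tests verify by
simulation — voting amplifies any above-chance frame accuracy.

Metrics follow the conventions of the reference result tables, which
satisfy FAR + precision = 100 and FRR + recall = 100 on every printed row:
FAR is the macro false-discovery rate (100 − macro precision) and FRR the
macro miss rate (100 − macro recall), *not* the textbook FP/(FP+TN)
definitions; F1 is the macro average of the per-class F1 scores, not the
harmonic mean of the macro precision/recall. Welch's t statistic,
Satterthwaite degrees of freedom, two-sided p and the 95 % CI of the mean
difference come from `stats::t.test`; the tests recompute the textbook
formulas independently.

**Temporal aggregation** quantifies the privacy threat of longer
observation: all contiguous runs of a subject's frame predictions spanning
at least 7 s (a run of $k$ in-window frames spans $4 + 0.5(k-1)$ s, so the
shortest qualifying run has 7 frames) are majority-voted, binned by
duration (1 s bins), and summarized per subject and as the cohort's
cumulative fraction of subjects at >= 95 % accuracy by each duration. Runs
may cross window boundaries — the frame sequence is treated as one ordered
list per subject; neither the boundary rule nor the bin width is fixed by
the source, so both are parameters.

**Grad-CAM** attaches to the fourth convolution stage by default (the ReLU
output): channel weights are spatial means of the class-score gradient,
maps are rectified weighted activation sums, bilinearly upsampled,
normalized to [0, 1] and averaged per class over correctly classified
instances only; the class score is the logit for class 1 and its negative
for class 0.

## What the synthetic cohort does and does not emulate

Per subject the generator draws: heart-rate mean (normal around 72 bpm,
between-subject SD 6), beat-to-beat variability (around 2.5 bpm, SD 0.8),
Gaussian-bump pulse shape with width ~0.12 s and amplitude ~0.45 mm,
respiration at 0.15-0.35 Hz with amplitude ~4 mm and slow random phase
drift, white body-motion and receiver noise (SD 0.01), and a random ellipse
distortion (offsets ±0.5, amplitudes 0.8-1.2, phase error ±0.3 rad). Class
structure enters as mean shifts of `effect_size` pooled SDs: sex shifts
heart-rate mean, pulse width and pulse amplitude (a chest-morphology
channel); age group shifts heart-rate variability (the quantity most
consistently reported to change with age). Magnitudes are configuration,
not physiological claims; `effect_size = 0` makes the classes exchangeable
and is the package's null condition.

Not emulated: true beat morphology (dicrotic structure), motion artifacts
beyond white noise and drift, multi-path and multi-person scenes,
non-resting scenarios (Valsalva, apnea, tilt), and the receiver physics of
a real six-port front end. Passing tests therefore demonstrate that the
*pipeline* recovers planted class structure through the full radar chain —
they say nothing about how much demographic signal real radar recordings
carry, which is exactly the question requiring the clinical data.

## Desk-scale profiles

The default profiles match the reference settings (200x200 images, the
full GAN schedule). The test suite and the worked examples use reduced
profiles chosen once: tone-scalogram fixtures at 32 px, a three-stage
classifier (`cnn_spec_small()`) at 32-48 px, GAN smoke runs of 1-2 epochs,
and an end-to-end recovery experiment with 12 subjects x 100 s at 48 px,
6 held-out subjects and 5 training epochs — 60 held-out windows, enough for
a 70 % accuracy bound to clear chance by more than three binomial standard
errors. The null-effect check averages three such cohorts and uses a
subject-level error band, because windows of one subject are strongly
correlated: with 6 test subjects per repetition the effective sample is 18
subject decisions, not 180 windows.

## Known limitations

* The penalty's batch-normalization linearization (running statistics
  inside the penalty term) departs from frameworks that differentiate
  through batch statistics; for the small critics used here the difference
  is far below the training noise floor.
* Ridge localization — and therefore scalogram content — is
  resolution-limited below ~0.6 Hz for 4 s frames.
* `welch_test()` requires non-degenerate variances; repeated identical
  accuracies across runs (possible at desk scale with tiny test sets) make
  the comparison undefined.
* The pure-R training loop is CPU-bound; the published 151-epoch GAN
  schedule at 200x200 is supported but intended for long-running batch use,
  not interactive work.
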