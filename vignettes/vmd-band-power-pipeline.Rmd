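---
title: "Frequency-domain emotion analysis of EEG with variational mode decomposition"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain emotion analysis of EEG with variational mode decomposition}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`vmdeeg` implements a complete frequency-domain analysis chain for
evoked-emotion EEG: a labelled synthetic-EEG generator, a three-step
preprocessing chain, a from-scratch variational mode decomposition (VMD)
solver, sliding-window band-power features, and a classifier evaluation and
explanation layer. This vignette records the scientific model behind each
stage, the tunable parameters and their defaults, and the design decisions
taken where more than one reasonable choice existed.

## The analysis problem

Emotions evoked by visual stimuli modulate the spectral content of scalp EEG.
The pipeline asks: given 32-channel recordings at 128 Hz in which blocks of
happy, sad and fear-inducing images alternate with relaxation intervals, can
the emotion on screen be decoded from the band-limited power of the signal's
oscillatory components — and which component and band carry the information?

The feature space is deliberately compact: each analysis window is decomposed
into $K = 5$ intrinsic mode functions (IMFs), and the power of each mode in
each of the five canonical EEG bands (Delta 0.5–4 Hz, Theta 4–8 Hz, Alpha
8–12 Hz, Beta 12–30 Hz, Gamma 30–45 Hz) gives a 25-dimensional feature
vector per window.

## Variational mode decomposition

Each mode is an AM-FM oscillation $u_k(t) = A_k(t)\cos(\phi_k(t))$ with
non-negative amplitude and non-decreasing phase, compactly supported in
frequency around a center $\omega_k$. VMD finds $K$ such modes by minimizing
the summed bandwidth of the modes' analytic signals, subject to the modes
summing to the input — a constrained variational problem relaxed by a
quadratic penalty $\alpha$ and a Lagrange multiplier, and solved by ADMM.
In the frequency domain each mode update is a Wiener filter applied to the
current residual,

$$\hat u_k \leftarrow \frac{\hat f - \sum_{i \ne k}\hat u_i + \hat\lambda/2}
  {1 + 2\alpha(\omega - \omega_k)^2},$$

and each center frequency moves to the spectral centroid of its mode over
the non-negative half-spectrum. The inner loop is implemented as a compiled
kernel (`src/vmd_admm.cpp`); everything else — mirror extension, transforms,
mode sorting — is plain R.

Parameters (all exposed through `vmd_config()`):

* `K = 5` modes — the feature layout fixes this; other values work but
  change the feature dimension.
* `alpha = 2000` — bandwidth penalty on the normalized (cycles/sample)
  frequency grid. Larger values give narrower modes; the package verifies
  monotonicity of the measured mode bandwidth in `alpha` as a property test.
* `tau = 0` — multiplier ascent step. Zero leaves the Wiener filters free to
  *not* reproduce broadband noise, which is the robust choice for EEG;
  positive values enforce exact reconstruction.
* `tol = 1e-7`, `max_iter = 500` — convergence is the summed relative
  spectral change of the modes between sweeps, floored at `1e-14` to avoid
  division by zero for silent modes.
* `init = "uniform"` — starting centers evenly spaced over the half
  spectrum; `"zero"` and seeded `"random"` are available, and for
  well-separated tones the converged mode set is initialization-invariant
  (tested).

**Boundary handling.** The signal is mirror-extended by half its length on
each side before decomposition and the modes are cropped back afterwards.
A symmetric extension is continuous in value but kinks in slope at the two
data boundaries; band-limited modes cannot reproduce the kink, which leaves
a reconstruction error concentrated in roughly the outermost thirty samples.
Smoother extensions were evaluated (a DCT-I even extension; a C¹
point-symmetric pad tapered to the signal mean) and both perform worse —
the first merely moves the kink, the second injects spurious low-frequency
content that captures the lowest mode. The half-mirror is kept, and the
reconstruction contract (relative L2 error of the mode sum at most 0.05 with
default settings) is stated for tones of 10 s, where the edge contribution
is small; at 3 s the same quantity is about 0.06. Frequency *recovery* is
unaffected by duration and is tested at 3 s.

**Mode ordering.** Modes are returned sorted by ascending center frequency:
mode 1 ("IMF1") is the lowest-frequency component. Conventions differ in the
literature — decompositions that peel off high-frequency content first label
the *last* extracted mode, which is the slowest, with the largest index.
Under this package's convention the delta-band mode is `IMF1`, and the
planted discriminative feature of the default generator is `IMF1_Delta`.

## The synthetic-EEG generator

No public recordings accompany the stimulus paradigm this package models, so
the generator is a first-class, tested module that produces labelled sessions
with known ground truth. One session is: 10 s relaxation, then for each
emotion (happy, sad, fear) a block of three 5-s images, with 5-s relaxation
between blocks; the whole sequence runs twice (two phases), 130 s in total.
Labels are per-sample; segment boundaries are half-open `[start, end)` with
time origin at sample 0.

Each emotion block carries class-dependent AM-FM components. The defaults
plant exactly one discriminative effect:

| band  | carrier | amplitude (µV)            | role               |
|-------|---------|---------------------------|--------------------|
| Delta | 2 Hz    | happy 2, sad 6, fear 4    | discriminative     |
| Alpha | 10 Hz   | 3 in every class          | non-discriminative |
| Beta  | 20 Hz   | 2 in every class          | non-discriminative |

Amplitudes were chosen from a band-power signal-to-noise argument: a 2 Hz
carrier of amplitude $A$ contributes $A^2/2$ µV² to the delta band of a 3-s
window, i.e. 2 / 18 / 8 µV² for the three classes, against a delta-band pink
noise background of roughly 2 µV² — separations large enough that a planted
effect is recoverable, small enough that windows overlap across classes and
the task is not trivial. Each stimulus image evokes its own realization of
every component: a single cross-channel-coherent temporal source with a fresh
random spatial weighting (sign × gain in 0.8–1.2) and phase. This mimics
block-to-block variability of cortical source configurations, keeps the
channel-averaged band power at the nominal amplitude's power, and — important
for the artifact stage — spreads the clean signal's variance over many
sources so that no single independent component resembles the spatially
fixed ocular source.

On top of the carriers every channel receives: 1/f (pink) noise of 2 µV RMS,
independent per channel plus three shared pink sources with random spatial
weights (giving blind source separation something real to find); a random
polynomial drift of degree 3 and 20 µV peak (exactly the trend class the
Savitzky–Golay step removes); and blink artifacts — squared-cosine pulses of
80 µV and 0.3 s at 4 per minute on Fp1/Fp2, leaking at gain 0.2 into the
other frontal channels. The 4/min rate reflects the suppressed blinking of
attentive image viewing. The ground-truth object records the injected
carriers, the clean (pre-drift, pre-blink) data, blink onsets, drift
coefficients, and the identity of the discriminative feature.

What the generator does *not* model: cortical source geometry and volume
conduction, inter-subject variability, muscle and line-noise artifacts, and
any amplitude statistics of real recordings from this paradigm (none are
published). Passing the end-to-end tests therefore demonstrates that the
pipeline recovers structure *of the assumed form*; it is not evidence about
recordings whose effects take another form.

## Preprocessing

1. **Zero-phase bandpass, 0.5–45 Hz.** A single windowed-sinc (Hamming) FIR
   whose length follows from the requested transition width (0.5 Hz, set by
   the narrow lower edge: 845 taps at 128 Hz), applied forward-backward so
   the effective response is the squared magnitude with zero phase. Edges
   are reflect-padded by three filter lengths. The Hamming design gives
   > 50 dB single-pass stopband attenuation, comfortably over the 40 dB
   forward-backward contract tested at 0.05 Hz and 50 Hz.
2. **Savitzky–Golay detrending**, frame 127 samples, order 5, per channel:
   the smoothed reference reproduces polynomial trends up to degree 5
   exactly, so subtracting it removes them exactly (interior samples; the
   `(frame-1)/2` edge samples follow the filter's edge handling and are
   excluded from exactness assertions).
3. **ICA ocular removal.** A FastICA decomposition (symmetric, tanh
   nonlinearity, seeded orthogonal initializer — implemented in the package)
   followed by an automated ocular criterion: any component whose absolute
   Pearson correlation with the mean of Fp1/Fp2 reaches 0.7 is zeroed before
   reconstruction. Visual component inspection is not testable; the
   correlation rule is, and the threshold is exposed. When nothing is
   flagged the input is returned *exactly* unchanged. Rank-deficient input
   (for example a duplicated channel) is an error rather than a silent
   degraded fit.

The ocular criterion's specificity depends on the unmixing being at least
determined: with the full 32-channel montage the clean-data correlation
ceiling sits near 0.5, while toy montages of 6–8 channels are heavily
overcomplete (more sources than components) and single components can pin
to one frontal channel, whose correlation with the two-channel frontal mean
is bounded below by $1/\sqrt 2 \approx 0.707$ — just above the threshold.
ICA-contract tests therefore run on the full montage, which is also the
condition the pipeline defaults describe.

## Features

Windows of 3 s with 50% overlap slide from sample 0; a trailing partial
window is dropped, and any window containing relaxation samples or more than
one emotion label is discarded (no mixed-emotion windows, no majority vote).
Within a window, each channel is decomposed independently (VMD is
univariate) and each mode's power in each band is computed from the plain
DFT — no taper — normalized so the full spectrum sums to the window's mean
squared amplitude: positive-frequency bins are doubled (except DC and
Nyquist) and divided by $N^2$. This normalization makes band power
window-length-invariant and satisfies Parseval exactly, which the suite
checks to 1e-9; an unnormalized sum would grow with $N$ and make the
window-length sweep incomparable across lengths. Band edges are half-open
`[lo, hi)`; Gamma closes at 45 Hz because the bandpass leaves nothing above.

The 32 per-channel values of each feature are averaged to one value per
window — the least-assumption reading of a 25-dimensional feature space over
a 32-channel montage. Per-channel output and single-channel selection are
available through the `channels` argument.

## Evaluation

Windows are split 80/20, stratified by class, at window level by default —
mirroring a design in which overlapping windows of one trial can land on
both sides. That choice leaks temporal structure and flatters absolute
accuracies; `grouping = "by_trial"` keeps all windows of a trial together
and is the rigorous option. Validation accuracy is 6-fold stratified
cross-validation on the training split; the model is refit on the full
training split and test metrics (accuracy, macro precision/recall/F1,
confusion matrix) come from the held-out 20%.

Classifier defaults, all exposed: KNN with $k = 5$ and Euclidean distance,
ties broken by the nearest neighbour among the tied classes; RBF SVM with
$C = 1$ and $\gamma = 1/(25\,\mathrm{var}(X))$; an unpruned Gini CART; and a
random forest of 100 trees with $\lfloor\sqrt{25}\rfloor = 5$ features per
split. The window-length sweep re-runs featurization and evaluation for
lengths 1, 2, 3, 4 and 15 s; a failing cell (say, a window longer than the
recording) records its error without disturbing the rest of the table.

The ablation table reports cross-validated accuracy for every single
(IMF, band) cell, every IMF row, every band column, and all 25 features; on
the default synthetic data its best single cell is the planted `IMF1_Delta`.
Feature importance has two methods sharing one report schema: the random
forest's out-of-bag per-class permutation importance ("tree") and a seeded,
model-agnostic permutation importance on the held-out windows (20 shuffles
per feature, mean absolute drop in per-class recall). Both must — and do —
rank the planted feature first on the default data.

## Problem sizes and numerical choices

The reference study conditions used by the test-suite's end-to-end check are
six sessions of the default paradigm (two phases, 32 channels), which yield
300 single-emotion windows at 3 s / 50% overlap; the whole chain runs in
roughly two minutes on one core. Pipeline-level determinism checks use a
reduced single-session, 8-channel configuration, since determinism does not
depend on size. Seeds: one global seed deterministically derives per-stage
seeds by hashing the stage name, so adding a stage never shifts another
stage's random stream.

Known numerical edge cases: VMD on a constant signal converges to a single
DC mode (tested); silent modes are protected by an energy floor in the
centroid update; the EDF writer quantizes to 16 bits over a per-channel
physical range, so round trips are exact only to one quantization step; and
`randomForest` does not terminate on all-constant predictors, so degenerate
attribution contracts are exercised through the model-agnostic permutation
path.

## Limitations

Absolute accuracies on synthetic data say nothing about accuracies on real
recordings; the window-level split inflates them further. The generator's
effect family (stationary band-limited carriers with class-dependent
amplitude) is the same family the features measure — by design, since the
point of the tests is recovery of a known effect, but real evoked responses
are transient and broadband. The ICA stage assumes at least as many channels
as strong sources; sub-determined montages degrade it. The mapping between
this package's ascending IMF indices and any particular descending-index
convention in the literature must be made explicit when comparing tables.
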