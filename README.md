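# vmdeeg

Frequency-domain analysis of evoked-emotion EEG built around variational mode
decomposition (VMD). The package is for researchers who want a tested,
reproducible implementation of the full chain from raw multichannel EEG to an
interpretable emotion classifier: cleaning, decomposition into intrinsic mode
functions (IMFs), band-power features, classical classifiers, and
feature-importance analysis — plus a synthetic-EEG generator with known
ground truth, so every stage can be verified quantitatively.

## The method

EEG windows are decomposed into K = 5 amplitude/frequency-modulated modes
u_k(t) = A_k(t) cos(φ_k(t)) by minimizing the summed bandwidth of the modes'
analytic signals subject to Σ_k u_k = f (ADMM; quadratic penalty α,
multiplier step τ). In the frequency domain each mode update is a Wiener
filter of the current residual centred on the mode's frequency ω_k, and ω_k
moves to the spectral centroid of its mode. For each 3-s window (50%
overlap), the power of every mode in every canonical band — Delta (0.5–4),
Theta (4–8), Alpha (8–12), Beta (12–30), Gamma (30–45 Hz) — is computed with
a Parseval-exact DFT normalization, giving 25 features per window. Windows
are labelled by the emotion on screen (happy / sad / fear); KNN, SVM,
decision tree and random forest are compared by 6-fold cross-validation on
an 80% training split and scored on the held-out 20%, with a per-IMF /
per-band ablation table and permutation-based feature importance closing the
loop.

Preprocessing follows standard EEG practice: a zero-phase (forward-backward)
windowed-sinc FIR bandpass at 0.5–45 Hz, subtraction of a Savitzky–Golay
reference (frame 127, order 5) to remove slow trends, and FastICA-based
removal of ocular components, flagged automatically by their correlation
with the frontal-polar channel mean.

## Worked example

```r
library(vmdeeg)

# one synthetic session: 32 channels, 128 Hz, two stimulus phases (130 s)
g  <- generate_recording(paradigm_spec(), class_effects(), seed = 1)
pp <- preprocess_recording(g$recording)
f  <- extract_features(pp$recording)        # 25 band powers per window
r  <- train_eval(f, model_spec("rf"), split_spec(seed = 1), cv_spec(seed = 1))
r
#> rf: validation accuracy 0.7963 (6-fold: 0.778 1.000 0.667 1.000 0.667 0.667)
#>   test accuracy 0.8889 | macro P 0.9167 R 0.8889 F1 0.8857 (n=9)
#>        predicted
#> truth   fear happy sad
#>   fear     3     0   0
#>   happy    0     3   0
#>   sad      1     0   2

explain(r, method = "tree")
#> Feature importance (tree), top 6 of 25:
#>   IMF1_Delta   0.17969  (fear 0.1171, happy 0.2257, sad 0.1963)
#>   IMF4_Delta   0.07297  (fear 0.0763, happy 0.0773, sad 0.0653)
#>   IMF5_Delta   0.04985  (fear 0.0652, happy 0.0677, sad 0.0167)
#>   ...
```

The validation accuracy (0.80) and test accuracy (0.89) of this single
50-window session are noisy; they stabilize once several sessions are
pooled (below).

One 130-s session yields ~50 windows; the numbers above come from that small
run. The generator plants its discriminative effect in the delta band of the
lowest-frequency mode, and the importance report recovers exactly that
feature (`IMF1_Delta`). At the test suite's full study scale — six sessions,
300 windows — the random forest reaches test accuracy ≈ 0.98 and the
ablation table's best single (IMF, band) cell is again `IMF1_Delta`.

A decomposition on its own:

```r
fs <- 128; t <- (0:(3 * fs - 1)) / fs
x <- cos(2 * pi * 2 * t) + cos(2 * pi * 24 * t)
vmd_decompose(x, fs, vmd_config(K = 2))
#> VMD decomposition: K = 2 modes, 384 samples
#>   center frequencies (Hz): 2, 24
#>   bandwidths (Hz):         0.0338, 0.184
#>   converged in 5 sweeps (residual 2.72e-09 )
```

A thin command-line wrapper over the same functions lives in
`inst/cli/vmdeeg.R` (subcommands `simulate`, `preprocess`, `decompose`,
`featurize`, `train`, `sweep`, `ablation`, `explain`, `run-all`).

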