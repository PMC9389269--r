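---
title: "Methods: multimodal acute-stress detection in stressfuse"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: multimodal acute-stress detection in stressfuse}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette explains the models and procedures in `stressfuse`, the
assumptions behind them, the tunable parameters and their defaults, what
the synthetic data generator does and does not emulate, and the numerical
and design choices made where the methodology left them open.

## The detection problem

Acute stress induced by a timed mental-arithmetic task alters heart
rhythm, voice production and facial dynamics simultaneously. The toolkit
treats detection as a three-stage classification — *calm*, *control*
(paced arithmetic) and *experimental* (time-pressured arithmetic) — whose
two arithmetic stages are collapsed to a single *stress* label for
evaluation, since both provoke the same acute response. Three
single-modality classifiers produce stage posteriors that a late-fusion
rule combines into one decision.

## ECG preprocessing and heartbeat relocation

**Denoising.** A biquad notch at 50 Hz (quality factor 30) removes mains
interference, and a band-pass keeps 0.5–50 Hz, where ECG energy is
concentrated, suppressing baseline wander and muscle noise. Both filters
run forward-backward (zero phase) so R-wave positions are not shifted.
The band-pass is realized as a 2nd-order Butterworth high-pass cascaded
with a 4th-order low-pass: a single 8th-order transfer-function band-pass
with a normalized low edge of 0.0005 (0.5 Hz at 2 kHz) is numerically
unstable and was observed to ring and amplify, which is why the cascade —
not a design preference — is used. The record is then z-scored, which
removes amplitude scaling so later thresholds are scale-free.

**R-peak detection.** Local maxima above `threshold_frac` (default 0.5)
times the global maximum of the standardized signal, deduplicated by a
250 ms refractory interval (physiologically no two R waves are closer);
the larger peak wins a refractory conflict.

**Relocation.** Excerpts cut by task timing start and end at arbitrary
phases of the cardiac cycle. Relocation re-cuts the segment at inter-beat
midpoints: the distance `T1` between the first detected R wave and its
unobserved predecessor is estimated from the short-term autocorrelation
of the 2 s of signal preceding it (reversed), and symmetrically `T2`
after the last peak. The autocorrelation `acf[k] = Σ x[n]x[n+k]`
(computed exactly via FFT, normalized so `acf[0] = 1`) is center-clipped
with `α = 0.1`, `β = −0.1`; normalizing first makes these thresholds
scale-free. The segment is then `[R1 − ⌊T1/2⌋, RN + ⌊T2/2⌋]`; midpoint
rounding is floor, and indices are 1-based throughout (the R convention —
the arithmetic of the rule is base-independent).

**First-harmonic selection.** The period is read off the clipped
autocorrelation as the lag of the maximum of the *first dominant positive
run* after the lag-0 main lobe: runs are scanned in lag order and the
first whose peak reaches 50% of the global post-lobe maximum is taken.
A simpler rule — take the first positive run unconditionally — fails on
realistic beat morphology: the R-to-T-wave cross-correlation survives
clipping as a weak run (~0.17 normalized) well before the true R-R peak
(~0.63), and biased period estimates by ~150 ms in our experiments. The
dominance requirement rejects such side lobes while lag-order scanning
still prefers the fundamental `P` over `2P`.

**Rendering.** The relocated segment is rasterized as an
amplitude-vs-time line plot into a 230 × 307 grayscale matrix (the 2D
classifier's input geometry), min–max scaled per segment, replicated to
three channels at the model input. Rendering is deterministic; line
width and styling are fixed because classification depends on the trace
shape, not plot cosmetics.

## Voice features

Audio is resampled to 16 kHz (fixing the frame geometry at 480-sample
windows, 240-sample hops, and the Mel bank span regardless of the
recording device), pre-emphasized (`y[n] = x[n] − 0.97 x[n−1]`), framed
with a 30 ms Hamming window advancing 15 ms (a 30 ms window with 15 ms
overlap — hop and overlap coincide at 50%), transformed by STFT to
*power* spectra, projected through 64 triangular Mel filters spanning
0–8 kHz (`m = 2595·log₁₀(1 + f/700)`), and compressed with
`log(1 + E/ε)`, `ε = 10⁻¹⁰`, which maps silence to exactly zero. The
matrix is rendered like the ECG image. 64 bands is a conventional
resolution that keeps the rendered image well conditioned; the frame
count obeys `⌊(len_ms − 30)/15⌋ + 1` exactly at 16 kHz.

## Face clips

Face detection is an *interface*: any `function(frame, index)` returning
a box and optional eye landmarks. Detectors are cited prior work, not a
contribution, so none is reimplemented; a deterministic stub replays
known boxes (the synthetic generator emits exact ones). With landmarks,
frames are aligned by a 2-point similarity transform to canonical eye
positions; without, the box is cropped and resized. Undetected frames
reuse the nearest detected frame's geometry, keeping one crop per input
frame. Training clips are 64 consecutive frames at a seeded random
offset; evaluation clips are the central window; sequences shorter than
64 are looped cyclically (looping preserves temporal statistics better
than padding with frozen or zero frames). Augmentation rescales to
224 × 270, crops 224 × 224 (random offset in training, center at
evaluation), and flips horizontally with probability ½ in training only —
one crop window and one flip decision shared by all 64 frames, because
per-frame jitter would corrupt the temporal signal the video net reads.

## Classifiers

Both backbones are built from one exact layer engine (im2col
convolutions, average/max pooling, identity-shortcut residual blocks
`y = F(x) + X`, inception blocks, global average pooling, softmax head);
gradients are analytic and verified against finite differences.

* the **residual 2D net** (ECG and Mel images): `tiny` = stem conv +
  two residual stages at widths 8/16 on 32 × 32 inputs; `full` follows
  the published 50-layer bottleneck layout (3+4+6+3 blocks).
* the **video net** (face clips): `tiny` = a pooling stem, one 3×3×3
  conv stage, the TAM, and two inception blocks on 32 × 32 × 64-frame
  clips; `full` follows the inflated inception-v1 layout (9 inception
  blocks).

**Temporal attention module.** `z_t` is the mean of frame *t* over
channels and space; `S = σ(W₂·ReLU(W₁·z))` with `W₁ ∈ R^{(T/r)×T}`,
`W₂ ∈ R^{T×(T/r)}`; the output rescales frame *t* by `S_t ∈ (0,1)` — a
per-frame contraction. The reduction ratio `r` is not prescribed by the
methodology; the default is 4, with hidden size `max(1, round(T/r))`
when `T/r` is not integral. The TAM sits after the first
convolution-and-pooling stage, before the first inception block, where
it can rescale the temporal information entering the inception stack;
the insertion index is configurable. Disabling it removes *only* the TAM
node: every other node keeps its name and, because each node draws its
initial weights from its own name-derived seed stream, its exact initial
values — which is what makes the ablation contract testable.

**Training.** Adam with cross-entropy over the three stages; weights are
initialized uniform-at-random (Glorot bounds). Each call splits its data
80/20 into train/validation (stratified, seeded) and returns the weights
with the best validation accuracy. Full-scale reference settings are
lr 10⁻⁴, batch 32, 80 epochs for the 2D nets and lr 0.01, single-clip
batches, 30 epochs for the video net; the desk-scale harness uses
lr 10⁻³/batch 8/30 epochs (2D) and lr 0.01/batch 2/15 epochs (video),
sized so a full run finishes in minutes on one CPU. Inputs are
standardized per sample (zero mean, unit variance): with raw all-positive
pixel intensities the first ReLU stage operates in a nearly linear
regime and global pooling averages the temporal signal away — the video
net demonstrably failed to learn without this, and it is standard
practice.

## Eigenvector fusion

The stage posteriors of voice, face and ECG form the columns of the
3 × 3 stress information matrix `M`. Its eigenvector for the
largest-magnitude eigenvalue — for a nonnegative column-stochastic
matrix, the Perron eigenvalue 1 — is sign-fixed to the nonnegative
orthant and L1-normalized into stage weights `w` (interpreted as stage
proportions, hence sum 1; the normalization convention is ours). The
decision is the stage with the largest absolute row sum of `diag(w)·M`,
ties broken toward the earlier stage for determinism. Inputs that are
not simplex-valid are rejected rather than coerced, which keeps the
Perron argument valid and avoids a complex-arithmetic branch. When the
leading eigenvalue is repeated (e.g. the all-uniform matrix), the
eigenvector is not unique and power iteration from the uniform vector
selects the symmetric fixed point.

Two properties worth knowing:

* *Unanimity*: if all three modalities assign probability 1 to stage
  *s*, the basis vector `e_s` is the Perron vector and the decision is
  *s*.
* *Label permutation is not exactly neutral*: relabeling stages maps
  `M` to `PM` (a row permutation), and the Perron vector of `PM` is not
  `P` times that of `M`. On random stochastic matrices the decision
  follows the permutation in ~97% of cases; it is exact for unanimous
  and equal-posterior matrices. This asymmetry is inherent to the
  fusion rule, not an implementation artifact, and the tests assert
  exactly that.

Single-modality binary predictions use the same path's convention:
argmax over the three stages, then collapse control/experimental to
stress.

## Synthetic data

The generator produces, per sample and from a single seed:

* **ECG** (2 kHz, 10 s): Gaussian R waves flanked by smaller P/T bumps at
  intervals drawn per class — calm 60–75 bpm with 20 ms beat-to-beat
  jitter; control 85–100 bpm / 35 ms; experimental 100–120 bpm / 45 ms —
  plus white noise at 20 dB SNR and a faint 50 Hz hum. Exact R positions
  are emitted as truth. A parametric template is used *because* exact
  truth is required; no dynamical P-QRS-T model is attempted.
* **Voice** (16 kHz, 2 s): a harmonic tone at a class fundamental
  (120/180/220 Hz) with harmonic rolloff `1/h^tilt`
  (tilt 1.5/1.0/0.8 — flatter under stress, raising the spectral
  centroid), slow amplitude modulation and noise.
* **Video** (30 fps, 90 frames, 48 × 64): a textured face patch whose
  mouth region oscillates at 0.5/1.5/2.5 Hz with amplitude 0.2/0.5/0.7.
  The frequencies sit below the tiny video net's post-pooling Nyquist
  (3.75 Hz), and amplitude grows with stress (more facial motion), so
  both spectral and energy cues carry class information. Exact per-frame
  boxes are emitted for the stub detector.

Stress-class heart rates are strictly above the calm range by
construction, so a threshold on true mean R-R separates calm from stress
with no error — if the end-to-end pipeline fails on this data the
pipeline is at fault, not the data. That is also the honest limit of
what passing shows: the generator emulates the class-dependent
*structure* of real signals, not their morphology, inter-subject
variability, detector noise, or label ambiguity, so synthetic accuracy
says nothing about accuracy on clinical recordings.

For estimator benchmarking (R-R recovery), records are generated with
heart rate uniform in 60–120 bpm, 20 dB SNR and 3 ms jitter: the
benchmark isolates estimator noise, and the short-window autocorrelation
by definition assumes local periodicity; class-level jitter defaults are
deliberately larger and unrelated to this benchmark.

## Evaluation harness

`make_folds()` builds stratified k-fold plans (per-fold class balance
within one sample) with the inner 80/20 train/validation split.
`evaluate()` reports accuracy, precision, recall and F1 with *stress* as
the positive class (detection of the condition is the target), plus the
raw 2 × 2 confusion matrix and a column-normalized form (each
predicted-label column sums to 1, matching how such confusion tables are
commonly presented). Metrics always recompute exactly from the stored
confusion matrix.

`run_end_to_end()` preprocesses every sample once, trains the three
tiny classifiers per fold, fuses test-sample posteriors, and reports
pooled and per-fold metrics. The desk-scale defaults — 60 samples,
3 folds, 32 × 32 inputs, 64-frame clips — are chosen so the whole run
takes a few minutes on one CPU; k = 10 plans are fully supported and
exercised by the harness tests. Fold means and pooled metrics are both
reported since averaging conventions differ between studies. The
`report` component is a pure function of the configuration seed
(bit-identical across reruns); wall-clock timings per stage
(preprocessing / feature extraction / fusion) are informative and kept
in a separate `timing` component precisely so the report can be
compared byte-for-byte.

## Known limitations

* The full-size backbones are instantiable and layout-correct but not
  trained by the test suite; no pretrained weights ship with the package.
* The fusion rule's label asymmetry (above) means near-tied matrices can
  flip decisions under relabeling.
* The WAV reader/writer covers mono PCM 8/16/32-bit and float — enough
  for the toolkit's exchange needs, not a general audio library.
* Heartbeat relocation assumes at least 2 s of recorded context around
  the boundary R waves; excerpts without it are rejected (the
  preprocessing driver drops context-less boundary peaks first).
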