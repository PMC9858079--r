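---
title: "Methods: from single-lead ECG to rhythm-labeled time-frequency images"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from single-lead ECG to rhythm-labeled time-frequency images}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(beatgram)
```

beatgram turns a single-lead electrocardiogram into a set of per-wave
time-frequency images labeled by rhythm class, suitable for training an image
classifier to discriminate normal sinus rhythm (60–100 bpm) from bradycardia
(< 60 bpm) and tachycardia (> 100 bpm). This vignette documents the models,
the tunable parameters, and the numerical decisions behind each stage, and is
the authoritative account of *why* the defaults are what they are.

## The synthetic generator and what it emulates

Real annotated ECG archives ship fiducial annotations of limited precision
and license-encumbered bulk data. To make every stage of the pipeline
testable against exact ground truth, `synthesize_record()` generates
single-lead signals from a parametric beat model:

$$x(t) = \sum_{w \in \{P,Q,R,S,T\}} a_w \exp\!\left(-\frac{(t - c_w)^2}{2\sigma_w^2}\right),$$

a sum of five Gaussian deflections, the standard morphology-only reduction of
the ECGSYN family of dynamical models. Defaults follow typical adult lead-II
values: $a_P = 0.25$ mV, $a_R = 1.6$ mV (the dominant deflection),
$a_T = 0.3$ mV, $a_Q = a_S = -0.15$ mV, with centers at $-160$, $-28$, $0$,
$28$, $190$ ms relative to R and widths of 20, 9, 12, 9, 35 ms. The default
sampling rate is 360 Hz, a common archival rate for single-lead rhythm data.

Two deliberate choices make the ground truth *exact* rather than approximate:

* **Truncated support.** Each deflection is zeroed where its magnitude falls
  below 1% of its own peak (`onset_frac = 0.01`). The onset and offset of a
  wave are then analytic, $c_w \pm \sigma_w\sqrt{-2\ln 0.01}$, and — because
  the signal is *exactly* zero between waves — they coincide to within one
  sample with what a zero-crossing scan of the sampled waveform finds.
  Without truncation, the overlap of the S and T tails moves the S–T zero
  crossing tens of milliseconds away from any threshold-based definition of
  the T onset, and "ground truth" becomes a matter of convention. The 1%
  step this introduces (at most 16 µV at the R wave) is far below the noise
  floor of any physical recording.
* **Rate-adaptive timing.** Centers and widths are scaled by
  $\sqrt{RR / RR_{\mathrm{ref}}}$ with $RR_{\mathrm{ref}} = 60/72$ s, the
  familiar square-root shortening of cardiac intervals (Bazett's correction
  applied in reverse). This serves physiology and geometry at once: beats
  physically fit inside the RR slot at tachycardic rates, and the three
  rhythm classes differ in wave duration and spectral content the way real
  rate changes do — which is what makes per-wave images informative about
  rate class at all. Disable with `rate_adapt = FALSE`.

Beats are placed strictly periodically at $RR = 60/\mathrm{bpm}$, centered in
their RR slot when they fit, with optional seeded Gaussian RR jitter
(`rr_jitter_sd`, default 0) to emulate the small respiratory variation of
sinus rhythm. Rates whose beat extent exceeds 98% of the RR interval are
rejected rather than overlapped; with the default template this admits the
full 40–180 bpm range.

The noise model (`noise_spec()`) adds the three classes of contamination the
preprocessing stage is designed to remove: a baseline-wander sinusoid
(default 0.3 Hz), a power-line sinusoid (50 or 60 Hz), and white broadband
noise, all seeded and reproducible.

What the generator does **not** emulate — and hence what passing tests do not
establish about real data: ectopic and arrhythmic morphologies beyond rate
change, atrial fibrillation, biphasic or inverted T waves, electrode-motion
artefacts (which are impulsive, not Gaussian), QRS morphology variation
between beats, and multi-lead geometry. Results on this generator bound the
pipeline's *correctness*, not its clinical performance.

## Preprocessing

`bandpass_filter()` implements the diagnostic 0.5–40 Hz band as a cascade of
a 4th-order Butterworth high-pass and a 10th-order Butterworth low-pass,
each run forward–backward (zero phase). Three numerical points:

* Zero-phase filtering preserves fiducial timing exactly — a causal filter
  of this order would shift wave onsets by tens of milliseconds.
* Forward–backward application squares the magnitude response, so a filter
  designed naively at the band edges would be −6 dB there and its measured
  −3 dB cutoff would sit ~10% inside the band. The design cutoffs are
  therefore pre-shifted by $(\sqrt 2 - 1)^{-1/2n}$ in the tan-prewarped
  analog domain so the *net* response is −3 dB at 0.5 and 40 Hz. The
  low-pass order (10) is the smallest round value for which the net response
  is also ≥ 20 dB down at 50 Hz, the nearer power-line frequency; a
  4th-order edge cannot satisfy both constraints at once.
* The signal is mirror-padded by up to 5 s before filtering. The 0.5 Hz
  high-pass edge has a multi-second settling time, and without padding the
  start-up transient leaks well into a 10-s record.

`wavelet_denoise()` decomposes the signal into nine levels with the
orthonormal Daubechies-8 filter bank (periodized boundary handling,
implemented in the package; the filter taps are the published db8
coefficients, cross-checked against an independent reference implementation
on a frozen fixture). Denoising follows standard wavelet practice: soft
thresholding of detail levels 1–2 with the universal threshold
$\sigma\sqrt{2\ln N}$, $\sigma$ estimated from the level-1 details by
MAD/0.6745 — broadband noise lives almost entirely in the two finest levels
at 360 Hz. The level-9 approximation (below ~0.35 Hz) is zeroed to remove
residual baseline wander. Signals whose length is not a multiple of $2^9$
are mirror-padded to the next valid length and cropped after reconstruction.
With thresholding disabled the transform reconstructs to machine precision;
with it enabled, distortion on a clean beat is held under 2% RMS of the peak.

`normalize_amplitude()` divides by $\max|x|$. Max-absolute scaling (rather
than min–max to $[0,1]$) is essential: it preserves the zero baseline and the
exact indices of all zero crossings, which the delineator consumes.
`trim_record()` crops half the first and last RR intervals outside the
outermost R peaks (integer floor division, clamped to the record), so a
conforming record starts with a P wave and ends with a T wave.

The pipeline order is filter → denoise → normalize → trim
(`preprocess_record()`). Normalizing last-but-one means the unit peak refers
to the cleaned signal; each stage is exposed separately for other orderings.

## Delineation

`detect_r_peaks()` is the classic Pan–Tompkins chain — 5–15 Hz band-pass,
five-point derivative, squaring, 150 ms moving-window integration — with the
standard adaptive dual threshold (signal/noise running estimates, threshold
at $NPK + 0.25(SPK - NPK)$), a 200 ms refractory period, and an RR-based
search-back at half threshold. Both the band-pass and the integration window
are applied symmetrically (zero phase), and each detection is refined to the
signal maximum within ±100 ms, so reported indices sit on the R apex itself.
Thresholds adapt multiplicatively, making detection invariant to positive
rescaling of the input.

P and T peaks are the signal maxima in RR-scaled windows:
$[R - 0.35\,RR_{\mathrm{prev}},\ R - 60\ \mathrm{ms})$ to the left and
$(R + 80\ \mathrm{ms},\ R + 0.6\,RR_{\mathrm{next}}]$ to the right. The
fractions cover typical P and T timing across 40–180 bpm while the fixed
guard gaps keep the QRS complex itself out of both windows; all four numbers
are arguments of `locate_p_t_peaks()`. Beats whose windows leave the record
(first/last beats of a short record) are dropped rather than guessed.

Wave bounds use zero crossings on the zero-baseline preprocessed signal:

* **P and T** (`find_wave_bounds()`): scan outward from the peak until the
  sign differs from the peak's (an exact zero counts); report the far-side
  sample; clamp to the record boundary with a flag if no crossing exists.
* **Q and S** are the signal minima within 80 ms before/after R — a
  definition the windowed-search literature leaves implicit.
* **QRS bounds** (`find_qrs_bounds()`): the *last* zero crossing in
  $[P_{\mathrm{off}}, Q)$ is the QRS onset and the *first* crossing in
  $(S, T_{\mathrm{on}}]$ the QRS offset. "Search forward for the last
  crossing" is self-contradictory as a scan direction; it is resolved here as
  "the last crossing in the window", which is scan-order independent. For
  these two bounds the sample on the *QRS side* of the crossing pair is
  reported, so on the generator's truncated beats the detected bound lands
  exactly on the analytic fiducial. Windows without a crossing fall back to
  the window boundary, flagged.

`delineate_beats()` composes the above and enforces the strict ordering
$P_{on} < P_{peak} < P_{off} \le QRS_{on} < Q < R < S < QRS_{off} \le T_{on}
< T_{peak} < T_{off}$, dropping (and counting) violating beats. All indices
throughout the package are 1-based R indices; per-wave segments are the
right-open integer ranges $[on, off)$, and segments shorter than 3 samples
are dropped.

## Time-frequency representations

**Spectrogram** (`stft_spectrogram()`): Hann window of length
$\min(64, \lceil n/4\rceil)$ rounded up to even (at least 4), 75% overlap,
zero-padded to a 256-point DFT so even short P segments get a readable
frequency axis. The PSD is one-sided and density-scaled,
$|X|^2 / (f_s \sum w^2)$ with interior bins doubled, so
$\sum \mathrm{PSD}\,\Delta f\,\Delta t$ approximates signal energy (verified
to 10% in the tests). Window parameters are arguments; these defaults trade
frequency resolution against the very short segments the delineator emits.

**Irisgram** (`irisgram()`): the spectrogram re-plotted in polar
coordinates. Amplitudes go to decibels, $Z = 10\log_{10}(\mathrm{PSD} +
\varepsilon)$ with $\varepsilon = 10^{-12}$ as a floor for exact zeros, hard-
clipped to the fixed display range $[-120, 120]$ dB. Geometry: $\theta$ spans
$[-\pi, \pi]$ in exactly $T$ uniform steps ($T$ = number of time frames),
$\rho = \max(f)/3 + f$ — the $\max(f)/3$ offset is the central "pupil" that
gives the representation its name — and $X = \rho\cos\theta$,
$Y = \rho\sin\theta$ on the outer-product grid, so every grid point satisfies
$X^2 + Y^2 = \rho^2$ and the surface lives in the closed annulus
$[\max(f)/3,\ 4\max(f)/3]$.

**Scalogram** (`cwt_scalogram()`): the magnitude surface $|W(a, b)|$ of the
continuous wavelet transform. (The defining norm-of-coefficients expression
is interpreted as exactly this — the modulus of the CWT coefficient at each
scale/translation — the one reading under which it is a well-defined
surface.) The mother wavelet is the analytic Morlet with center frequency
$f_c = 0.8125$ cycles/sample, evaluated in the frequency domain with
$\sqrt a$ (L2) normalization, so a scale $a$ responds to $f_c f_s / a$ Hz and
rescaling the input by $c$ rescales every coefficient by $c$. Each wave type
gets its own scale vector — 64 logarithmically spaced scales covering the
wave's characteristic band: P 5–30 Hz, QRS 8–50 Hz, T 0–10 Hz with the lower
edge clamped to 0.5 Hz, since scale diverges at DC. Scales are further
clamped to $[1, 2n]$ samples (warning emitted): a 0.5 Hz analysis scale is
several times longer than a T segment, and coefficients at such scales carry
no localized information. In practice a T segment at 360 Hz is analysed from
roughly 2 Hz upward.

## Image rendering and dataset assembly

`render_image()` maps a representation to a 224 × 224 × 3 8-bit array — the
input geometry of the standard ImageNet-family classifiers. Values are
min–max normalized **per image** and passed through a fixed 256-level
perceptually uniform colormap (viridis; configurable but pinned in tests).
Per-image scaling mirrors what autoscaled surface plots do and maximizes
contrast for weak waves; the cost is that absolute amplitude is not
comparable across images, which is acceptable because class information here
lives in time-frequency *shape*. A degenerate all-equal matrix renders as a
uniform image. Rectangular matrices are bilinearly resized; the irisgram is
rendered as a top-down orthographic projection of its annular surface
(nearest-neighbor lookup in $(\rho, \theta)$ per output pixel), since a 2-D
classifier consumes the overhead view of the 3-D surface anyway. Rendering
is fully deterministic: the same representation yields byte-identical PNGs.

`build_dataset()` delineates each record, extracts one wave kind, renders
one representation per segment into class-named subdirectories, and returns
a manifest. `split_dataset()` performs a stratified 70/30 split (exact per
class up to rounding; a singleton class goes to train with a warning);
`kfold_split()` deals each class round-robin into 5 near-equal folds. Both
are seeded. Splits stratify by class only — beats from one record can land
on both sides, mirroring beat-level dataset counts. For subject-level
generalization claims, group by `record_id` before splitting; the manifest
carries the column precisely so that leakage-free splits are possible.

## Classification and evaluation

The evaluation protocol is the package's contract; the classifier is a
pluggable stand-in. `classifier_spec()` offers a single-hidden-layer
perceptron (default: 16 hidden units, weight decay $10^{-3}$, full-batch
BFGS, on 16 × 16 grayscale downsampled pixels), multinomial logistic
regression, and a majority-class baseline. The default is deliberately small:
the synthetic classes differ in smooth, global image structure, and a compact
model keeps training deterministic (fixed-seed weight initialization,
order-independent full-batch optimization) and fast on one CPU. Large
pretrained convolutional networks are out of scope; any model exposing the
same train/predict surface can be plugged in, and probability ties are broken
by class order.

`confusion_matrix()` / `class_report()` compute the standard quantities, in
percent: per-class sensitivity $100\,C_{ii}/\sum_j C_{ij}$, precision
$100\,C_{ii}/\sum_j C_{ji}$ (undefined — `NA`, flagged — for never-predicted
classes), per-class misclassification $100 - \text{sensitivity}$, and overall
accuracy $100\,\mathrm{tr}(C)/\sum C$. Per-class specificity is deliberately
not part of the report. Printing rounds to one decimal; stored values are
full precision. `summarize_kfold()` reports mean ± sample (n−1) standard
deviation of macro-averaged sensitivity, macro-averaged precision and
accuracy across folds.

## Problem sizes and verification scale

The test suite exercises the pipeline at the scale the method itself is
specified at: 10-s records at 360 Hz (the archival segment length the
pipeline targets), rates 40/72/140 bpm for the three classes, and an
end-to-end dataset of ≥ 60 beats per class (10/5/3 records respectively)
rendered as T-wave scalograms, split 70/30, and classified with the default
perceptron. Fiducial recovery is asserted at ±20 ms (95% of fiducials),
R-peak recall/precision at ≥ 0.95 under 10 dB SNR broadband noise with 50 ms
tolerance, and end-to-end test accuracy at ≥ 90%. These sizes were chosen as
the smallest at which each claim is meaningfully testable.

## Known limitations

* The generator's Gaussian beats are smoother than real ECG; detectors tuned
  here may need window adjustments for notched QRS or biphasic T waves.
* Zero-crossing delineation presumes the zero-mean baseline that the
  preprocessing establishes; applied to raw, drifting signals it degrades
  gracefully but without guarantees.
* Per-image color scaling discards absolute amplitude; rhythm classes are
  separable without it, amplitude-based pathologies would not be.
* The default beat-level split measures within-record generalization only.
* File I/O is plain CSV (signal and annotation sidecars); binary waveform
  archive formats are outside the package's scope.
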