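---
title: "Decoding hand-movement direction from fNIRS: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Decoding hand-movement direction from fNIRS: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(nirsdirect)
```

## The scientific problem

Functional near-infrared spectroscopy (fNIRS) measures cortical
hemodynamics through the scalp: light at two wavelengths (760 and 830 nm)
is injected by sources and collected by detectors, and changes in optical
attenuation reflect changes in oxy- (HbO) and deoxyhemoglobin (HbR)
concentration in the sampled tissue. Because fNIRS is portable and immune
to electromagnetic noise, it is an attractive recording modality for
brain-machine interfaces — *if* its spatial resolution and signal-to-noise
ratio suffice to resolve parameters of movement beyond gross laterality.

This package implements a complete analysis chain for the hardest version
of that question at sensor level: can the *direction* of unilateral hand
movements (e.g. leftward vs. downward wrist movements of the right hand)
be decoded from single trials of multi-channel fNIRS recorded over
sensorimotor cortex? The chain covers:

1. **Geometry** — montage representation, enumeration of source-detector
   channels, distance-based channel classes, projection of the 3D optode
   patch onto a least-squares plane for mapping.
2. **Synthetic sessions** — a generative forward model with known ground
   truth, so every downstream stage is testable without recorded data.
3. **Preprocessing** — Butterworth low-pass filtering, trial epoching,
   modified Beer-Lambert (MBLL) conversion to ΔHbO/ΔHbR, and two-step
   channel selection.
4. **Topography** — trial-averaged responses, direction-contrast SNR per
   channel, and triangulated linear interpolation into sensor-space maps.
5. **Decoding** — shrinkage-regularized linear discriminant analysis
   (RLDA) under repeated stratified cross-validation, resolved over trial
   time, with exact binomial significance and FDR correction across
   subjects.
6. **Head-tracking control** — the same preprocessing and decoding applied
   to 6-DOF head-motion traces, the key control separating cortical
   hemodynamics from motion artifacts.

## The forward model behind the synthetic generator

`generate_session()` simulates one recording session. Its defaults are
the study conditions the rest of the package is validated against: 30
trials per direction (left, down), 10 s movement blocks, a 2-4 s uniform
preparation jitter, optical sampling at 7.94 Hz, head tracking at 30 Hz,
and a 32-optode montage (9 co-located sources, 23 detectors; 288
source-detector channels) with a dense patch over contralateral
sensorimotor cortex.

For every *contralateral long-distance* channel \(k\) (source-detector
distance 2.5-5.2 cm over contralateral sensorimotor cortex) the clean HbO
response to a trial of direction \(d\) is

\[
\Delta \mathrm{HbO}_k(t) = s_k \, g_k(d)\, a_i \, (h \ast B)(t),
\]

where \(B\) is the 10 s movement boxcar, \(h\) a double-gamma hemodynamic
response kernel (`hrf_kernel()`, peak 6 s, 15% undershoot), \(s_k\) a
per-channel scale (U(0.7, 1.3)), \(a_i\) a per-trial lognormal amplitude
jitter (sd 0.2), and \(g_k(d)\) the direction gain. On *tuned* channels
(half of the contralateral long-distance channels by default) the gain
splits a channel-specific contrast \(c_k\) around 1:
\(g_k = 1 \pm c_k/2\), with \(c_k = \texttt{tuning\_gain} \times
U(0.5, 1.5)\) and half the tuned channels preferring each direction —
mirroring the empirical observation that some channels respond more to
one direction and some to the other. Untuned responding channels have
\(g_k \equiv 1\): they see the movement but not its direction. HbR is a
delayed (1 s), negatively scaled copy
(\(\Delta \mathrm{HbR} = -0.35\, \Delta \mathrm{HbO}\)).

Physiological noise enters in the attenuation (log-intensity) domain, as
extra-cortical physiology does in real recordings: cardiac (1.1 Hz),
respiratory (0.3 Hz) and Mayer-wave (0.1 Hz) oscillations, a random-walk
drift, and white noise, each with a shared (all-channel) component and
per-channel replicas with independent phases and slightly jittered
frequencies. Amplitudes are expressed in µM·mm HbO-equivalents (defaults:
5, 8, 10, drift 8, white 3 against a 30 µM·mm peak response), which a
scientist would recognise as a moderately noisy but usable recording. The
intensity model is then

\[
I(\lambda, t) = I_0 \exp\{-\varepsilon(\lambda,\mathrm{HbO})\,
\Delta\mathrm{HbO}(t) - \varepsilon(\lambda,\mathrm{HbR})\,
\Delta\mathrm{HbR}(t) - \mathrm{noise}(\lambda, t)\}.
\]

The trial *sequence* is a single balanced pseudo-random permutation (30
trials per direction in random order). Sequence design interacts
measurably with cross-validated null accuracy on autocorrelated data: a
global permutation can, by chance, place more trials of one direction
early and the other late, letting slow noise inflate single-subject null
accuracies by a few points, while tightly *blocked* sequences
over-correct and bias cross-validation below chance (trials adjacent in
time share noise across classes, the well-known below-chance CV
phenomenon). The global permutation is the milder and more conventional
of the two; its residual bias averages to well under a percentage point
at cohort level, which is what the chance-level calibration asserts.

Head motion: the 6-DOF trace contains slow wander plus sensor noise, and
— when `direction_coupling` is on, the default — small direction-locked
oscillations at the 0.25 Hz movement frequency during movement blocks
(yaw and lateral translation for left/right, pitch and vertical for
down/up; 1.5° and 0.3 cm by default, well under the "small movements"
regime of <1 cm, <3°). Critically, `motion_to_optics_gain` defaults to 0:
small head movements do *not* couple into the optical channels. The
`session = 2` preset emulates the motion-control session — voluntary,
roughly three-fold larger coupled head movements and *no* hand movement,
hence no cortical response at all.

### What the generator does and does not emulate

It emulates the statistical structure that the pipeline's claims rest on:
direction-tuned amplitudes confined to contralateral long-distance
channels, hemodynamic latency, realistic noise spectra, and head motion
correlated with — but optically decoupled from — the task. It does *not*
model photon transport, scalp-coupling optics, per-subject anatomical
variability beyond parameter jitter, or waveform-level tuning (an
optional latency-shift mode was considered and left out: amplitude
contrast is the simpler mechanism and suffices for every property tested
here). Passing tests on synthetic data therefore show the *pipeline* is
correct and calibrated; they do not show that real cortex carries this
much directional information. The default `tuning_gain = 0.3` makes
tuned channels clearly detectable; the empirically realistic regime of
weak tuning is reached by lowering it (the package's tests probe gains
down to 0.03).

## Preprocessing choices

**Filtering.** 3rd-order Butterworth low-pass. Offline analyses use
acausal (forward-backward, zero-phase) filtering at 0.15 Hz; the decoding
branch uses a causal single pass at 0.12 Hz — the corrected cutoff
compensating the single pass's earlier -3 dB point — because a real-time
interface cannot see the signal's future. 0.3 and 0.5 Hz variants are
supported. The corrected-cutoff derivation itself is not re-implemented;
0.12 Hz is a configured constant. The causal filter is initialised at the
signal's first value so that the start-up transient decays from zero
rather than from the intensity's DC level.

**Pipeline order** is fixed: filter the continuous recording, then epoch,
then convert. Filtering epoched segments instead would hit the filter
transient within every trial; a regression test asserts the orders are
*not* equivalent.

**Epoching.** Every trial spans 6 s before movement onset (MO) to 25 s
after movement end (ME); nothing is rejected. Sample counts use
round-half-away-from-zero: at 7.94 Hz a 41 s window is exactly
`round(41 * 7.94) + 1 = 327` samples. The baseline is the mean over
\([-1, 0)\) s — closed-open, strictly before MO.

**MBLL conversion.** Per trial, channel and wavelength:
\(\Delta A(t) = -\log(I(t)/\bar I_{\text{baseline}})\), then
\((\Delta\mathrm{HbO}, \Delta\mathrm{HbR}) = \varepsilon^{-1} \Delta A\)
with a 2×2 extinction matrix. No differential-pathlength division is
applied, so outputs are concentration × pathlength in µM·mm. The packaged
extinction values are natural-log molar absorption coefficients converted
from the standard Prahl hemoglobin compilation to (µM·mm)⁻¹; they are a
documented stand-in for the historical tabulation average, and the table
is replaceable (`extinction_table(matrix = ...)`). Channels with any
non-positive intensity ratio (which would make the logarithm complex) on
any trial are *flagged* invalid, never silently dropped.

A subtlety worth knowing: the baseline is the mean *intensity*, so when
the baseline window still contains decaying response from the previous
trial, the recovered concentrations differ from "truth minus mean truth"
by a Jensen (geometric- vs arithmetic-mean) gap of order
\(\tfrac{1}{2}\mathrm{var}(\Delta A)\) over the window — around
\(10^{-5}\) µM·mm for tightly packed noise-free trials, i.e. harmless,
but the package's exactness test uses well-separated trials where the
inversion is exact to machine precision.

**Channel selection** is two-step: validity first, then the distance
window — closed on both ends, default [2.5, 5.2] cm (long-distance,
cortex-penetrating), with [0, 2] cm as the scalp-only short-distance
control class.

## Topographic maps

The contralateral optode positions are projected onto their least-squares
best-fit plane (scores on the two leading principal axes; axis signs are
fixed by making the largest-magnitude loading positive, so maps are
reproducible). Channels sit midway between source and detector. The
direction-contrast SNR of a channel is

\[
\mathrm{SNR} = \frac{|\bar l - \bar d|}{\hat\sigma}, \qquad
\hat\sigma = \mathrm{sd}\{\text{trials with their own direction's mean
subtracted, both directions pooled}\},
\]

with the sample (n−1) standard deviation, computed per time point and
averaged over ME ± 1 s by default (the window is configurable down to a
single sample; whether a window statistic or per-time-point convention is
meant was left open by the source description — the per-time-point
convention is adopted and documented here). Maps use piecewise-linear
barycentric interpolation on a Delaunay triangulation of the channel
midpoints, exact at the data points and masked outside the convex hull.
The triangulation is computed by exhaustive circumcircle testing — cubic
in the channel count, exact, and entirely adequate at montage scale.

## Decoding

**Classifier.** RLDA with the pooled within-class covariance shrunk
toward a scaled identity, \(\Sigma(\lambda) = (1-\lambda)\Sigma +
\lambda\,(\mathrm{tr}\,\Sigma/d)\, I\). This one-parameter scheme is the
standard specialisation of Friedman-style regularised discriminant
analysis used throughout the BMI literature; with ~35 feature channels
and ~54 training trials per fold, plain LDA is at the edge of
invertibility, and shrinkage is what makes single-time-point decoding
stable. `lambda = "auto"` selects over the grid {0, 0.01, 0.05, 0.1,
0.25, 0.5, 0.75, 1} by stratified 5-fold cross-validation *inside the
training set*; no held-out information reaches the hyperparameter.
Prediction ties (exactly equal discriminant scores) break
deterministically to the lexicographically smallest label.

**Cross-validation.** Label-stratified 10-fold CV, repeated (5 by default
for time-resolved curves, 10 for single-time-point analyses — both within
the conventional 5-10 range; the smaller default keeps a 327-point curve
at roughly 16000 classifier fits). DA is the percentage of correctly
decoded trials pooled over folds, averaged over repeats. Time-resolved
decoding runs an independent CV at every epoch sample, using per-channel
amplitudes (HbO, HbR, or both concatenated; optionally a sliding window
of consecutive samples) as features. The time-resolved default is a fixed
`lambda = 0.25`: a moderate a-priori shrinkage involves no data-driven
selection at all and decodes a full curve in seconds, while `"auto"`
remains available where the extra nesting is wanted.

**Significance.** For \(t\) targets and \(n\) decoded trials the chance
tail probability of \(k\) correct predictions is the exact binomial sum
\(p(k) = \sum_{j=k}^n \binom{n}{j} t^{-j} (1-1/t)^{n-j}\); the
significance level is \(l = 100\,k^*/n\) with \(k^*\) the smallest
count whose tail probability does not exceed \(\alpha\) (attaining
\(\alpha\) counts as significant, which makes \(\alpha = 1\) degenerate
to \(l = 0\) as expected). Peak-DA extraction smooths the DA curve with
an acausal 0.5 Hz low-pass, takes the maximum in the 5-20 s window after
MO, converts the smoothed DA back to a correct-trial count by rounding
*down* (conservative), and corrects across subjects by
Benjamini-Hochberg FDR. Group-level thresholds pool trials across
subjects.

## The head-tracking control

The 30 Hz 6-DOF trace is resampled to 7.94 Hz by anti-aliased rational
resampling — a zero-phase Butterworth band-limit below the output
Nyquist followed by spline evaluation on the exact rational grid
(7.94/30 = 397/1500) — then filtered, epoched and
baseline-referenced *identically* to the fNIRS branch (the tracker is
assumed to share the fNIRS causal filter spec, the natural reading of
"processed exactly alike"), and decoded with the same RLDA machinery on
the six position/orientation features. Orientation stays in degrees; no
quaternion handling, since the device reports Euler-like angles.

The control logic is a dissociation of *time courses*: head-motion DA
rises within a second or two of MO and plateaus until ME (motion is
locked to the movement itself), whereas fNIRS DA rises with hemodynamic
latency several seconds after MO and persists past ME. On synthetic
session-1 analogues (hand tuning on, small coupled head motion on,
optical coupling zero) the tests assert exactly this ordering of
threshold crossings; on session-2 analogues (head motion only) the
tracker decodes above 80% while the fNIRS curve never leaves the exact
binomial chance band.

## Numerical and degenerate-input conventions

- Round-half-away-from-zero for window-to-sample conversion (base R's
  `round()` is round-half-even, which would shift exact half-sample
  windows by one sample).
- Zero pooled SNR denominator (noise-free degenerate input) reports
  SNR 0 with a warning instead of dividing by zero.
- Collinear point sets are rejected (rank check against the leading
  singular value) before plane projection or triangulation.
- Empty channel selections warn rather than error: an empty long-distance
  set on a valid recording is an analysis outcome, not a crash.
- `binomial_p()` is evaluated through the regularised incomplete beta
  machinery of `pbinom`, stable to \(n \gg 10^4\); tests pin it to exact
  coefficient sums and Monte-Carlo simulation.
- All simulation, fold and subset randomness is seeded; identical
  configuration and seed reproduce a run bit-for-bit.

## Problem sizes used in the packaged checks

The test-suite calibration runs use the full study design: 10 simulated
null subjects (30 trials per direction, 288-channel montage, ~66
contralateral long-distance channels) for the chance-level check, a
5-point tuning-gain ladder with two subjects per gain decoded over the
8-16 s response window, twelve subjects for the control-channel checks
(single-subject epoch-mean null accuracies scatter with a standard
deviation near 4 percentage points, so a dozen are needed to pin the
cohort mean to ~1 point), and one session-2 analogue for the motion
dissociation. Orchestration
tests use a reduced 12-optode montage and 8 trials per direction, which
exercises every code path at a fraction of the cost.

## Known limitations

- Sensor-space only: no image reconstruction, no registration beyond the
  four region tags; the montage coordinates are a synthetic emulation of
  a typical arrangement, not digitised positions.
- No motion-artifact *correction* (spline, wavelet, or short-channel
  regression); short channels serve as a control comparison only, which
  is the design being emulated.
- The generator's direction tuning is amplitude-only; waveform-level
  tuning would require a richer model than the claims tested here need.
- Null-calibration accuracy assumes the block-balanced trial sequence;
  fully random sequences combined with strong drift can push null DA a
  few points above chance (a property of cross-validated decoding on
  autocorrelated data, not of this implementation).
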