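# nirsdirect

Single-trial decoding of hand-movement **direction** from functional
near-infrared spectroscopy (fNIRS), with the full analysis chain around
it: modified Beer-Lambert conversion of raw two-wavelength intensities to
hemoglobin concentration changes, Butterworth filtering and trial
epoching, distance-based channel selection, direction-contrast SNR
topographies, time-resolved shrinkage-LDA decoding with exact binomial
significance testing, and a head-tracking control branch that rules out
motion artifacts. A synthetic session generator with known ground truth
makes every stage testable end to end.

The package is aimed at researchers in optical neuroimaging and
brain-machine interfacing who want a tested, reproducible reference
implementation of this analysis style — and a simulator to calibrate it
against.

## The method in brief

A session delivers raw light intensities $I(\lambda, t)$ at
$\lambda \in \{760, 830\}\,$nm for every source-detector channel, an
event table of 10 s movement blocks (directions left/down), and
optionally a 6-DOF head-tracking trace. The pipeline:

1. **Filter** the continuous intensities (3rd-order Butterworth; causal
   0.12 Hz for decoding, acausal zero-phase 0.15 Hz for maps).
2. **Epoch** every trial from 6 s before movement onset (MO) to 25 s
   after movement end (ME); no trial rejection.
3. **Convert** via the modified Beer-Lambert law:
   $\Delta A = -\log(I/\bar I_{\text{baseline}})$, then
   $(\Delta\text{HbO}, \Delta\text{HbR}) = \varepsilon^{-1}\Delta A$ in
   µM·mm, baseline = mean over the second before MO. Channels producing
   complex values are flagged invalid.
4. **Select** valid channels with source-detector distance 2.5–5.2 cm
   (long-distance, cortex-penetrating; 0–2 cm short-distance channels
   serve as a scalp-only control).
5. **Decode** direction at every epoch sample with regularized LDA
   (pooled covariance shrunk toward $(\mathrm{tr}\,\Sigma/d)I$) under
   repeated stratified 10-fold cross-validation, giving a decoding
   accuracy curve DA(t).
6. **Test** against chance 100/t % with the exact binomial tail
   $p(k) = \sum_{j\ge k}\binom{n}{j}t^{-j}(1-1/t)^{n-j}$; peak DA is
   extracted from the 0.5 Hz-smoothed curve in the 5–20 s window and
   FDR-corrected across subjects.
7. **Control**: the head-tracking trace is resampled to 7.94 Hz,
   processed identically and decoded with the same machinery; artifact
   contamination would make the fNIRS DA curve mirror the tracker's
   rapid-onset plateau rather than the slow hemodynamic rise.

## Worked example

```r
library(nirsdirect)

layout <- default_montage()            # 32 optodes, 288 channels
ses    <- generate_session(sim_config(seed = 2), layout)
conc   <- preprocess_session(ses)      # causal 0.12 Hz -> epochs -> MBLL
contra <- select_channels(conc, layout$channels, 2.5, 5.2,
                          region = "contra_SM")
length(contra)
#> [1] 66

curve <- time_resolved_da(conc, contra, "hbo", seed = 11)
curve
#> <da_curve> 327 time points, 60 trials, 2 classes (chance 50.0%)
#>   max DA 100.0% at 8.6 s; significance level 71.7% (p < 0.001)
```

The curve sits at chance before the movement cue, climbs with
hemodynamic latency (here ~50% at 5 s, ~92% at 8 s after MO at the
default simulated tuning), plateaus after ~10 s, and decays back below
the significance level tens of seconds after movement end —
`plot(curve, movement_end = 10)` draws it with the chance line and the
binomial threshold. The threshold (71.7% for 60 trials at p < 0.001) is
the smallest accuracy whose chance probability does not exceed the
level. The head-track control of the same session:

```r
track <- decode_track(track_pipeline(ses), seed = 5)
mean(track$da[track$time > 2 & track$time < 9])   # plateau between MO and ME
#> [1] 97.9881
```

rises immediately at MO — the temporal dissociation that separates
cortical hemodynamics from motion artifacts. `run_pipeline()` chains all
of this (plus SNR maps and control channel sets) over a cohort of
simulated subjects and writes curve tables, a per-subject peak-DA table
and a JSON manifest.

## Package layout

| Where | What |
|---|---|
| `R/geometry.R`, `R/montage.R` | layouts, channel enumeration, plane projection |
| `R/simulate.R` | synthetic session generator (`sim_config`, `generate_session`) |
| `R/preprocess.R` | filtering, epoching, MBLL, channel selection |
| `R/topomap.R` | direction means, SNR, triangulated interpolation |
| `R/rlda.R`, `R/decode.R` | RLDA model, CV, DA curves, binomial/FDR statistics |
| `R/headtrack.R` | resampling, track preprocessing, track decoding |
| `R/pipeline.R` | cohort orchestration and report writing |
| `vignettes/direction-decoding.Rmd` | models, assumptions, design choices |
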