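---
title: "Estimating chest-equivalent QRS durations from a mobile ECG lead"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating chest-equivalent QRS durations from a mobile ECG lead}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

The duration of the QRS complex — the time from ventricular-depolarization
onset to offset, typically 80–120 ms — is a clinically meaningful ECG
quantity. It is normally read from a standard chest lead. A *mobile* lead
(for instance electrodes near the ear) is far more comfortable for
long-term wear, but its signal is only a few percent of the chest lead's
peak-to-peak amplitude and is easily corrupted by motion. `mobileqrs`
estimates chest-equivalent QRS durations from such a lead, given a
training session in which the mobile lead was recorded simultaneously
with an annotated chest reference.

## The three-stage model

**Stage I — heartbeat identification.** After a zero-phase 2–30 Hz
Butterworth bandpass (order 6), spike candidates are local maxima of the
absolute signal exceeding half of a moving 95th-percentile envelope
(2 s window), separated by at least a 250 ms refractory period. Each
candidate is described by ten features (amplitude, peak-to-peak range,
local-SNR ratio, half-max width, maximum slope, energy concentration,
inter-candidate interval and its ratio to the running median, correlation
with the running mean spike, and excess kurtosis) and classified real or
false by a soft-margin *linear* SVM trained against the chest lead's R
peaks. A linear kernel keeps the decision function a simple weighted sum
over support vectors; features are standardized with constants stored in
the model.

**Stage II — QRS localization and purification.** Accepted R peaks bound
R-to-R beat segments: each segment holds the *offset* of one QRS and the
*onset* of the next, with the most distinguishable landmark (the R peak)
at its edges. Segments are resampled to a common 512-sample grid, scaled
to [0, 1], and expanded into three synchronized views: amplitude, first
difference, and the local angle subtended at each sample by its
neighbours ten samples away (computed in coordinates where ten index
steps span one unit). A per-subject template beat is learned by K-medoid
clustering (K = 3) of the concatenated views under Euclidean distance —
K-means++ seeding followed by best-improvement PAM swaps — taking the
medoid of the most populous cluster, on the view that the subject's
dominant morphology is the clean one. The template carries annotated QRS
boundary indices.

Each beat is aligned to the template by multiview dynamic time warping:
local cost is the squared Euclidean distance summed over the three
views, the accumulated table uses the standard predecessor set
{(m−1, n), (m−1, n−1), (m, n−1)}, and boundaries transfer along the
optimal path. The terminal path distance is the beat's *distortion*;
normalized by the training-session maximum, its histogram is thresholded
by the triangle method (maximum perpendicular distance to the line from
the histogram peak to its rightmost nonempty bin, 50 bins) to yield a
per-subject distortion threshold τ. A beat's binary signal quality index
is 1 iff both its distortion and the trailing 10-beat moving average are
at or below τ; only SQI = 1 beats contribute durations.

**Stage III — calibration.** Durations are assembled across adjacent
segments (onset from segment *j*−1, offset from segment *j*), subjected
to a 300 ms sanity bound, and averaged over each evaluation minute.
Because different lead placements see systematically different QRS
widths, a single additive bias — the difference of training-session mean
durations between the chest reference and the mobile estimates — maps
mobile estimates onto the chest scale. Higher-order calibration is
deliberately avoided: it would overfit the handful of training minutes
and obscure how faithfully the mobile estimates track the reference.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| band edges | 2–30 | Hz | retains QRS energy, rejects wander and mains |
| envelope window / fraction | 2 / 0.5 | s / – | adapts the spike threshold to slow SNR changes |
| refractory | 250 | ms | upper bound on plausible heart rate |
| truth-matching tolerance | 75 | ms | generous against lead-to-lead latency |
| SVM cost C | 1 | – | standard soft margin; features standardized |
| resampled beat length | 512 | samples | see numerical choices |
| angle gap | 10 | samples | captures piece-wise, not sample-wise, slope changes |
| K (clusters) | 3 | – | separates dominant morphology from artifact modes |
| histogram bins | 50 | – | resolves the clean-mode/tail transition |
| smoothing order A | 10 | beats | rejects beats inside bad neighbourhoods |
| sanity bound | 300 | ms | discards pathological warps before averaging |

## Numerical choices

* **Zero-phase filtering.** The filter is applied forward–backward, so
  its magnitude response is squared and its phase is exactly zero —
  durations are timing measurements and must not be shifted by filter
  group delay.
* **Beat grid of 512 samples.** At 500 Hz and resting heart rates an
  R-to-R segment is roughly 430 samples. A common grid *coarser* than
  the native one (e.g. 256) makes the boundary-transfer quantum larger
  than a native sample and caps achievable precision above the sampling
  period; 512 keeps the warp grid finer than the native grid, so
  resampling is interpolation, never decimation. Boundary indices are
  mapped back to record time continuously (no rounding) when durations
  are assembled.
* **Boundary tie-break.** When several test samples warp onto a template
  boundary sample (a vertical path run), the outer-bound rule is used:
  the last aligned sample for the offset, the first for the onset. The
  ambiguity then widens rather than narrows the QRS; the widening is
  systematic and is absorbed by the stage III bias. If a degenerate warp
  collapses the two boundaries, the beat is flagged and excluded.
* **Degenerate beats.** Flat-line segments (saturated artifacts) cannot
  be min-max scaled; they are flagged, excluded from clustering, skipped
  in warping, and forced to SQI = 0.
* **Triangle geometry.** Distances are computed in (bin index, count)
  coordinates; the argmax is invariant to duplicating the value set, and
  τ is reported at the selected bin's centre.
* **Distortion normalization.** Raw distortions are divided by the
  training-session maximum and clipped to [0, 1], so the training-learned
  τ transfers unchanged to testing; testing beats more distorted than
  anything seen in training saturate at 1 and are always rejected.
* **Smoothing start-up.** The trailing moving average uses a shrinking
  window over the first A−1 beats (the mean of what is available), so
  the series has no undefined prefix.
* **Ties.** `sign(0)` in the SVM decision is +1; equal-size clusters are
  broken by lower within-cluster dissimilarity, then lower index; DTW
  backtracking prefers the diagonal predecessor.

## Design choices at genuinely open points

* **Template boundary annotation.** The template's QRS boundaries can be
  taken from the synchronized chest annotations (`template_ann` defaults
  to the chest reference — the only option for real paired recordings)
  or from per-beat boundaries of the mobile lead itself when those exist.
  The synthetic study uses the latter: with chest-annotated boundaries
  the warp transfer silently absorbs most of the lead bias inside stage
  II, entangling localization with calibration; annotating the template
  with the mobile lead's own boundaries keeps the stages orthogonal —
  stage II measures the mobile QRS, stage III owns the lead bias.
* **Single-view ablation.** The single-view (amplitude-only) DTW used
  for comparison re-learns its own normalization constant and threshold
  on the training session under the same restriction, so the comparison
  is between complete pipelines, not between thresholds.
* **Evaluation layout.** Fifteen two-minute trials per session; the
  second minute of each trial is the evaluation minute and also contains
  the 20 s artifact burst, so every evaluated minute exercises the
  purifier.

## The synthetic-data generator

No public dataset pairs a mobile lead with an annotated chest lead, so
the package ships a generator whose defaults *are* the study conditions:

* Each heartbeat is a sum of five Gaussian wavelets at the P/Q/R/S/T
  characteristic points; the true QRS onset/offset are defined
  analytically at ±2σ of the Q and S wavelets, so ground truth is exact
  by construction rather than annotated.
* RR intervals follow a 70 bpm baseline with a ±4 bpm slow drift and
  15 ms beat-to-beat jitter; true QRS durations are 95 ± 5 ms with a
  ±6 ms slow modulation (420 s period, random phase) emulating the
  gradual duration changes of an exercise protocol — this is what makes
  the true minute means genuinely different across evaluation minutes.
* The mobile lead re-synthesizes the same beat train at 3% amplitude
  with every QRS widened by the 8 ms lead bias, then adds baseline
  wander (0.01 units at 0.33 Hz), broadband noise (SD 0.003 ≈ 10% of the
  mobile R amplitude), a 20 s artifact burst in every trial's second
  minute (noise ×8 plus a motion sway component), and ~2 false spikes
  per minute placed away from true R peaks.
* Training and testing sessions share all subject-level parameters and
  differ only in realization; everything is reproducible from one seed.

What the generator does **not** emulate: pathological morphologies
(bundle-branch block, ectopy), respiration coupling, electrode-contact
dropouts, and realistic 1/f artifact spectra. Passing tests on this
generator therefore demonstrate that the estimation chain is correct and
robust to the modelled degradations — not that the clinical performance
on real ear-lead recordings is reproduced.

## Problem sizes used by the tests

The test-suite study runs use 15 two-minute trials per session
(~2 100 beats each) for the end-to-end checks, 3-trial sessions for
component smoke tests, 1 000 random instances (M, N ≤ 8) for the DTW
path oracle, 200 random instances (n ≤ 12, K = 3) for the PAM oracle,
and 10 000 seeded draws for the seeding-law check. The noise-free
convergence check requires every per-beat duration to fall within two
native samples (4 ms at 500 Hz) of ground truth.

## Known limitations

* The calibration is per subject and additive; it cannot correct
  rate-dependent lead bias.
* The SQI is binary; minutes dominated by artifacts yield missing
  estimates (propagated, never imputed).
* Template learning assumes the subject's dominant training morphology
  is clean; a training session that is mostly artifact would select a
  distorted template.
* With a chest-annotated template on real data, part of the lead bias is
  absorbed in stage II; the reported bias then quantifies the residual,
  not the full lead-to-lead offset.
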