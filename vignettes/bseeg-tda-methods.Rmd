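---
title: "Spectral and topological delirium screening scores: models, parameters, design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spectral and topological delirium screening scores: models, parameters, design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bseegtda)
```

## The problem

Delirium — an acute, fluctuating disturbance of attention and cognition —
is common in elderly inpatients and dangerous when missed. Its EEG
signature is *diffuse slowing*: globally dominant delta/theta activity
replacing the normal posterior alpha rhythm. A two-channel forehead EEG
(Fp1–A1, Fp2–A2) is cheap and fast enough for bedside screening, but its
traces must be reduced to a number a non-specialist can act on. This
package implements two such numbers and the machinery to compare them:

* the **BSEEG score**, a spectral slowing index, and
* the **TDA score**, a topological irregularity index,

plus the shared pre-processing, a synthetic EEG generator, and ROC/DeLong
evaluation of labeled score tables.

## The BSEEG score

Each QC-passed 4-s window is Fourier-transformed (one-sided periodogram,
Parseval-consistent scaling, rectangular taper). A 4-s window gives a
0.25 Hz grid at either device rate (500 Hz or 128 Hz), so 3 Hz and
10 Hz are exact bins. The window score is

$$s = \log_{10} \frac{\widehat{P}(3\,\mathrm{Hz})}{\widehat{P}(10\,\mathrm{Hz})},$$

the log power-spectral-density ratio of slow (delta) to fast (alpha)
activity. It is positive when slowing dominates, negative for a normal
alpha-dominant spectrum, invariant to amplitude scaling, and
anti-symmetric under swapping the two components. The subject-channel
score is the median over windows. Choices worth noting:

* **log transform on by default.** A raw ratio is bounded below by zero
  and cannot produce the signed scores (positive = slowed, negative =
  normal) that make the scale interpretable; the raw ratio remains
  available (`bseeg$log10 = FALSE`).
* **Single nearest-bin read-off** rather than a band average, because the
  target frequencies are exact grid bins; a ±0.25 Hz band average is one
  flag away (`bseeg$band_average`).
* **Median aggregation** across windows for robustness to residual
  artifact windows; the mean is available in config.
* A zero denominator is floored at $10^{-6}$ times the smallest positive
  density, so the score is finite for degenerate (single-line) spectra;
  an all-zero window would give `NA`, but such windows are rejected as
  flatlines before scoring.

## The TDA score

The topological route does not ask *where* the spectral mass sits but *how
regular the waveform's trajectory is*. Each QC-passed 2-s window is:

1. **z-scored** (amplitude invariance),
2. **delay-embedded**: point $i$ is
   $(x_i, x_{i+\tau}, \dots, x_{i+(d-1)\tau})$ with $d = 3$ and
   $\tau = \mathrm{round}(f_s / 10)$ samples (≈100 ms, roughly a quarter
   of an alpha cycle — the standard Takens-style heuristic),
3. summarized by **degree-1 Vietoris–Rips persistent homology**: a
   simplex enters the filtration at its largest pairwise Euclidean
   distance; each 1-cycle (loop) contributes a (birth, death) pair,
4. reduced to the **Betti-1 curve** $\beta_1(\varepsilon)$ — the number of
   loops alive at scale $\varepsilon$ on a 200-point uniform grid from 0
   to the cloud diameter — whose rectangular-rule **area** is the window
   score.

A clean oscillation embeds to a closed loop: one dominant, long-lived
pair. Irregular, slowed, or noisy signals spread their trajectory through
the embedding space and accumulate many short- and mid-lived loops, which
*raises* the Betti-curve area. On the synthetic cohorts below, slowed
recordings score consistently higher than normal ones; the regression
tests pin that direction.

Numerical and design choices:

* **Rips rather than Čech/alpha filtration**: the natural choice for
  delay-embedded point clouds in $\mathbb{R}^d$, and the one that can be
  verified exactly against brute-force boundary-matrix reduction, which
  the test suite does for every fixture cloud of up to 8 points.
* **Filtration capped at the cloud diameter** (`max_filtration = "auto"`):
  every loop's death is then resolved, the Betti curve has compact
  support, and the area is finite without a global constant.
* **Enclosing-radius truncation** (exact): beyond
  $\min_i \max_j d(i,j)$ the complex is a cone and carries no degree-1
  homology, so no simplex past that scale is enumerated.
* **Apparent-pair shortcut** (exact): the compiled reduction works on the
  anti-transpose (edge columns, triangle cofacet rows) and skips the
  zero-persistence facet–cofacet pairs that dominate Rips filtrations —
  the standard device that makes persistence on ~230-point clouds take
  tens of milliseconds rather than tens of seconds. Identity of the
  output with textbook full-matrix reduction is asserted in the tests.
* **Uniform-stride subsampling** to at most `tda$max_points = 400` points
  keeps the worst case bounded and, unlike random subsampling, is
  deterministic. At the default rates (2-s windows at 125–128 Hz after
  embedding) clouds have ~226–230 points, so the cap rarely binds.
* **500 Hz recordings are decimated to 125 Hz** after filtering (the
  0.5–20 Hz band-pass leaves nothing near the new Nyquist of 62.5 Hz),
  so both devices produce comparable point clouds; the spectral score
  always runs at native rate.
* **Grid area vs. exact area.** The grid area converges to total
  persistence $\sum (d_i - b_i)$ as the grid refines; at 200 points the
  error is below one grid step times the curve maximum.
  `betti_area_exact()` is exported for users who want the limit directly.
* The subject score is the median window area minus `tda$center_offset`
  (default 0). The offset lets a deployment center the scale on a
  reference cohort so that irregular recordings land positive — the raw
  area is strictly positive and has no natural zero.

The embedding and filtration parameters are deliberately plain defaults,
all exposed in config: published forehead-EEG work in this area reports
that such parameters were tuned per device without publishing the values,
so this package ships one reproducible parameter set rather than guessing
a tuned one.

## Shared pre-processing

* **Band-pass 0.5–20 Hz**, 4th-order Butterworth, applied
  forward-backward (`signal::filtfilt`) for zero phase — slow waves must
  not be phase-shifted before windowing. The signal mean is subtracted
  first, so DC offsets vanish identically. Gain at 10 Hz ≈ 1; the tests
  check the 40 Hz attenuation against the designed transfer-function
  magnitude.
* **Windowing**: consecutive, non-overlapping, aligned to the record
  start; a trailing partial window is dropped. 4-s windows feed the
  spectral score, 2-s windows the topological one.
* **Per-window QC** (all thresholds in config): reject when
  (a) peak |amplitude| > 200 µV, (b) variance < 2 µV² (*flatline*), or
  (c) more than half the power lies above 15 Hz (*high_freq_power* —
  EMG/interference). The flatline floor is set above zero-phase filter
  ringing: a hard lead-off span adjacent to 30 µV signal picks up as much
  as ~1 µV² of leaked variance from the 0.5 Hz edge of the filter, so a
  floor of 0.01 µV² would never fire on real filtered flatlines; 2 µV²
  (1.4 µV RMS) is still far below any physiological EEG.
* **Usable-signal gate**: a subject-channel is scored only if its passed
  windows cover ≥ 30 s, evaluated independently per window duration (so
  a subject can have a spectral score but no topological one). The
  boundary (exactly 30 s) counts as usable; "strictly more than 30 s"
  is not distinguishable from available descriptions, and the inclusive
  convention is the documented one.
* ECG spikes are handled by window rejection, not template subtraction —
  no subtraction recipe is defensible without the reference data to
  validate it.

## The synthetic generator

`simulate_eeg()` emulates the two regimes the scores must separate, with
a slowing index $s \in [0, 1]$:

$$x(t) = (1-s)\,A_\alpha(t)\sin\phi_\alpha(t) + s\,A_\delta(t)\sin\phi_\delta(t) + \text{pink}(t) + \text{artifacts}.$$

* The alpha component wanders ±0.8 Hz around 10 Hz, the delta component
  ±1 Hz around 2.5 Hz — centered *off* the 3 Hz analysis bin on purpose,
  so the generator cannot trivially feed the score's numerator. The
  wander is a 0.4 Hz sweep plus smoothed noise: every 4-s window sees
  the component cross its band, rather than parking off-bin for a whole
  window. Both components carry slow (~±30%) amplitude modulation with
  randomized phases.
* Background is 1/f (pink) noise at 10 µV RMS over a 30 µV oscillation
  scale — spectra keep a realistic slope, so the ratio score is not
  degenerate at $s = 0$.
* Artifacts at per-minute Poisson rates (defaults: EMG bursts 1, ECG
  spike trains 4, baseline drift 0.5, flatline 0): EMG = 15–30 Hz noise
  burst of 0.5–2 s, peak ≥5× the base amplitude (the band overlaps the
  EEG pass-band, as real EMG does, so its post-filter remnant is visible
  to QC); ECG = ~1 Hz train of biphasic 80 ms spikes; drift = sub-0.3 Hz
  swell removed by the high-pass; flatline = zeroed span.
* Cohorts draw each subject's slowing index from
  Normal(group mean, sd = 0.08), clipped to [0, 1] — a modest
  within-group spread so group separation is governed by the group means.
* Everything is reproducible from (config, seed), and generation leaves
  the caller's RNG state untouched.

What the generator does **not** emulate: non-stationary sleep/wake
transitions, eye-blink/EOG fronts, electrode pops, mains hum, medication
effects, or any physiologically detailed neural-mass dynamics. Passing
tests on this generator therefore demonstrate that the pipeline recovers
*planted* spectral slowing under a realistic artifact burden — not
clinical performance on patient data.

## Evaluation

Subjects are labeled delirious if any instrument crosses its cut-off
(CAM-ICU positive, DRS ≥ 19, DOSS ≥ 3, or chart documentation). Score
tables are evaluated per channel: AUC by the Mann–Whitney estimator
(ties ½) with a DeLong 95% CI, the paired DeLong test between the two
scores on subjects with both present (missing scores are dropped per
analysis, so the single-score AUCs use all subjects with that score),
and the operating point at sensitivity ≥ 0.80 chosen as the realized
ROC point of maximal specificity — no interpolation, so the reported
threshold is achievable. Identical score vectors make the DeLong variance
zero; that comparison is flagged degenerate and reported as p = 1 rather
than a division by zero. Group demographics use the Pearson chi-square
without continuity correction and the pooled-variance unpaired t — the
conventions that reproduce published cohort tables of this kind. All
p-values are two-sided.

## Problem sizes and runtime

The persistence computation dominates runtime (~60–70 ms per 2-s window).
The shipped tests and the acceptance script size their simulations
accordingly, as the package's own choices: TDA-bearing cohort runs use
16 + 16 subjects with 60-s recordings (~30 windows/subject); the
spectral-only recovery and null checks use 30 + 30 subjects at the full
120-s default. The DeLong-vs-bootstrap check uses $10^5$ stratified
paired resamples of a 6-subject toy table.

## Known limitations

* The EDF reader/writer covers continuous 16-bit recordings with
  µV/mV/V physical dimensions — no annotations, no BDF/FIF.
* Persistence is computed in degrees 0 and 1 only; no landscapes, images
  or higher homology.
* The TDA score's sign convention depends on `center_offset`, which this
  package does not calibrate automatically; the default raw area is
  strictly positive.
* Specificity confidence intervals at the fixed-sensitivity operating
  point are not provided; the point estimate is reported and any interval
  would be a package-specific convention.
* `two_sample_t` follows the a − b sign convention; published tables may
  print the opposite sign depending on group order.
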