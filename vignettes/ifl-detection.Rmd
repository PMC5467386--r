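---
title: "Detecting inspiratory flow limitation from breath shape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting inspiratory flow limitation from breath shape}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(iflscan)
```

## The problem

During sleep, a partially collapsed upper airway limits inspiratory flow:
instead of the rounded, quasi-sinusoidal flow–time curve of an open airway,
the inspiration develops a mid-inspiratory plateau whose depth and width
track the degree of obstruction. `iflscan` grades every inspiration of a
nasal-cannula airflow recording as non-flow-limited (NIFL), mildly limited
(IFL1) or severely limited (IFL2), using only the shape of the normalized
breath. Single-breath labels are the scope; event-level rules (runs of
four or more abnormal breaths, arousal linkage) are deliberately out of
scope, as are expiratory analysis and snore detection.

## Preprocessing

The pipeline assumes a single-channel airflow signal, nominally 20 Hz,
with positive flow meaning inspiration and a known zero-flow baseline
(default 0, configurable). Processing is:

1. **Low-pass filtering** at 2 Hz. Respiratory content sits below about
   1 Hz, while snoring and cannula noise sit above, so 2 Hz preserves
   breath shape and removes noise. The realization is a 4th-order
   Butterworth applied forward–backward, because a zero-phase response is
   what keeps breath *onsets* where they are; a causal filter would delay
   every zero crossing. `signal::filtfilt` starts each pass from rest, so
   the package pads both ends with odd reflections (as scientific
   filtering routines conventionally do) before filtering; without the
   padding even a constant signal comes back distorted near its edges.
2. **Segmentation**: an inspiration is a maximal run of positive
   baseline-relative flow, entered at a negative-to-positive crossing.
   Runs shorter than 0.5 s (configurable) are discarded as noise-driven
   crossings — at 20 Hz that is ten samples, well below any physiological
   inspiration.
3. **Normalization**: each inspiration is linearly interpolated onto 100
   equally spaced points of normalized time `[0, 1]`, then the amplitude is
   affinely rescaled to min 0, max 1. Rescaling *after* resampling makes
   the extremes exact on the final grid. Linear interpolation is the
   simplest scheme consistent with a fixed 100-point representation;
   smoother interpolants would implicitly re-filter the breath. The
   amplitude is rescaled from the breath's own minimum rather than the
   recording baseline (a config switch in spirit: pass the raw segment
   through your own offset first if the alternative is wanted); the
   minimum-based map is what guarantees the exact `[0, 1]` range every
   downstream formula assumes. Breaths with fewer than 4 samples or
   constant amplitude are rejected as degenerate.

All features operate on this normalized form, so the same physical breath
recorded at different gains yields identical features by construction.

## Features

**Flatness index.** `FI = sqrt(mean((F(i) - M)^2)) / (M * D)` over the
middle 50 % of the breath (grid indices 25–74), where `M` is the mean of
that window and `D = 1` for a single breath. Two readings of this index
circulate — a summed absolute deviation and a root-mean-square deviation —
and they differ by a factor of the window length. The package defaults to
the RMS reading (a *relative* deviation, dimensionless and independent of
the window size) and offers the mean-absolute-deviation variant via
`variant = "mad"`. `M` is computed over the same middle window, not the
whole breath: that choice makes FI exactly 0 for a perfectly flat plateau,
which is the physiological anchor of the index — *low* FI means *severe*
obstruction, so its decision direction is decreasing with severity. A
window that is identically zero has no meaningful relative deviation and
raises a degenerate-window error.

**Polynomial residuals.** A degree-k polynomial (k = 1, 2, 3) is fitted to
the 100 points and scored by the sum of absolute residuals over all 100
points. Although an iterative damped least-squares optimiser is the
traditional tool here, the model is linear in its coefficients, so the
package solves the weighted normal equations directly via QR — exact,
deterministic, and verified in the test suite against an independent
closed-form solution to 1e-6 over a thousand random breaths. Residuals are
summed over the full grid; restricting to the middle half is treated as a
display convention of the flatness index only.

**Weighted third-order residual (primary feature).** A weight profile
gives the endpoints weight `A = 50`, the (first) flow-peak sample weight
`B = 200`, and everything else `C = 1`. Recommended ranges are A in
[50, 100] and B in [200, 400]; values outside them require an explicit
`unsafe` override. The weights enter **both** the fit objective and the
residual sum. The design intent of the weighting is that the fitted curve
itself is pulled through the endpoints and peak, so both stages must see
the weights: a weighted sum over an unweighted fit would leave the curve
free at exactly the points the weighting is supposed to pin. With the
endpoints and peak effectively interpolated, the remaining cubic freedom
cannot track a mid-inspiratory plateau, and the residual concentrates on
the flattening that defines IFL. Tie-break: on a plateau at the maximum
the *first* maximal sample takes `B` (deterministic and
order-independent); if the peak falls on an endpoint, `B` takes precedence
over `A` since it carries the stronger penalty.

For breaths with a unique maximum, FI and the unweighted residuals are
invariant under time reversal (polynomials are closed under `t -> 1 - t`
and the FI window is symmetric); the test suite checks this property.

## Classification and calibration

Each method maps its score to the three classes with two thresholds.
Boundary values belong to the `<=` side of each printed interval. For the
first-order method the shipped intervals are interpreted with the severe
rule `<= 4.54` so that the three intervals partition the line (the only
reading under which the method's NIFL rule `> 6.19` is coherent).

Recalibration reproduces the original cut-point procedure: the direction
is set by comparing NIFL and IFL2 median scores, then each threshold is
chosen on the corresponding *adjacent-pair* two-class problem (NIFL vs
IFL1, IFL1 vs IFL2) to maximise sensitivity + specificity, matching the
pairwise structure of the published ROC comparisons. Candidate thresholds
are midpoints between consecutive distinct scores — deterministic and
classifier-agnostic — with ties broken toward the smaller threshold. If
the two pairwise optima cross (possible on heavily overlapped data), the
IFL1 interval is collapsed to keep the decision rule a partition, with a
warning. AUC is computed as the tie-aware Mann–Whitney normalisation, so
it is invariant under monotone transforms of the scores.

## Evaluation

The 3×3 confusion matrix is summarised by per-class accuracy (= one-vs-rest
sensitivity), one-vs-rest specificity
`(total - row - col + diag) / (total - row)` — the standard multi-class
reading, adopted because no formal definition ships with the original
tables — overall accuracy (trace/total, reported as a percentage rounded
half-up to two decimals, matching table formatting), and the six cobweb
arms `counts[a, b] / rowsum[a]`. The cobweb radar is cropped at 0.5 with a
dashed reference hexagon at 1/3, the per-arm rate of a uniform random
classifier; the numeric arm table is the tested surface, the SVG is
presentation.

## The synthetic generator

No clinical recordings ship with the package, so a generator provides
labelled breaths for calibration and end-to-end testing. It emulates the
qualitative taxonomy of development-set shapes — rounded/sinusoidal
breaths, mildly flattened tops, multi-peak breaths, severe flat tops, and
time-inverted variants of all of these — as parametric families on the
100-point grid (base curve `sin(pi * t^skew)`, raised-cosine soft clipping
for plateaus, an `sin(pi t) cos(2 pi n t)` ripple for multi-peak shapes).
Soft shoulders rather than hard truncation avoid grid-aligned constant
maxima that would make the peak tie-break pathological.

Severity labels follow the families: sinusoidal is NIFL; clipping below
85 % of peak across at least 40 % of the breath is IFL2; every other
deformation is IFL1. No quantitative mild/severe boundary is established
in the literature the way the shape families are; this rule is a modeling
choice and labelled as such.

Noise is additive **band-limited** Gaussian noise: white noise smoothed
with a Gaussian kernel (sd 6 grid samples) and rescaled to
`noise_sd` (default 0.02 of peak amplitude — visible but
class-preserving). The band limit is deliberate: the generator emits
breaths as they exist *after* the 2 Hz acquisition filter, and for a 2–4 s
inspiration resampled to 100 points that filter leaves no white component
— per-breath noise is smooth. White noise at the same sd would be a
physically impossible input for this pipeline and, because the weighted
fit pins three individual samples, would inject variance no real recording
exhibits.

The family parameter ranges are the generator's fixed study conditions,
chosen so the three severity groups are qualitatively distinct — as
curated development prototypes are — while remaining overlapped enough
that classification is non-trivial: sinusoidal skew U(0.83, 0.89);
mild_flat plateau U(0.72, 0.80) at width U(0.32, 0.38); multi_peak with 2
or 3 peaks and ripple amplitude U(0.050, 0.062) or U(0.080, 0.100)
respectively (prominence scaled so 2- and 3-peak members are comparably
deformed); flat_top plateau U(0.50, 0.58) at width U(0.58, 0.78); skew
U(0.85, 0.95) for the deformed families; time inversion with probability
1/2. Under these conditions the held-out three-class accuracy of the
calibrated weighted-cubic feature is 0.93–0.98 across seeds, with every
cobweb arm below 0.1 — the same qualitative picture as on clinical data,
where the weighted cubic dominates the other four features.

What passing these tests does *not* show: the generator contains no
snoring oscillation superimposed on inspiration, no mouth-leak artefact,
no breath-to-breath autocorrelation, no apneas/hypopneas, and its families
are far cleaner than the continuum of real breath shapes. Results on the
synthetic study demonstrate that the machinery is implemented correctly
and that the feature ordering behaves as designed, not that the shipped
cut-offs transfer to any particular recording system.

## Problem sizes and determinism

The test suite exercises the fit oracle on 1,000 random breaths, the
evaluation tally on ~300 random label vectors, the end-to-end study at 200
breaths per class (calibrate on one half, evaluate on the held-out half),
and the chance-classifier reference at 3,000 items per class; the full
suite runs in well under a minute. Every stochastic component takes an
explicit seed: `generate_dataset()` requires one, and the acceptance
script derives all randomness from its `--seed` flag, so all outputs are
bit-reproducible.

## Known limitations

- Single-breath granularity only; no event or arousal logic.
- The shipped cut-offs are frozen defaults from a development set of
  curated prototypes; new recording hardware warrants recalibration with
  `calibrate_cutoffs()`.
- The flatness index is undefined for breaths whose middle window is
  identically zero, and the generator cannot produce every pathological
  real-world shape (see above).
- EDF input is not implemented; traces arrive as delimited text.
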