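---
title: "Real-time MRI pressure-volume analysis: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Real-time MRI pressure-volume analysis: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rtpvr)
```

## The problem

The end-systolic pressure-volume relationship (ESPVR) is the reference
description of left-ventricular (LV) systolic function: across a transient
preload reduction (vena cava occlusion, VCO), the per-beat end-systolic (ES)
pressure-volume points trace a curve whose slope, the end-systolic elastance
`E_ES`, is a load-independent contractility index. Real-time (RT) short-axis
MRI during VCO makes it possible to measure this relationship with actual LV
geometry rather than the idealized geometry assumed by sonomicrometry or the
uncalibrated volume signal of a conductance catheter.

`rtpvr` implements the full analysis chain for such studies:

1. **segmentation** — frame-propagated level-set segmentation of the LV
   cavity from one manual contour per slice series;
2. **geometry** — cavity area, moment-ellipse shape descriptors and
   cavity-obliteration flags;
3. **hemodynamics** — pressure filtering, calibration against the
   pre-acquisition segment, acquisition-window detection from the scanner's
   noise burst, beat segmentation, area-pressure synchronization and
   pressure-area (PA) loop assembly;
4. **fits** — per-beat end-systole detection by iterative maximal-elastance
   regression, ESPAR fitting, trapezoidal ESPVR reconstruction,
   conductance-catheter calibration and BSA indexing;
5. **phantom** — a synthetic VCO study generator with exact ground truth,
   which is the package's validation harness.

Because in-vivo recordings of this kind are not publicly deposited, every
quantitative claim the package makes about itself is established on the
phantom, where truth is known by construction.

## The phantom

`phantom_config()` encodes the study conditions of an anesthetized adult
sheep protocol: cycle length 0.637 s, free-running frames every 59.2 ms
(~10.8 images per beat), pixel spacing 2.0313 mm, 12-bit pressure sampled at
5 kHz, peak LV pressure held near 90 mmHg before occlusion, and ES pressure
falling 2.26 mmHg per beat during a 20-beat occlusion. Slices are imaged at
25/50/75% of the apex-to-base distance during separate occlusions, each with
its own pressure recording.

Each level carries a truth end-systolic pressure-area relationship (ESPAR),
stored as pressure-on-area coefficients `P = b2 A^2 + b1 A + b0`. Defaults
place baseline ES areas near 2.6 / 4.6 / 9.2 cm² (apex / mid / base, matching
reported baseline geometry) with mid/base linear (slopes 20 and 10 mmHg/cm²,
pressure intercepts 12.02 and 8.39 mmHg) and the apex quadratic
(`b2 = -5, b1 = 29.2, b0 = 48`), so that the apical cavity obliterates
(area ≤ 0.25 cm²) around occlusion beat 16 — inside the 50-90 mmHg ESPVR
grid, which is the mechanism that bends the ESPVR in vivo.

Within a beat, cavity area follows half-cosine interpolation between
per-beat ED and ES truth values (smooth, single ES per beat). The pressure
waveform is a half-cosine upstroke, a late-ejection *plateau* at the beat's
ES pressure, and a fast half-cosine isovolumic fall. End systole sits at the
plateau's end: minimum area coincides with (near-)peak pressure, so the
maximal-elastance point is exact by construction, and — as in vivo, where
pressure plateaus through late ejection — the pairing of nadir area with
near-peak pressure is insensitive to frame-scale timing shifts. The default
timing gives an ED-ES interval of ~0.26 s, matching reported values. A
raised-cosine bump without a plateau was rejected: it concentrates the
waveform's curvature exactly at end systole, which makes the ESPAR
artificially sensitive to one-frame alignment shifts in a way real pressure
traces are not.

Images render an anti-aliased cavity ellipse (fixed per-level axis ratio and
orientation taken from reported baseline shape) inside a myocardial annulus
(wall 1.1 cm) on a dark background, with ferumoxytol-like contrast
(blood 0.85, myocardium 0.45, background 0.10 on [0, 1]) and additive
Gaussian noise (sd 0.04). Truth masks are the pixels with ≥ 50% cavity
coverage; the cavity radius shrinks continuously to zero at collapse and the
mask empties below half a pixel-area. The raw pressure trace adds broadband
noise (1 mmHg RMS), a 100-400 Hz noise burst (5 mmHg RMS) spanning exactly
the image-acquisition window, and an affine miscalibration (gain 1.08,
offset -4 mmHg) whose truth is recorded. A conductance record corrupts the
integrated truth volume with the inverse of the two-point calibration model
(`measured = truth / 0.39 + 30 ml + noise`), with the paper-style gain 0.39.

What the phantom does **not** emulate: MR physics (k-space, reconstruction
artifacts), papillary muscles, the RV cavity, through-plane motion,
respiratory or gating artifacts, ECG, and beat-to-beat cycle-length decline
(a ~5 ms effect over a 20-beat occlusion, ignored). Passing tests therefore
demonstrate correctness of the *computational chain* under controlled,
idealized image formation — not segmentation robustness to real MR artifact.

## Segmentation

Each frame minimizes a two-phase piecewise-constant (Chan-Vese-type) energy
with a boundary-length penalty and an L2 shape prior toward the previous
frame's converged signed-distance field,

E(φ) = λ ∫ (I−c₁)²(1−H(φ)) + (I−c₂)²H(φ) + μ ∫ δ(φ)|∇φ| + β ∫ (φ−φ_prior)² ,

with φ < 0 inside. Two departures from the textbook model matter here:

* **Localized statistics.** The region means `c1`, `c2` are computed in a
  narrow band (`band_px`, default 4 px) around the zero level, so the
  competition is blood pool vs adjacent myocardium rather than vs the whole
  image. The band must stay inside the wall (≈ 5.4 px at 2 mm spacing) or
  dark background leaks into `c2` and shifts the boundary into the
  myocardium.
* **Blood-pool anchoring.** The cavity's intensity class is fixed when the
  first frame is seeded. During sequence propagation the first frame's band
  means serve as a reference; a frame whose settled inside mean falls below
  their midpoint has lost the blood pool and is declared empty. This is the
  cavity-collapse mechanism, and it prevents the contour from migrating to
  the myocardium/background two-phase split after obliteration. A frame with
  no band contrast at all (`min_contrast`, default 0.05) is likewise empty —
  the uniform-image tie-break.

Numerics: smeared Heaviside/delta with width `delta_eps` (default 1.0 px);
explicit curvature step with stability bound `dt * mu_curvature <= 1`
(defaults 0.5 and 0.4); the shape term is treated semi-implicitly and is
unconditionally stable, so the β → ∞ limit exactly reproduces the prior. The
field is reinitialized to a signed distance (via Euclidean distance
transforms) every `reinit_every = 30` iterations, which is also the
convergence checkpoint: a binary mask stationary between checkpoints stops
the frame. Post-processing keeps the single connected component with
maximal overlap with the prior and fills holes. After an empty mask the last
non-empty field remains the prior so the cavity is re-acquired when it
reopens.

Defaults (`lambda_region` 25, `mu_curvature` 0.4, `beta_shape` 0.15,
`band_px` 4, `delta_eps` 1.0) were frozen by a grid search on the phantom,
scored on Dice against truth masks and on collapse-detection timing; the
sharper `delta_eps` in particular removes a partial-volume over-segmentation
bias of 4-6 px masks near obliteration. All knobs are exposed because in
vivo studies are known to need occasional per-dataset adjustment.

The band-restricted energy is not a Lyapunov function of the localized flow
(pixels enter and leave the band), so monotone energy descent is asserted in
the global-statistics regime (band covering the image, β = 0, reduced step),
where the discrete flow does descend the two-phase energy.

## Geometry

Cavity area is the foreground pixel count times the pixel area. The ellipse
fit uses second central image moments with the 1/12-pixel finite-bin
correction: full axes are `4*sqrt(eigenvalues)` of the covariance, the
orientation that of the major eigenvector, wrapped to (-90, 90]. Moments are
preferred over boundary least squares because they stay well-behaved on the
small, ragged masks near collapse. Orientation of near-circular sections is
intrinsically ill-determined; fits with axis ratio < 1.02 are flagged rather
than dropped (in vivo apical ratios run ~1.15-1.26, where orientation is
meaningful but noisy). The orientation relative to the RV insertion is the
signed angle between the undirected major axis and the centroid-to-landmark
line, positive toward the septal side; whether the published convention
measures against this chord or an image axis is not stated, so the
convention here is declared, not inferred.

Obliteration is area ≤ 0.25 cm², threshold inclusive; shape descriptors at
flagged frames are excluded from downstream axis/angle analysis. ED/ES
frames are the per-beat area maximum/minimum (first occurrence on ties); ES
is later refined by the maximal-elastance criterion.

## Hemodynamics

* **Filtering**: 4th-order zero-phase Butterworth low-pass, default cutoff
  30 Hz. The published pipeline used a proprietary constrained least
  Pth-norm IIR design whose coefficients are not printed; any IIR meeting
  the passband contract is equivalent for this purpose. Zero-phase filtering
  uses odd-symmetric end padding (plain forward-backward filtering has large
  edge transients on signals with non-zero ends).
* **Acquisition window**: the scanner superimposes a high-frequency burst on
  the raw trace; the window is where the 80 Hz-high-passed sliding 100-ms
  RMS exceeds `k = 3` times the quiet-segment RMS, the latter estimated as
  the 10th percentile of the sliding RMS (the burst covers most of the
  record, the ≥ 5 s pre-acquisition segment supplies the low tail).
* **Calibration**: the affine map carrying the pre-acquisition segment's
  mean per-beat minimum/maximum onto the reference ED and peak-systolic
  pressures, applied to the whole record.
* **Beats**: onsets at upward crossings of half the global peak dP/dt with a
  200-ms refractory period; dP/dt by central differences.
* **Alignment**: on one reference beat, the time where dP/dt first reaches a
  quarter of its within-beat peak on the upstroke (mode `"max_dpdt"` is also
  provided) is matched to the beat's peak-area time, refined to sub-frame
  precision by a parabolic fit through the three frames around the maximum;
  candidate peaks are local maxima within just over half a cycle and the
  nearest in time wins, so imposed lags up to ±300 ms resolve without
  beat aliasing. Whether the quarter-peak rule is per-beat or global is not
  stated in the source; per-beat on the first covered baseline beat is used.
  One rigid offset aligns the whole record — no per-beat warping.
* **Loops**: each beat is resampled on a uniform 50-point grid; pressure is
  read from the high-rate trace and area linearly interpolated from the
  frame series (pressure has ~50 times the temporal resolution, so area is
  brought to the pressure clock, not vice versa). Obliterated frames retain
  zero area; beats not fully covered by the frames are skipped.

## End-systole detection and fits

End systole maximizes the elastance `P/(A - A0)`, but `A0` is itself the
intercept of the end-systolic line — so the scheme iterates (a shooting-point
iterative regression): pick the maximal-elastance sample per beat given the
current `A0`; regress `P` on `A` through the picks; update `A0` to the
line's area intercept; stop when the update falls below `tol` (1e-4 cm²,
cap 50 iterations, oscillation flagged). On noiseless loops the iteration is
validated against an exhaustive search over every per-beat sample choice
minimizing the regression residual (tractable at 5 beats × 10 samples).
Beats whose minimum area reaches the obliteration threshold are excluded
from the regression, as in the source protocol. ESPAR is fitted
pressure-on-area in both linear (slope, area intercept `A0`, pressure
intercept) and quadratic forms; the pressure intercept is the fitted
pressure at zero area.

The ESPVR is reconstructed on the 50-90 mmHg grid in 5-mmHg steps (9
points). At each grid pressure the fitted ESPARs are inverted on their
rising branch (areas clamp to zero at obliteration — no real root or a
negative solution), assembled into five stations — apical tip (area 0),
the three imaged levels at 25/50/75% of the LV length, and a valve plane —
and integrated with the composite trapezoid
`V = Σ (A_i + A_{i+1})/2 · (d_{i+1} - d_i)`. The printed source formula
omits the 1/2 factor through a typographic garble; the standard trapezoid is
used, consistent with its text. The valve-plane area extrapolates the
mid-to-base linear trend (floored at 0); its distance moves toward the apex
as pressure falls, `d5 = L(1 - κ(90 - P)/90)` with `κ = 0.1` — the source
states the motion (from sonomicrometry in dogs) but no formula, so the rule
is linear in pressure, anchored at the base position at 90 mmHg, and
exposed in configuration. A constant baseline volume offset is available
(default 0 for phantoms) since its derivation is unspecified in the source.
`E_ES` and `V0` come from the line fitted to the 9 grid points; a quadratic
fit quantifies curvature, with a case-resampling bootstrap (200 replicates)
for the standard error of the quadratic term. Quadratic pooled fits use
ordinary least squares — the mixed-effects machinery of the original
statistical analysis is out of scope.

Conductance records are calibrated with the two-point model
`V_corr(t) = α (V_cond(t) - V_cond,ES) + V_cine,ES`,
`α = (V_cine,ED - V_cine,ES)/(V_cond,ED - V_cond,ES)`, so corrected baseline
ED/ES equal the cine reference exactly and recalibration is the identity.
The volume channel is low-passed (zero-phase, 15 Hz) before the two-point
extremes are read and before ES detection — ventricular volume has no
physiological content there, and raw conductance noise would otherwise
inflate the ED-ES swing and bias the gain. ES detection then reuses the same
maximal-elastance iteration with volume in place of area; the final line is
fitted through ES points inside 50-90 mmHg for comparability with the
imaging grid. Elastance indexes to BSA with exponent 1 and volumes
optionally with exponent 1.5 (both conventions appear in the source; both
are exposed).

## What the tests establish, and on what sizes

The test-suite acceptance checks run entirely on the phantom: pooled Dice
against truth masks on a three-level, 20-beat-per-level study at default
noise; apical collapse-detection timing against the rasterized truth masks
over ten seeds (the oracle is the truth *mask* area, since the continuous
area model differs from its own rasterization by up to 2 px at the 6-px
threshold); moment-ellipse recovery on rasterized ellipses of 0.8-2.5 cm
semi-axes (orientation asserted at axis ratios ≥ 1.3 — below that the
estimand itself degrades faster than the 1° tolerance at a few hundred
pixels); lag recovery and one-frame ESPAR-slope stability; maximal-elastance
recovery on synthetic loops (noiseless and at pipeline-scale noise, 20
seeds); trapezoid exactness and convergence on an analytic semi-ellipsoid;
full-pipeline `E_ES` recovery and collapse-induced ESPVR curvature over 20
seeds on 96-px, 21-beat studies; and the conductance identities plus
cross-route agreement. The reduced frame counts and raster sizes keep the
suite fast; none of the checked properties depends on record length beyond
the beats needed for the fits.

## Known limitations

* The level-set variant is this package's own (the published study deferred
  its functional to cited prior work); equivalence to that implementation
  cannot be asserted — only Dice-level behavior on the phantom.
* Binary-mask moments carry O(1 px) rasterization noise; at the 2 mm
  acquisition spacing, orientation of sub-300-pixel masks is good to a few
  degrees, not fractions of a degree.
* The ESPVR rests on three slices plus two extrapolated stations; the
  trapezoid underestimates volumes of convex area profiles (the known
  RT-vs-cine ES volume offset), and the valve-plane rule is a modeling
  choice, not a measurement.
* Long-axis segmentation, EDPVR analysis, ECG/respiratory handling,
  mixed-effects inference and finite-element modeling are out of scope.
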