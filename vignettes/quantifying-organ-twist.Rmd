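---
title: "Quantifying 3D twist and bending of rod-shaped plant organs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying 3D twist and bending of rod-shaped plant organs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rodtwist)
```

## The measurement problem

A dorsoventral organ like a leaf petiole deforms in two geometrically
distinct ways. Bending curves the midline; twisting rotates the
cross-section about the midline while leaving the midline straight.
Phototropic responses mix both, and a 2D projection cannot separate them:
an organ bent toward the camera looks twisted, and vice versa. The method
implemented here works entirely in 3D. Its inputs are three ordered point
tracks per organ, obtained by manual tracking of microscopy z-stacks:

* the **midline** — the central vasculature, tracked as the centre of the
  brightest spot of each transverse section;
* the **left** and **right margins** — the points where the flat adaxial
  surface ends in strong curvature.

Point index 0 is the blade–petiole junction end; arc length and
cumulative angles are measured from there. Coordinates are micrometres
(voxel units are converted at read time with a per-axis scale).

## Model and pipeline

At every arc-length position $s$ along the midline we attach the material
frame $(e_{\mathrm{lat}}, e_{\mathrm{long}}, e_{\mathrm{ad}})$:
$e_{\mathrm{long}}$ is the unit midline tangent,
$e_{\mathrm{lat}}$ is the unit vector from the right to the left margin
*measured in the cross-section plane* (the plane through the midline
point perpendicular to the tangent), and
$e_{\mathrm{ad}} = e_{\mathrm{long}} \times e_{\mathrm{lat}}$ is the
adaxial direction. The local deformation rates are

$$\tau = \frac{d e_{\mathrm{ad}}}{ds} \cdot e_{\mathrm{lat}}, \qquad
\kappa_1 = \frac{d e_{\mathrm{long}}}{ds} \cdot e_{\mathrm{lat}}, \qquad
\kappa_2 = \frac{d e_{\mathrm{ad}}}{ds} \cdot e_{\mathrm{long}},$$

twist, lateral bending and vertical bending respectively, all in rad/µm;
cumulative angles are their integrals from $s = 0$. Because both margin
intersections lie in the section plane, $e_{\mathrm{lat}}$ is
automatically perpendicular to the tangent on straight midlines; the
`orthogonalize_lateral` option enforces exact perpendicularity for
strongly curved ones, where the two margin cross points sit at slightly
different planes' worth of curvature.

`rod_deformation()` runs the pipeline: Gaussian denoising → cubic
interpolation → uniform arc-length resampling → frames on cross-sections
→ finite-difference rates → cumulative angles.

### Sign conventions

The triple $(e_{\mathrm{long}}, e_{\mathrm{lat}}, e_{\mathrm{ad}})$ is
right-handed, and $\tau > 0$ means the adaxial vector rotates toward
$e_{\mathrm{lat}}$ with increasing $s$. Twist is a *chirality*:
reflecting the organ in a mirror negates $\tau$ pointwise, but swapping
which margin is called "left" does **not** — relabelling negates both
$e_{\mathrm{lat}}$ and $e_{\mathrm{ad}}$, and their pairing in $\tau$ is
unchanged. (The bending rates $\kappa_1, \kappa_2$, each involving only
one flipped vector, do change sign under relabelling, which is why
summaries quote the magnitude of cumulative bending.) These are exact
properties of the estimator and are enforced in the test suite.

## Tunable parameters

| parameter | default | unit | role |
|---|---|---|---|
| `window_um` | 1000 | µm | Gaussian denoising window (truncation width) |
| `ds_um` | 10 | µm | arc-length grid step for frames and derivatives |
| `fit_method` | `cubic` | — | curve representation (`cubic`, `poly9`, `gauss8`) |
| `parameterization` | `chord_length` | — | fitting parameter (`axis_z` for near-vertical organs) |
| `interior_margin_um` | 0 (200 recommended) | µm | length excluded from each end in summaries |

**Smoothing window.** The kernel convention must be fixed explicitly,
since a "window" could mean a standard deviation, a FWHM or a support
width. Here `window_um` is the *truncation width* $W$ of a Gaussian with
$\sigma = W/4$, cut at $\pm W/2$ and renormalized; $W = 4\sigma$ captures
about 95% of the kernel mass. With this convention the familiar decade
comparison behaves as expected on manually tracked organs: a 100 µm
window barely changes the track, 1000 µm removes tracking jitter while
preserving organ shape, and 10 000 µm collapses the track toward its mean
and destroys the signal. Weights are computed over the *chord-length
parameter*, not the point index, so unevenly spaced manual tracks are
smoothed by physical distance. There is no automatic window selection:
choose the window against the noise scale, and keep it well below the
track length (see *Edge effects* below).

**Curve fitting.** Natural cubic interpolation (zero second derivative at
the ends, since tracked data carry no end-derivative information) passes
exactly through every denoised point and imposes no global shape. The two
global alternatives are retained as negative controls: a degree-9
polynomial and a sum of 8 Gaussian bumps both leave strictly positive
residuals on wavy tracks because the organ outline has more sign changes
of curvature than their functional form can follow. The `gauss8` fit is
deterministic: centres start evenly spread over the domain, widths at
domain/16, amplitudes from a linear warm start, then Levenberg–Marquardt.

**Arc length.** The position-along-the-organ coordinate is the integral
of the curve speed along the fitted parameter. The chord-length
parameterization makes this correct for any organ orientation; the
`axis_z` mode (integrating along the imaging axis) is retained for organs
whose long axis is nearly parallel to $z$, and agrees with the default to
about $10^{-4}$ relative on noiseless monotone-$z$ tracks.

## Numerical choices

* **Frame derivatives** use central differences on the uniform $s$ grid
  (one-sided at the two ends). Frames exist only pointwise — each one
  comes from a root-finding problem on the margin curves — so there is no
  closed-form $s$-dependence to differentiate analytically. Halving
  `ds_um` changes interior twist by well under 0.5%.
* **Cross-section roots** are found by scanning dense margin samples for
  sign changes of the plane function and refining with Brent's method;
  when a strongly curved organ yields several intersections, the root
  nearest the previous accepted one (scanning $s$ upward) is taken, which
  implements the assumption that each margin pierces each section once.
* **End trimming.** A margin track may stop short of the first or last
  section planes (tracking truncation, noise). The profile covers the
  $s$ range where *both* margins intersect their planes, rebased to start
  at 0; a missing intersection strictly inside that range is an error.
* **Cumulative angles** are trapezoidal integrals; against a linear rate
  ramp the quadratic closed form is matched to 0.1% at the default grid.
* **Generator integration** uses fixed-step RK4 at step
  `point_spacing_um / 4` with per-step Gram–Schmidt re-orthonormalization
  (drift above $10^{-6}$ aborts with an error). The frame evolves with
  angular velocity
  $\omega = -\tau\, e_{\mathrm{long}} + \kappa_2\, e_{\mathrm{lat}} + \kappa_1\, e_{\mathrm{ad}}$,
  which is exactly the rotation for which the extraction formulas above
  return the prescribed $(\tau, \kappa_1, \kappa_2)$ with the same signs.

## Edge effects, and why twist is more robust than curvature

A truncated, renormalized kernel behaves differently near track ends:
the effective weights become one-sided, and smoothed points within
$W/2$ of an end are biased toward the interior. Two consequences matter.

First, the measured organ is *shorter* than the tracked one — the
smoothed track starts inside the original — which is why a 3.2 mm rod
analyzed at the default window reports roughly 2.84 mm.

Second, the two rate families respond very differently. The **twist**
estimate is nearly immune to end bias: the kernel shifts the margin's
rotational phase and its axial position by the *same* weighted-mean
displacement, and the two biases cancel in the phase-vs-arc-length slope.
A noise-free 15 deg/mm rod is recovered to 0.01% at the default window
even 200 µm from the ends. **Curvature** ($\kappa_1, \kappa_2$) enjoys no
such cancellation: the one-sided kernel straightens the track, and
midline curvature within about $W/2$ of an end is systematically
underestimated. Validation of the curvature channels therefore either
excludes half a window at each end or uses a window matched to the noise
level — for noise-free synthetic tracks a 100 µm window recovers bending
to better than 0.01% everywhere beyond 200 µm. The practical guidance for
real data follows: *the window must be well below the track length*, and
curvature values within half a window of the ends should not be
interpreted. An 873 µm arc analyzed with a 1000 µm window is meaningless;
the same arc with a 100 µm window recovers its 1/2000 µm⁻¹ curvature to
a fraction of a percent.

## The synthetic generator as ground truth

`simulate_rod()` emulates what the tracking produces: three ordered point
lists for a rod of prescribed geometry. Defaults match the measured
organ — 3.2 mm length, 100 µm margin radius, points every 20 µm — and
tracking error is modelled as isotropic Gaussian displacement (5 µm is a
realistic scale for careful manual tracking at ~1 µm voxels). Rate
profiles may be constants or arbitrary functions of $s$.

What it deliberately does **not** emulate: anisotropic axial noise
(light-sheet z-blur would widen the $z$ component), the biological
bumpiness of real margins, curvature-dependent tracking difficulty, and
unequal margin radii. Passing the round-trip tests therefore shows the
*estimator* is correct and noise-tolerant at realistic magnitudes; it
does not certify any particular biological tracking protocol.

With 5 µm noise and the default window, the recovered mean twist of a
15 deg/mm rod stays within 10% of truth in at least 18 of 20 seeds (the
test suite checks exactly this), and within ~3% in typical runs.

## The helix growth model

If twisting arises from differential growth of more than two surface
regions, the most-grown region winds as a helix of radius $r$ (the organ
radius) and total turn $\theta$ around the least-grown, straight region
of length $L$. Assuming a constant helix angle, the most-grown length is
$\sqrt{L^2 + (r\theta)^2}$ and the growth ratio is

$$\frac{\sqrt{L^2 + (r\theta)^2}}{L} \;\approx\; 1 + \frac{(r\theta)^2}{2L^2}.$$

For the measured scenario ($L = 3.2$ mm, $r = 0.1$ mm,
$\theta = \pi/3$) the closed form gives
`r format(differential_growth_ratio(3.2, 0.1, pi/3), digits = 7)` — a
length difference of ~0.05%, far below microscopic detectability, which
is the model's point: tiny differential growth suffices for a large
twist. Note that rounder figures sometimes quoted for such scenarios
(≈1.002 at these parameters, or ≈1.01 for $L = 3$ mm, $r = 0.2$ mm,
$\theta = \pi$) are not reproducible from the stated parameters via this
formula; the closed form is authoritative in this package, and its
limits, scale invariance and small-angle expansion are what the tests
pin down.

## Problem sizes and determinism

The validation suite runs entirely on synthetic rods at the measured
organ scale: 161 tracked points per curve (3.2 mm at 20 µm spacing),
analysis grids of ~300 points at `ds_um = 10`, and 20 noise replicates
for the noise-tolerance check. A full pipeline run takes well under two
seconds on one core. All noise is explicitly seeded; noise-free analyses
are bit-for-bit deterministic, and the command-line `measure` and
`simulate` commands reproduce byte-identical outputs across runs.

## Known limitations

* Manual tracking is assumed; there is no image I/O, automated tracking
  or segmentation.
* The MTrackJ-style reader is a minimal permissive dialect (track blocks
  with point lines), not a full format implementation; the labelled CSV
  is the canonical interchange.
* Summaries are per organ; comparing biological replicates is left to
  the caller.
* Curvature within half a smoothing window of the track ends is biased
  toward zero (see *Edge effects*); twist is not, but endpoint values of
  all rates use one-sided differences and deserve an interior margin.
* The growth model is purely geometric — no elasticity or energy.
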