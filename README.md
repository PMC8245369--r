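# rodtwist

Three-dimensional quantification of twisting and bending in rod-shaped
plant organs from tracked curves.

Dorsoventral organs such as the Arabidopsis leaf petiole respond to
lateral light by both **bending** (curvature of the organ midline) and
**twisting** (rotation of the cross-section about the midline, which
leaves the midline straight). Classical 2D measurements of twist are
biased by bending and by the viewing angle. `rodtwist` implements a fully
3D method: from three manually tracked curves per organ — the midline
(central vasculature) and the two margins — it reconstructs the material
frame of every cross-section and separates local twist from the two
bending components, with no assumption about how the organ is oriented
relative to the imaging axes.

## The method

Each track is denoised with a Gaussian filter over chord length and
converted to a smooth curve by natural cubic interpolation. Arc length
`s` is measured along the midline from the blade–petiole junction
(point index 0). At each `s` on a uniform grid, the cross-section is the
plane through the midline point perpendicular to the midline tangent, and
the material frame is

- `e_lateral(s)` — unit vector along `x_left_margin(s) − x_right_margin(s)`,
  where the margin positions are the intersections of the margin curves
  with the cross-section plane;
- `e_longitudinal(s)` — unit midline tangent `d x_midline / ds`;
- `e_adaxial(s)` — `e_longitudinal(s) × e_lateral(s)`.

Local deformation rates (rad/µm) are arc-length derivatives of the frame:

| quantity | definition | meaning |
|---|---|---|
| twist `τ(s)` | `d e_adaxial/ds · e_lateral` | rotation of the cross-section about the midline |
| lateral bending `κ1(s)` | `d e_longitudinal/ds · e_lateral` | midline curvature perpendicular to the adaxial direction |
| vertical bending `κ2(s)` | `d e_adaxial/ds · e_longitudinal` | midline curvature in the adaxial plane |

Cumulative angles are integrals of the local rates from `s = 0`.
Summaries report twist in degrees/mm, the field's customary unit.

The package also includes:

- a **synthetic rod generator** (`simulate_rod()`) that integrates the
  frame evolution for prescribed twist/bend profiles and emits tracks
  with optional tracking noise, providing exact ground truth for
  validating the pipeline;
- the **helix growth model** (`differential_growth_ratio()`): the
  differential-growth length ratio needed to produce a twist of total
  angle θ in an organ of length L and radius r,
  `√(L² + (rθ)²) / L`.

## Worked example

Simulate a light-stimulated petiole (3.2 mm long, 100 µm margin radius,
uniform twist totalling 48°, 5 µm tracking noise) and measure it back
with the standard configuration:

```r
library(rodtwist)
spec <- rod_spec(length_um = 3200, margin_radius_um = 100,
                 twist = 48 * pi/180/3200,   # rad/um, i.e. 15 deg/mm
                 noise_sd_um = 5, seed = 42)
rod <- simulate_rod(spec)
fit <- rod_deformation(rod$tracks, window_um = 1000, ds_um = 10)
summary(fit, interior_margin_um = 200)
#> Deformation summary
#>   measured length          2870.0 um (interior margin 200 um)
#>   local twist               14.91 deg/mm (s.d. 1.05, |mean| 14.91)
#>   max |cum. twist|          39.65 deg
#>   max |cum. bending|         0.59 deg
```

The prescribed 15 deg/mm twist is recovered within 1% despite the noise,
and the bending channels confirm the rod is straight (max cumulative
bending below a degree). The measured length is shorter than 3.2 mm
because the smoothing window pulls the track ends inward; the 200 µm
interior margin additionally excludes the end regions where one-sided
derivatives are used.

For real data, write the tracks as a CSV with header `track,point,x,y,z`
(labels `midline`, `left_margin`, `right_margin`; point 0 at the
blade–petiole junction; coordinates in µm, or in voxels combined with a
`unit_scale`) and call `read_tracks_csv()`, or use `read_mtrackj_mdf()`
for MTrackJ-style exports.

A command-line interface wraps the same functions:

```sh
exec/rodtwist simulate --config spec.json --tracks tracks.csv --truth truth.csv
exec/rodtwist measure --input tracks.csv --profile profile.csv \
    --summary summary.json --interior-margin 200
exec/rodtwist growth-ratio --L 3.2 --r 0.1 --theta-deg 60
```

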