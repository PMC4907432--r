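---
title: "Synthesizing panoramic radiographs from dental CBCT: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Synthesizing panoramic radiographs from dental CBCT: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cbctpano)
```

## The problem

A panoramic radiograph shows the whole dentition as if the curved dental
arch were unrolled flat. Classical synthesis from a CBCT volume extrudes a
single 2D arch curve vertically into a cylinder and samples the volume on
that sheet (the *cylinder method*). Tooth long axes, however, are not
vertical: incisors are proclined by 8--20 degrees, and by different amounts
in the upper and lower jaw. A vertical sheet that passes through a tilted
incisor's cervical third misses its crown and root apex, so cylinder-method
single-slice images routinely lose incisors and molars, and recovering them
requires thick slabs that destroy contrast.

`cbctpano` instead extracts a *curved panoramic surface* that follows the
long axes of the teeth in three steps, then develops that surface
isometrically into the output image.

## The procedure

**Step 1 — dental arch curve.** The axial maximum-intensity projection
(MIP) concentrates the dentition into a bright arch, because enamel is the
densest tissue in the head. Pixels are clustered into `k` intensity classes
by seeded 1-D k-means++ (k-means++ initialisation, then exact weighted
Lloyd iterations on the distinct values); the brightest cluster(s) form the
bone mask. Because the jaws can be nearly as bright as the teeth, a
*spatial quadrangle* — the smallest centroid-anchored axis-aligned
rectangle, with aspect ratio fixed to the mask's per-axis standard
deviations, that covers a proportion `p` of mask pixels — removes posterior
jaw bone before fitting. A parabola is then fitted to the isolated arch
pixels by least squares in a PCA-rotated frame (so the method does not
depend on patient orientation), an odd number of control points is placed
on it at equal arc-length steps symmetric about the apex, and a Hermite
cubic spline with Catmull–Rom tangents through those points becomes the
arch curve. Keeping the spline rather than the parabola preserves the
ability to adjust individual control points on irregular arches.

**Step 2 — panoramic curved surface.** The spline derivative yields
perpendicular lines at uniform arc-length steps. Each line generates an
oblique sagittal section: the volume resampled (bilinearly in-plane) on the
vertical sheet through that line, spanning all axial slices. Teeth are
segmented in each section with the same clustering rule, speckles below
`min_area` pixels are removed, and one polynomial `u(z)` of degree 5 (the
*long axial curve*) is fitted through the combined upper-and-lower tooth
pixels — the bite gap simply contributes no pixels, and the polynomial
bridges it. Mapping each curve back through its generating line produces a
grid of 3D points: the panoramic curved surface, with triangle-strip
connectivity and per-vertex normals from a local PCA plane fit (smallest
eigenvector of the 3×3 neighbourhood covariance, oriented outward).

**Step 3 — development and rendering.** Joining the per-section surface
points at a reference transverse row gives a 3D piecewise-linear polyline;
it is straightened by the arc-length rule, `w_i = sum_{j<=i} L_j`, while
the ordinate keeps the axial slice index, `h_j = z_j`. The single-slice
radiograph samples the volume (trilinearly) at the development's inverse;
the thickened radiograph averages samples at integer offsets along the
per-vertex surface normals, which reveals structures lying near but not on
the surface, such as the mandibular canal. The cylinder baseline is
implemented alongside for comparison and shares the development width rule.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `k_mip` | 5 | MIP clustering classes; the bone mask is the top class. Empirical per scan: use a value at which jaw and teeth separate (or deliberately merge, see below). |
| `p` | 0.75 | quadrangle coverage proportion (fraction of bone pixels retained). Empirical per scan; see "Empirical parameters on phantoms". |
| `n_control_points` | 7 | odd spline control-point count; 3 is a parabola-like arch, more allows irregular arches. |
| `step_px` | 1 px | arc-length spacing of the normal lines, hence output column resolution. |
| `half_length_px` | 20 px | half-width of each sagittal section; must cover crown radius plus tilt excursion. |
| `k_section` | 4 | per-section clustering classes. 4 isolates enamel on open-bite scans; 2 suits closed-bite scans where teeth and jaw merge into one bright class. |
| `degree` | 5 | long-axis polynomial degree. See the degree study below. |
| `min_area` | 10 px | section speckle filter; least squares on salt noise is catastrophic. |
| `smooth_px` | 5 px | half-width of the triangular kernel applied to the `u(z)` profiles along the arch (see "Numerical choices"). |
| `k_neighbors` | 9 | PCA normal-estimation neighbourhood (3×3 grid window). |
| `n_slices` | 1 / 21 | slab thickness in voxels; odd. 1 is the single-slice image. |
| `reference_row` | `"mid"` | transverse row joined into the development polyline; `"per_row_mean"` averages segment lengths over all rows, an integer selects e.g. the occlusal slice. |

All clustering is seeded (`seed`, default 0); two runs with one
configuration are bitwise identical.

## The synthetic jaw phantom

Patient CBCT scans are not distributable, so validation runs on a phantom
with closed-form ground truth (`phantom_config()` /
`generate_phantom()`). It emulates exactly the features the method's
stages depend on:

- a parabolic dental arch of discrete capsule-shaped teeth (cylinder plus
  hemispherical caps) with concentric enamel shell, dentine body and pulp
  core; the defaults on a 160³ grid at 0.3 mm voxels give 10 teeth per jaw,
  crown radius 1.3 mm, enamel cap 0.7 mm;
- tilted long axes, strongest at the incisors: upper 15°, lower 8°,
  decreasing linearly to 0° at the molars. The asymmetry between jaws is
  anatomically standard (upper incisors are more proclined) and gives the
  combined long-axis profile the odd component that distinguishes a
  quintic from a quartic fit;
- upper teeth slightly longer than lower (6.9 vs 6.3 mm), again matching
  typical anatomy;
- a jaw-bone band (half-width 14 voxels) following the arch with posterior
  ramus wings, so the spatial-threshold step has something real to remove,
  and wide enough that the optional mandibular-canal tube (radius 0.75 mm,
  10 voxels lingual of the arch, below the root apices) runs inside bone as
  it does anatomically;
- a soft-tissue ellipse, open- or closed-bite occlusion (closed bite
  staggers the upper row half a pitch so crowns interdigitate with a
  2-voxel z-overlap and disjoint enamel shells), an optional high-intensity
  implant, and seeded additive Gaussian noise (default sd 40 on a 0--2000
  gray scale, about 7% of the enamel–dentine contrast).

Every ground-truth quantity — arch coefficients, per-tooth centre and
long-axis unit vector, canal centreline — is closed-form, so tests measure
parameter recovery directly.

What the phantom does *not* emulate: real crown morphology (cusps,
multi-rooted molars), continuous proximal contacts, metal and beam-hardening
artifacts, scanner physics, and anatomical structures such as sinuses and
condyles. Passing tests therefore demonstrate geometric correctness of the
pipeline — segmentation thresholds transfer to tissue-like contrast, curve
and surface fits recover known geometry, the development is isometric — but
not robustness to clinical artifact levels.

## Empirical parameters on phantoms

The clustering class count and quadrangle proportion are empirical per
dataset (different scans legitimately use different `k`, and sections use
`k = 4` or `k = 2` depending on bite). On the phantom, discrete tissue
intensities make the top MIP cluster *teeth-only* at `k = 5`; a quadrangle
tuned for jaw-containing masks (`p = 0.75`) would then clip the terminal
molars it is supposed to keep, biasing the arch fit by ~0.2 voxels. The
phantom studies therefore use two configurations, fixed once:

- `k = 5`, `p = 0.99`: the teeth-only regime; the spatial threshold stays
  in the pipeline but retains the complete arch.
- `k = 2`, `p = 0.75`: the jaw-merged regime that motivates the quadrangle
  (jaws and teeth in one bright class); used for the quadrangle-ablation
  study, where removing the spatial threshold strictly degrades arch
  recovery.

## Numerical choices

**Orthogonal-distance parabola refinement.** An ordinary vertical-residual
LSF is biased through thick pixel clusters: within a blob of the mask the
conditional mean of `y` given `x` is flat while the model has slope, so the
fit systematically flattens the arch. The parabola is therefore refined by
geometric least squares (per-pixel foot points by an 8-step Newton
projection; simplex plus BFGS on the three coefficients), which is unbiased
for clusters symmetric about the curve. On exact on-curve input both fits
coincide to machine precision.

**Profile smoothing along the arch (`smooth_px = 5`).** Independent
per-section fits jitter at the voxel-quantisation level (a few tenths of a
pixel). The development polyline accumulates that jitter: each 1-px chord
gains a spurious transverse component, inflating the developed width by
10–30% and misregistering columns. A triangular kernel of half-width 5 px —
half a tooth width, far below the arch-level variation that must survive —
restores isometry. The alternative of fitting only one section in ten and
interpolating (which real dentitions with continuous contacts tolerate)
aliases against the phantom's discrete teeth: a fitted section can fall in
an interdental gap and a whole tooth drops out; `section_step_px = 10`
remains available for dense dentitions.

**Toothless-section gating.** Sections between or beyond the teeth contain
only jaw bone; fitting their top cluster would chase the wrong feature.
A section is gated out when the maximum intensity inside its segmented mask
falls in the lower half of the spread of that statistic across sections
("auto" rule; on scans where every section contains teeth the spread is
narrow and nothing is gated). Gated and stride-skipped columns are bridged
by linear interpolation of the neighbouring `u(z)` profiles in arc length;
columns whose immediate neighbours were also toothless are marked invalid.

**Out-of-range handling.** Above and below a section's fitted z-range the
polynomial has no evidence and is clamped to its boundary value, which
keeps the top and bottom margins of the image artifact-free. Out-of-volume
samples take the volume minimum (air). Sampled `u` is clipped to the
section half-length. The development reference row defaults to the
mid-height row; with an open bite that row lies in the occlusal gap, where
the bridged polynomial is smooth, and the `per_row_mean` option averages
segment lengths over all rows instead.

**Degenerate inputs.** Fewer distinct intensities than `k` reduces `k`
with a warning; a constant section yields an empty mask and the fallback
path; masks spanning fewer than `degree + 1` z-rows fall back likewise;
collinear masks are rejected by the parabola fit; duplicate control points
are rejected by the spline; a PCA neighbourhood with collinear points falls
back to the generating line's outward normal.

## The degree study

With tilted incisors the combined upper-lower long-axis profile is a
bridged, asymmetric bend. On the default phantom the quintic tracks every
true axis to well under 2 px; quartic fits are measurably worse at the
incisor sections (they lack the odd high-order component), and septic fits
show an order of magnitude higher coefficient variance across adjacent
sections — the instability that produces visibly disordered surface
regions. Degree 5 is the default; 1–7 are accepted.

## Problem sizes

The validation suite uses 160³ phantoms (the arch-recovery study spans a
3×3 grid of arch shapes, clean and at noise sd equal to 20% of the
enamel–dentine contrast) and 120³ phantoms for unit-level checks; the
acceptance script reruns the whole set from scratch in a few minutes on one
core. These sizes keep every closed-form check exact while remaining small
enough to iterate on; the pipeline itself is resolution-independent and
runs on clinical 512³ volumes unchanged.

## Known limitations

- The developed image corrects no geometric distortion across rows far
  from the reference row; like all arc-length developments it is exactly
  isometric only along that row.
- Thickened slabs average along straight normal offsets; strongly curved
  regions can produce slight jaggedness at large thicknesses.
- The quadrangle is axis-aligned in the PCA-rotated frame; a strongly
  asymmetric arch could warrant an oriented rectangle.
- Contrast enhancement of thickened images is deliberately out of scope;
  outputs are raw averaged intensities with a display-window utility
  (`apply_window`) for visualisation only.
- DICOM series input is not supported; convert to NIfTI or raw + YAML.
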