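---
title: "Methods: label fusion, volume revisualization and image validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: label fusion, volume revisualization and image validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette is the package's own account of what it computes and why
the open design decisions were taken the way they were.

## The interoperability model

The package treats a segmentation as a set of binary voxel masks, one
per named structure, delivered as DICOM slice series in one of two
vendor conventions: one series per structure ("multi-directory", the
Mimics/Avizo mask-export style, optionally zipped), or one combined
series whose voxel values encode structure membership
("single-directory", the VG Studio style). Both reduce to the same
internal representation:

* `volume_grid` — a 3D scalar array indexed `(slice, row, col)`
  (zero-based in all geometric formulas) with voxel spacing in mm, a
  physical origin, and a direction-cosine matrix. The centre of voxel
  `(s, r, c)` sits at `origin + orientation %*% (spacing * c(s, r, c))`.
* `label_map` — an unsigned 8-bit `volume_grid` plus a table mapping
  each non-zero voxel value to a structure name, an RGBA colour, its
  provenance and its voxel count.

**Slice ordering.** Slices are ordered by the projection of their
position onto the stack normal (the cross product of the row/column
direction cosines), with instance number breaking ties; filename order
is never trusted, because vendors disagree on naming. Inter-slice
spacing is the median of consecutive position deltas — positions are
authoritative, nominal slice-thickness tags are ignored — and a gap
deviating from that median by more than 1% (relative) aborts assembly,
since a silently irregular stack would corrupt all physical-space
computation downstream. A single slice gets a 1.0 mm default spacing.
When direction cosines are absent an axis-aligned identity orientation
is assumed and logged.

**Mask normalization.** Vendors export masks either as 0/255 binaries
or with arbitrary label values; `read_export()` normalizes every
imported mask to {0, 1}. A combined single-directory export is split
into one binary mask per distinct non-zero voxel value, and each split
mask remembers the value it carried (`source_value` attribute), so a
later merge can reproduce the original labelling even when a structure
was completely occluded during export.

## Label fusion

Structure *k* of *n* receives voxel value `round(k * 255 / n)`
(half-up rounding). The interoperability requirement is only that each
structure receive *a* voxel value; even spacing over [1, 255] was chosen
so structures land in separated columns of the transfer-function
domain and remain individually selectable, and the scheme is
overridable through `merge_masks(values = ...)`. Zero is reserved for
background, and at most 255 structures fit.

Overlaps between masks are not defined by the exporting platforms, so
the policy is explicit: `last-wins` (default — matching the usual
semantics of mask exports, where later masks overwrite), `first-wins`,
or `error` (which reports the first offending voxel and the two
structure names). For disjoint masks all three are provably identical,
and the suite checks this. Masks on disagreeing grids must first be
brought onto a common grid with `resample_nearest()`; nearest-neighbour
is the only resampler offered for masks and labels because interpolated
label values would be meaningless (a voxel "between" labels 85 and 170
is not label 127).

A single-directory export necessarily collapses overlaps at export time
(one voxel value per voxel); the fixture exporter uses `last-wins`
there, and the end-to-end tests therefore compare single-directory
round trips against the last-wins ground truth under every policy —
after splitting, the masks are disjoint and the policies coincide.

## Rendering

The renderer is a deliberately small software ray caster. The
literature the imported scenes come from names the illumination
ingredients (lights, shading, camera, projection; per-object colour and
opacity) but no equations, so the package fixes a fully standard model
and documents it:

* **Camera.** Orthographic or perspective; `camera_up` must not be
  parallel to the view direction (error otherwise). The orthographic
  window width `view_width` (mm) defaults to the volume's bounding
  sphere diameter; `fov_degrees` (default 30) is the vertical field of
  view in the perspective case.
* **Sampling.** Rays march in physical space with step
  `step_size_voxels * min(spacing)` (default 0.5 voxels); scalar
  volumes are sampled trilinearly, label volumes by nearest neighbour.
* **Transfer functions.** 1D: piecewise-linear RGBA interpolation
  between control points on the value axis, clamped outside. 2D:
  rectangular regions over (value, gradient magnitude); later regions
  override earlier ones, points in no region are transparent, and the
  optional `linear-edge` falloff scales opacity by the fractional
  distance to the nearest region edge. Rectangles were chosen because
  the source tools' exact 2D widget parameterization is not public; a
  rectangle set is the simplest shape family that can reproduce the
  "separated structure footprints" workflow (`label_footprint()`
  computes exactly those footprints from a joint value/gradient
  histogram).
* **Shading.** Blinn–Phong: `ambient + diffuse * max(0, n·l) +
  specular * max(0, n·h)^shininess`, with the normal `n` the negated
  normalized gradient (central differences, spacing-scaled, one-sided
  at borders). Voxels with zero gradient get ambient only. Defaults:
  ambient 0.2, diffuse 0.7, specular 0.2, shininess 32.
* **Compositing.** Front-to-back: `C += (1-A) a c`, `A += (1-A) a`,
  with the per-sample opacity corrected for step size,
  `a = 1 - (1 - a0)^(step / reference_step)`, reference step one voxel
  (`min(spacing)`), so halving the step does not brighten the image.
  Rays terminate once `A >= opacity_termination` (default 0.99) and are
  composited over the background.

Per-structure "light volumes" are approximated as per-label overrides
(`object_params`: colour, opacity scale, visibility), not as a separate
lighting-volume pass; this is an explicit simplification. Two-volume
overlay rendering samples the label map first at each step (the
segmentation enhances the region of interest), then the original
tomogram, along identical rays.

Numerical notes: the box intersection is done in continuous index
space; trilinear sampling replicates the border voxel beyond the grid;
early termination changes only where accumulation stops, and the
monotonicity test in the suite therefore disables it. The compositing
with step correction is *exactly* step-invariant through homogeneous
regions — only transitions contribute discretization error — which is
why the convergence test uses a piecewise-linear (smooth) transfer
function across the slab boundary.

## Interchange formats

Three standard writers are registered: headerless RAW (little-endian,
slice-major, column-fastest, with a JSON sidecar recording shape, value
kind and geometry — the sidecar is this package's convention and is
optional on read), lossless 8-bit greyscale PNG stacks (zero-padded
numeric filenames define order; inputs outside [0, 255] are min–max
rescaled, a constant volume degenerating to all zeros), and ITK
MetaImage (`.mhd` text header + `.raw` payload, with spacing, offset
and direction matrix mapped between this package's
`(slice, row, col)` convention and ITK's x-fastest order). The test
suite verifies MetaImage and DICOM outputs against independent readers
(SimpleITK, pydicom).

The processed-volume container (`save_processed()`) is a JSON manifest
referencing a MetaImage payload plus the label table, a provenance log
and an MD5 payload checksum. It is an open analogue of the internal
processed formats of GUI volume-exploration tools, not bit-compatible
with any of them — that compatibility is explicitly out of scope
because those layouts are undocumented. Scenes (camera, lighting,
transfer functions, volume paths) serialize to XML with a schema of
this package's own design; unknown elements under the root are
preserved verbatim on rewrite so hand-annotated scene files survive a
load/save cycle.

## The image-analysis battery

RGB screenshots are converted to 8-bit grey with the **unweighted
channel mean** `round((R+G+B)/3)` — the historical default of the
desktop analysis tools this battery mirrors — with CIE luminance
weights available as an option, since which convention the original
analyses used is not recorded. Sobel edges use the standard 3×3
kernels with edge replication at the borders and clamp-to-255 after
rounding (clamping rather than per-image rescaling keeps the operator
deterministic across images). The surface plot is a block-mean
heightfield. Correlation between two images reports Pearson's r and
the least-squares line.

Optical density is calibrated from a step tablet. The tablet tradition
fits a named sigmoid through the steps; since the actual function used
upstream is unknown, the package fits an **exactly interpolating
monotone piecewise-linear curve** instead — every supplied step grey
maps back to its supplied OD exactly (which makes knot recovery
testable), with clamped extrapolation beyond the darkest/lightest
steps. Results that depend on extrapolation may therefore differ from a
sigmoid fit; that is a known limitation.

## The synthetic phantom generator

No real specimen scans ship with the package; the fixture module
generates them. A phantom is a voxel grid (components ≥ 4) with up to
255 geometric structures — spheres, ellipsoids, axis-aligned tubes and
spherical shells, echoing the anatomy classes of typical use
(braincase ≈ shell, endocast ≈ sphere, skeletal elements ≈ tubes) — a
voxel belonging to a structure when its centre lies inside the shape.
The synthetic tomogram paints background grey 20 and per-structure base
intensities evenly spaced over [80, 220] (values chosen to be well
separated in 8 bits, as in a well-exposed CT window), plus seeded
Gaussian noise of SD 2 grey levels (default; a realistic
reconstruction-noise scale for 8-bit data). Generators are pure
functions of (spec, seed): identical inputs give bit-identical outputs,
and the global RNG state is restored afterwards.

The ground-truth manifest records pre-overlap voxel counts, the masks,
and the combined label array under each policy computed by an
independent per-voxel loop — deliberately *not* the merge module's code
path, so end-to-end tests compare two independent routes.

The default step tablet has 21 steps linearly spaced over OD
0.05–3.05, with band brightness following the transmittance model
`grey = 255 * 10^-(OD - od_min)` (lightest band normalized to 255).
Under this model the darkest bands differ by less than one grey level,
so an 8-bit rendering cannot resolve them; the generator therefore
returns the exact band mean greys as the calibration knots alongside
the quantized image, and calibration is fit from band means, not from
quantized pixels. The "unresolvable steps" error fires when two bands'
exact greys coincide (degenerate OD spacing), not on 8-bit rounding
collisions — otherwise the default tablet itself would be rejected.

What the phantoms do **not** emulate: scanner artefacts (beam
hardening, rings), partial-volume effects at structure boundaries,
anisotropic noise, vendor-private DICOM tags, and irregular slice
spacing. Passing tests therefore demonstrate correctness of the
transfer/merge/render/export machinery on clean geometry, not
robustness to degraded acquisitions.

## Problem sizes and tolerances in the suite

The suite runs on grids of 3³–30³ voxels, 20 random phantoms for the
end-to-end interoperability property, 100 random instances for the
merge and analysis oracles (images up to 32²), 100 random transfer
functions and 50 random scenes for the round-trip properties — sizes at
which the brute-force oracles stay exact and fast. Integer round trips
are checked bit-exactly; geometry to 1e-9 mm; calibration knot recovery
to 1e-9 OD; the renderer's two-slab composite to 1% with a 0.25-voxel
step, per the step-size-refinement character of that check.
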