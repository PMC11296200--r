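# segrevis

Revisualization of segmented volume data exported as DICOM.

## The problem

3D segmentation is routinely done in commercial visualization platforms
(Mimics, Avizo, VG Studio) whose native project formats do not travel.
What does travel is DICOM: every mainstream platform can export a
segmentation as plain DICOM slice series — either **one series per
segmented structure** (Mimics/Avizo mask exports, possibly zipped) or
**one combined series** in which each structure carries its own voxel
value (VG Studio). `segrevis` imports both layouts, collapses the
per-structure masks into a single labelled volume, re-renders it with
1D/2D transfer functions through a software ray caster, and exports the
result in open interchange formats — so a segmentation made in one tool
can be inspected, re-rendered and cross-validated anywhere. An image
analysis battery (histograms, Sobel edges, surface plots, optical
density calibrated against a step tablet, image-pair correlation)
supports quantitative comparison of renderings from different tools.

It is aimed at researchers in comparative morphology, paleontology and
biomedical imaging who receive segmented volumes from collaborators and
need to re-examine them without the software that produced them.

## The method in brief

* **Label fusion.** Each of the *n* structures is assigned the 8-bit
  voxel value `v_k = round(k * 255 / n)`, `k = 1..n` — evenly spaced
  over [1, 255] so structures stay separable along the value axis of a
  transfer function. Voxels claimed by several structures are resolved
  by a configurable overlap policy (`last-wins` by default).
* **Rendering.** Per-pixel rays are cast through the volume in physical
  space (orthographic or perspective), sampled trilinearly (scalars) or
  by nearest neighbour (labels), shaded with Blinn–Phong using the
  negated normalized gradient as surface normal, and composited front to
  back: `C += (1 - A) a c`, `A += (1 - A) a`, with per-sample opacity
  corrected for step size as `a = 1 - (1 - a0)^(step / reference_step)`.
* **Densitometry.** A synthetic 21-step tablet spanning optical density
  0.05–3.05 (transmittance model, `grey ∝ 10^-OD`) calibrates a
  monotone piecewise-linear grey→OD curve; `median_od()` maps an image
  through it.

## Worked example

```r
library(segrevis)

# a synthetic specimen: shell (braincase), sphere (endocast), tube (spine)
spec <- phantom_spec(
  grid_shape = c(24, 24, 24),
  structures = list(
    list(name = "braincase", shape = "shell", centre = c(11, 11, 11),
         inner_radius = 6, outer_radius = 9),
    list(name = "endocast",  shape = "sphere", centre = c(11, 11, 11), radius = 5),
    list(name = "spine",     shape = "tube", axis = "slice",
         centre = c(11, 11), radius = 2)),
  seed = 7)
ph <- generate_phantom(spec)

# vendor-style export (one DICOM series per structure), then re-import
layout <- export_vendor_style(ph$masks, style = "multi-dir", out_root = "export")
masks  <- read_export(layout)
labels <- merge_masks(masks, policy = "last-wins")
labels
#> label_map: 3 structure(s) on a 24 x 24 x 24 grid
#>  label_id      name voxel_value voxel_count
#>         1 braincase          85        2096
#>         2  endocast         170         396
#>         3     spine         255         312

identical(labels$grid$data, ph$manifest$combined[["last-wins"]])
#> [1] TRUE

# open containers and interchange formats
save_processed(labels, "phantom.pvl.json")   # MetaImage payload + label table
write_metaimage(labels$grid, "phantom.mhd")  # readable by ITK/SimpleITK

# optical-density calibration from the default synthetic step tablet
tablet <- generate_step_tablet()
cal <- fit_calibration(tablet$greys, tablet$ods)
cal
#> calibration_curve: 21 steps, OD [0.05, 3.05], grey [0.255, 255]
predict(cal, tablet$greys[c(1, 11, 21)])
#> [1] 0.05 1.55 3.05
round(median_od(tablet$image, cal), 3)
#> [1] 1.554
```

The three structures receive voxel values 85/170/255 (the evenly spaced
scheme for n = 3); the merged volume is bit-identical to the generator's
ground truth; the calibration curve returns each band's ground-truth
density at its mean grey, and the tablet's own median OD falls at the
middle band.

A thin command-line wrapper covers the same pipeline:

```sh
Rscript inst/cli/segrevis.R import --mode multi export/braincase \
    export/endocast export/spine --out vol.pvl.json
Rscript inst/cli/segrevis.R render vol.pvl.json --out render.png
Rscript inst/cli/segrevis.R export --format metaimage vol.pvl.json vol.mhd
```

## Scope notes

The processed volume container (`*.pvl.json` + MetaImage payload) is an
**open analogue** of the internal processed formats of GUI volume
exploration tools; it is deliberately documented and hash-checked, and
is **not bit-compatible** with any vendor-internal format. DICOM-SEG,
RTSTRUCT, multi-frame enhanced DICOM and compressed transfer syntaxes
are out of scope, as are GPU rendering and movie export.
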