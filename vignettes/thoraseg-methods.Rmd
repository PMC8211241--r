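---
title: "Automated thoracic segmentation of mouse lung microCT: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Automated thoracic segmentation: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(thoraseg)
```

## The problem

Autochthonous lung tumors in genetically engineered mice displace
air-filled lung with soft-tissue density. On non-contrast microCT the
tumor itself cannot be cleanly delineated from heart, vessels and
esophagus, but the *loss of lung* is a robust, quantitative surrogate:
the fraction of the thoracic cavity that is air-density falls as burden
grows. `thoraseg` measures that fraction fully automatically, so that
longitudinal studies with hundreds of scans can be read out without
analyst variability.

## Pipeline model and assumptions

The pipeline assumes: (i) bone is the densest tissue in the field of
view and the ribcage is the largest connected bone structure; (ii) the
thoracic cavity is, per axial slice, a single star-shaped region
enclosed by ribs and spine; (iii) in-cavity densities form three
separable modes (air-filled lung < intermediate < soft tissue); (iv) the
trachea is the most cranial central air column and splits in two at the
carina; and (v) the diaphragm produces, in each axial column, a density
step from dense abdomen below to air-filled lung above.

Working through the stages:

**Cavity mask.** Bone thresholding, largest 3D component
(26-connectivity by default), and a 3-slice union stack that bridges the
slice-to-slice jumps of obliquely-running ribs. Per slice, 8-connected
bone regions of at least `min_region_px = 3` pixels contribute their
boundary pixels to a pooled point set; the points are ordered clockwise
(decreasing mathematical angle from pi, ties broken by radius — fixed so
the cyclic order is reproducible) and joined by a closed periodic cubic
spline, sampled at ≥ 4x point density and filled by an even-odd
scanline rule that marks pixel centres inside the curve (this keeps the
rasterized area unbiased; a contour that fails to enclose its own
polygon area falls back to the control-point polygon). Pass 2 repeats
the outline using only the innermost `refine_fraction = 0.3` of points
about the pass-1 mask centroid — the mask centroid is computed per
slice, which we consider the natural reading since the refinement
corrects per-slice outline errors. The pass-2 mask is intersected with
pass 1, making refinement shrink-only by construction: the refinement
exists to keep intercostal muscle *out*, so it must never grow the
cavity. Slices with fewer than `min_regions = 3` bone regions inherit a
neighbouring mask only within 2 slices; beyond that they stay empty
rather than inventing anatomy.

**Auto bone threshold.** The data-driven threshold is a two-stage Otsu:
stage 1 on intensities above the volume median separates tissue from the
air-dominated background (air is typically more than half the grid, so
the volume median sits at air density and a single Otsu pass lands at
the air/tissue split, far below bone); stage 2 on the voxels above that
split isolates the bimodal bone/soft transition. A fixed numeric
threshold can be supplied instead.

**Density clustering.** One-dimensional k-means, k = 3, k++ seeding,
Lloyd iterations capped at `max_iter = 100`, fitted once per scan on the
pooled in-mask intensities — an intra-scan normalization that absorbs
calibration drift between scanners and sessions. Only in-mask voxels
after bone removal are clustered; bone remnants would otherwise drag the
soft centroid upward. Ascending centroids map to lung / intermediate /
soft. Exact midpoint ties go to the lower-density class. An emptied
cluster is re-seeded at the value farthest from its nearest centroid. By
default `restarts = 3` independent seedings keep the best objective,
with the first restart seeded deterministically at the `(2j - 1) / 2k`
quantiles — a strong one-dimensional initializer that reliably escapes
the rare shared Lloyd basin pure k++ restarts can fall into —
and `restarts = 1` reproduces a single pure k++ run. Above 5e6 in-mask voxels
a deterministic stride subsample fits the model and every voxel is then
classified, bounding memory without changing assignments.

**Axial bounds.** The cranial cutoff scans caudally through the
cranial-most 25% of slices for the first slice whose central lung-class
structure (components with centroids within half the mask's equivalent
radius, each ≥ `min_airway_px = 4` px) consists of exactly two disjoint
parts — the carina. Restricting to the cranial quarter avoids mistaking
paired bronchi deep in the lung for the bifurcation. The
heart–diaphragm interface is the argmax of the per-slice lung fraction,
ties resolved caudally. Under extreme burden the max-lung slice can
shift caudally from the anatomical dome apex; the pipeline logs the
bounds and proceeds (percent recovery is unaffected in our phantom
sweeps, but the interface index itself should not be over-interpreted in
that regime).

**Diaphragm.** Each in-mask column's intensity trace from the caudal end
to the interface is smoothed by a centred moving average
(`smoothing_window = 5` slices, edge-replicated) and the inflection
taken at the steepest descending gradient; the smoothed drop across it
must exceed 4x a robust noise scale (`mad(diff(trace)) / sqrt(2)`) and
the trace's dynamic range must exceed twice its MAD, otherwise the
column is declared unresolvable. The window and the significance rule
were validated against the closed-form logistic step (inflection
recovered within ±1 slice). Because the diaphragm is one connected
surface, unresolvable columns — chiefly the mediastinum, where dense
tissue sits both above and below the dome — receive the inflection
height interpolated from resolvable neighbours by iterative 8-neighbour
averaging. Everything caudal of the surface, intersected with the mask,
is removed from all counts.

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| `bone_threshold` | `"auto"` | intensity | bone gate; two-stage Otsu when auto |
| `connectivity` | 26 | — | 3D component connectivity |
| `stack_window` | 3 | slices | rib smoothing union |
| `refine_fraction` | 0.3 | — | innermost points used in pass 2 |
| `k_clusters` | 3 | — | density classes |
| `max_iter` | 100 | iterations | Lloyd cap |
| `restarts` | 3 | — | k++ restarts (1 = single run) |
| `min_region_px` | 3 | px | minimum bone region |
| `min_regions` | 3 | — | regions needed to outline a slice |
| `min_airway_px` | 4 | px | minimum airway component |
| `smoothing_window` | 5 | slices | diaphragm trace smoothing |
| `seed` | 1 | — | all pipeline randomness |

## The phantom: what it emulates, and what it does not

`generate_phantom()` renders a stylized thorax directly in image space:
an elliptical cavity tapering cranially, a closed ribcage (in-plane rib
arcs with intercostal gaps, a dorsal spine column, and staggered bridge
slices — every third slice closes one gap — so the ribcage is a single
3D component while typical slices still show `2 * rib_count + 1`
separate bone regions), two lung wings separated by a mediastinal
corridor that widens cranially (so the lung fraction peaks just above
the diaphragm dome apex, as in vivo), a heart ellipsoid, one tracheal
column splitting into two bronchi at the bifurcation slice (lumens are
preserved through tumors), a soft-density diaphragm dome, an
intermediate-density pleural lining and heart/tumor shells, and optional
spherical tumors that overwrite lung only. Intensities are per-class
Gaussian noise around configurable means (defaults 0.05 / 0.35 / 0.55 /
1.0, SD 0.03 — arbitrary units, since the pipeline only uses ordering);
optional in-plane Gaussian blur emulates minor respiratory motion on the
intensities while labels stay exact. Geometry constants were fixed once
so the default tumor-free composition sits near the field's typical
non-diseased readout (~40% lung, ~37% soft, ~20% intermediate).

The phantom does **not** emulate projection-space physics (beam
hardening, ring artifacts, reconstruction filters), partial-volume
mixtures at tissue interfaces, breathing deformation, textured
ground-glass opacities (intermediate tissue is uniform shells and
linings), or anatomical variation beyond the parameterized geometry.
Passing phantom tests therefore demonstrates the pipeline's geometric
and statistical logic — not its robustness to scanner physics, which
only real scans can establish.

## Numerical choices and degenerate inputs

* Component-size ties keep the component containing the smallest linear
  index; clockwise ordering starts at angle pi with radius tie-breaks —
  both fixed so reruns are bit-identical.
* Degenerate spline contours fall back to the control-point polygon;
  all-coincident points, empty bone masks, empty point pools and
  sub-minimum point counts raise descriptive errors.
* `dice()` of two empty masks is defined as 1; `spearman_rho()` on
  constant input errors (undefined).
* The interface at the caudal scan end yields an empty diaphragm with a
  warning; a missing bifurcation errors with a pointer to the
  `z_cranial` override.
* k-means on fewer than k distinct values errors
  (degenerate distribution).

## Test problem sizes

The unit suite runs on 96 x 96 x 72 phantoms (~1 s to generate, ~4 s to
segment); the acceptance-style suite and `scripts/acceptance.R` use the
full 160 x 160 x 120 study scale — 5 phantoms for mask fidelity, 10 with
randomized geometry for bound recovery, a 10-level nested tumor family
(ground-truth lung fractions spanning roughly 21–42%) for burden
recovery, 50 arrays of up to 200 values against the exact
dynamic-programming optimum for the clustering. These sizes were chosen
so the whole validation completes in minutes on one CPU while every
stage is still exercised at realistic anatomy-to-voxel proportions.

## Known limitations

* The mask follows the spline through the innermost rib points, so a
  thin band of intercostal tissue just inside the rib line is counted as
  cavity; on phantoms this biases `pct_lung` by about −2 to −3 points at
  study scale (larger on coarser grids). Longitudinal *changes* are
  unaffected since the band is stable across timepoints.
* The interface rule ("slice with the highest lung percentage") is not
  anatomically anchored under extreme burden (see above).
* Mediastinal diaphragm columns carry no intrinsic density step; their
  interpolated surface is only as good as the resolvable neighbours.
* `k_clusters` other than 3 changes the class map to generic cluster
  names; the tissue readout assumes 3.
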