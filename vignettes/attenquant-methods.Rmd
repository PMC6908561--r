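---
title: "Quantifying attenuation artifacts in myocardial perfusion SPECT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying attenuation artifacts in myocardial perfusion SPECT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(attenquant)
```

## The measurement model

Soft-tissue attenuation removes counts from parts of the left-ventricular
myocardium in SPECT perfusion images. Reconstructing the same acquisition
twice — once without attenuation correction (NAC) and once with CT-based
correction (AC) — isolates the artifact: wherever the correction restored
counts, the NAC image is depressed relative to the AC image, while genuine
perfusion defects, being physiological, appear identically in both.

`attenquant` quantifies the artifact on a slice × sector grid. A fixed
number of short-axis slices is analyzed, counted from the base: the slice
count is a camera constant tied to the voxel thickness (20 slices at 4 mm
for the CZT profile, 12 at 6.4 mm for the conventional profile), so both
cameras cover a comparable axial span (80 mm vs. 76.8 mm). Each slice is
divided into twelve 30° sectors about the LV centre, each voxel assigned by
the angle of its centre under a half-open binning rule. Segment counts are
normalized by the grand total over all analyzed segments, and the
per-segment ratio of normalized NAC to normalized AC counts is the artifact
descriptor.

The artifact mask is a pure threshold on that ratio — every defined segment
with ratio strictly below the camera threshold (0.90 CZT, 0.85
conventional). Three summary metrics follow:

* **extent** — artifact segments over total segments;
* **localization** — the circular mean (mean resultant direction) of the
  artifact segments' sector-centre angles;
* **depth** — mean NAC counts in the artifact segments divided by the mean
  over the `round(0.30 × n_total)` highest-count segments (72 of 240 for
  CZT, 43 of 144 conventional).

### Why segments without attenuation sit slightly above 1

Because each grid is normalized by its own total, removing counts from the
NAC volume raises the normalized value of every unaffected segment by a
common factor `T_AC / T_NAC`. With an artifact carrying a fraction `c` of
the counts at mean transmission `f`, unaffected segments sit at
`1 / (1 - (1 - f) c)` (a few percent above 1) and attenuated segments at `f`
times that. Delineation thresholds well below 1 are unaffected; the small
upward bias is the price of not needing any absolute calibration between
the two reconstructions. The same cancellation makes all three metrics
exactly invariant to a global rescaling of either volume.

### The angular reference frame

The frame places 0° at the anterior wall and increases through lateral
(90°), inferior (180°) and septal (270°); sector *i* covers
`[30(i−1), 30i)` with its centre at `30(i−1) + 15`. This choice puts the
phantom artifact centres (150°–165°) in the inferolateral wall and makes a
counter-clockwise shift point toward the lateral wall, matching the
anatomical description of the CZT-vs-conventional difference. The exact
origin of published polar-map figures is not recoverable, so the frame is a
package convention and can be rotated (`angular_convention(rotation_deg)`).

## Decisions that were genuinely open

**Strict threshold.** Delineation uses `ratio < threshold`, not `≤`: the
artifact is described as segments with a ratio *below* the no-attenuation
level, and strictness makes the noiseless boundary case deterministic. No
connectivity filtering is applied by default (the delineation is the
threshold and nothing more); `connectivity = TRUE` keeps the largest
4-connected component for noisy data.

**Localization weighting.** The artifact "centre" is read as an unweighted
circular mean of member sector centres. A depression-weighted variant
(weights `1 − ratio`) is available via `weighted = TRUE`; on symmetric
artifacts the two coincide.

**Depth source.** Depth is computed on the NAC grid — the attenuated image,
where the count reduction physically lives — with `source = "ac"` exposed as
a variant. Ties in the top-30% ranking are broken by segment position
(slice, then sector, ascending), making the reference set deterministic.

**Shared in-plane centre.** Both grids of a study are sectorized about one
centre: the count-weighted centroid of the AC counts over all analyzed
slices, snapped to the half-voxel grid. A reoriented short-axis stack has a
straight long axis, so a single in-plane position is the standard polar-map
assumption; the snap makes sector assignment exactly reproducible under
sub-voxel centroid jitter, whether from Poisson noise or from a small cold
defect (which would otherwise drag a per-slice count centroid by close to a
voxel on the affected slices and reshuffle boundary voxels between
sectors). Per-slice centroids remain available (`slice_centers()`) for
ventricles that are not straight after reorientation.

**Undefined segments.** Segments with zero AC counts have no defined ratio;
they are flagged, can never join the mask, and by default stay in the
extent denominator (they are analyzed segments that simply show no
artifact). Degenerate localization cases — an empty mask, or a perfectly
antipodal mask with zero resultant vector — return `NA` with a warning
rather than a fabricated angle.

## The synthetic phantom

The generator emulates a commercial cardiac insert imaged at the two camera
profiles: a cylindrical myocardial shell (outer radius 30 mm, wall 10 mm,
axial length 96 mm, optional hemispherical apical cap beyond the analyzed
span) of uniform expected count density, centred on the grid, with an empty
margin. Defaults were chosen once to be realistic for a phantom acquisition:
500 expected counts per 4 mm voxel puts ≈ 4 × 10³ counts in each CZT segment,
comfortably above clinical count levels, as phantom protocols are.

**Sector equalization.** A binary voxelization of an annulus on a square
grid does *not* put equal voxel counts in all twelve 30° sectors (the
square lattice has two symmetry classes of sectors), so a naively voxelized
"uniform" shell would not have equal expected segment counts and noiseless
fixtures would not be analytically exact. The builder therefore weights
each voxel by (mean sector voxel count / its own sector's count) within
each slice, which makes every segment's expectation exactly equal while
preserving total counts = density × number of shell voxels. This is a
property of the simulated object, not of the analysis pipeline, which never
sees the weights.

**Artifact model.** The artifact is injected as multiplicative transmission
factors `f ∈ (0,1)` on voxels inside non-overlapping angular × axial zones
of the NAC volume only — the simplest generative model consistent with a
ratio below 1 inside the artifact and 1 outside. Zone membership uses the
same half-open angular binning as sectorization, so sector-aligned zones
depress whole segments exactly: a noiseless fixture recovers its injected
mask segment for segment, extent to the rounding of the printed percentage,
depth equal to the (count-weighted) mean transmission, and localization
equal to the circular mean of the injected sector centres. No projection or
reconstruction physics, scatter, resolution recovery or partial-volume
effects are modeled; the realism of the multiplicative model is untested
here, and passing recovery tests demonstrates correctness of the
quantification, not fidelity of the artifact physics.

**Defects.** A solid defect scales the same greedily-filled nearest-voxel
set (within one voxel volume of the requested size, 2.1 cm³ by default) in
*both* volumes. Its invisibility to the delineation and metrics — up to a
single common renormalization constant in the ratio map — is the
computational form of the phantom control in which the defect appears
identically on both cameras while the artifact moves.

**Noise.** Poisson draws are applied independently to the NAC and AC
volumes, reflecting independent emission counting. At the default count
density the segment-level ratio SD is ≈ 0.02, several standard deviations
away from either threshold, so noise essentially never flips a segment; the
known upward bias of ratios of Poisson sums at low counts is acknowledged
and only tested in expectation.

**Cohorts.** Per acquisition, extent (% of segments) and depth (% residual
counts) are drawn from truncated normals — truncation intervals (0, 100)
and (1, 99), sampled by inverse CDF — and the artifact centre from a wrapped
normal. The drawn extent is converted to the nearest achievable segment
count and realized as one contiguous sector-aligned block centred on the
drawn angle (full sector columns plus a basal remainder column), matching
the single contiguous inferolateral/lateral artifact seen clinically; the
transmission factor is depth/100. Rounding the drawn extent to whole
segments changes it by at most 100/(2 × n_total) ≈ 0.21 percentage points.

## Statistics

Cohorts are summarized as mean ± sample SD per camera, with circular mean
and circular SD (`sqrt(−2 log R)`) for localization. Cameras are compared
with a paired t test implemented in closed form (`t = mean(d)/(sd(d)/√n)`,
two-sided p from `pt`), with localization differenced on the circle
(signed shortest angular difference) so pairs straddling 0°/360° do not
produce 350°-sized artifacts. Zero-variance differences are flagged as
degenerate (p = 1 when the mean difference is also zero) instead of
dividing by zero. The implementation agrees with `stats::t.test` to below
1e-9 on the test suite's worked samples, and its null calibration is
checked by simulation: 1000 repetitions of two 20-acquisition truth draws
from identical generators reject at P < .05 at a rate of 5% ± 2%.

## Problem sizes used in the checks

The packaged checks run the full image pipeline on the two reference
phantoms (240 and 144 segments), a 37-acquisition noisy CZT cohort for
extent recovery, and truth-level draws (no image volumes) for the
1000-repetition null calibration — sizes chosen so the whole suite
completes in about a minute while keeping Monte-Carlo error well inside the
stated tolerances.

## Known limitations

* The multiplicative zone model is a stand-in for real attenuation physics;
  nothing here validates it against measured projections.
* The myocardium membership rule (positive AC counts, optional radial band)
  is exact on synthetic shells but is not a substitute for model-based LV
  delineation on clinical images.
* Ratio bias at very low counts (≪ 100 per segment) is not corrected.
* The per-camera thresholds are fixed constants; their observer-based
  derivation is out of scope.
* No 17-segment model, perfusion scoring, or inter-camera registration.
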