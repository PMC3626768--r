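---
title: "Quantifying RFA tumor coverage from pre- and post-treatment CT"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying RFA tumor coverage from pre- and post-treatment CT}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The problem

Radiofrequency ablation (RFA) destroys a hepatic tumor by resistive heating
around a percutaneous electrode. The treatment succeeds when the induced
coagulation necrosis covers the whole tumor plus a safety margin (current
guidelines recommend about 1 cm). On follow-up CT the necrosis appears as a
non-perfused hypodense region, but judging visually whether it truly covers
the pre-treatment tumor is hard: the two lesions live in different scans,
the liver deforms between visits, and the contrast between residual tumor and
necrosis can be subtle. `rfacover` makes the comparison quantitative: it
realigns the post-treatment volume onto the pre-treatment one, segments both
lesions from a handful of operator-picked seed pixels, and reports four
slice-wise coverage indexes.

The pipeline has three image-processing stages — pre-processing,
segmentation, registration — followed by index computation:

1. **Pre-processing**: each axial slice is filtered with a 5×5 median; all
   later processing is restricted to a liver mask (supplied by the caller;
   interactive liver outlining is out of scope); the characteristic liver
   intensity range is estimated from the liver histogram and spread linearly
   over the full 12-bit dynamic range.
2. **Segmentation**: liver voxels are clustered by fuzzy c-means (FCM) into
   `c = 7` clusters labelled 1..7 by ascending centroid intensity; the tumor
   (on the pre image) and the necrosis (on the post image) are grown from
   seed pixels over the cluster-label map.
3. **Registration**: both lesions are replaced by a synthetic parenchyma
   pattern, the volumes are aligned by a global affine plus a B-spline
   free-form deformation (FFD) maximising normalised mutual information
   (NMI), and the resulting transform is applied to the original images —
   the necrosis mask is resampled into pre-treatment space; pre-treatment
   voxels are never resampled.

## Intensity conventions

Volumes are held as `ct_volume` objects: 3D arrays in `(slice, row, col)`
order with `(z, y, x)` spacing in mm, intensities in abstract 12-bit units
`[0, 4095]` (no Hounsfield calibration is assumed anywhere). Voxels excluded
from processing carry the reserved sentinel `-1`; it is never written as
NaN/Inf to files, and every statistic skips it.

## Pre-processing choices

* **Median filter**: 2D per slice. With 5 mm slices, a through-plane median
  would mix anatomically distant tissue; the in-plane 5×5 window matches the
  granularity of CT quantum noise. The filter is idempotent on plateaus and
  removes isolated impulse voxels by construction.
* **Characteristic liver range**: the liver-voxel histogram is built with
  unit-width bins; with modal height $H$, the range is
  $[\mathrm{lo}, \mathrm{hi}]$ where `lo`/`hi` are the lowest/highest
  intensities whose bin reaches `peak_fraction * H`. The default
  `peak_fraction = 0.025` is the midpoint of the 2–3% convention. We read
  "percent of the histogram peak" as peak *height* (not a count percentile);
  for a Gaussian bulk the cut sits at $k\sigma$ with
  $e^{-k^2/2} = 0.025$, i.e. $k \approx 2.7$. Lesion plateaus large enough
  to register on the histogram extend the range, which is what lets them
  survive the remapping with their internal gradations intact.
* **Contrast enhancement**: linear map of `[lo, hi]` onto `[0, 4095]`,
  clipping outside, monotone inside, sentinel untouched, rounded to integer
  units (the histogram-weighted FCM below assumes integer data).

## Fuzzy c-means and the cluster-label map

FCM minimises
$J = \sum_i \sum_k u_{ik}^m (x_i - v_k)^2$
with fuzziness `m = 2`, alternating membership and centroid updates until
the relative change of $J$ falls below `1e-5` (at most 300 iterations;
$J$ is checked to be non-increasing at every step). Because intensities are
integers, the iteration runs on the value histogram — mathematically
identical to the voxel-wise iteration and orders of magnitude faster.

Initialisation matters more than usual here: the parenchyma holds ~95% of
the liver's voxels, and initialising centroids at data *quantiles* puts all
seven inside the parenchyma mode, a local minimum the alternating updates do
not escape — the lesion plateaus then never get their own clusters and the
downstream extraction rules break. We therefore initialise centroids evenly
spaced over the observed intensity *range* (equally deterministic), which
gives minority plateaus their own basins. The RNG seed is used only to
re-seed a centroid in the degenerate empty-cluster case.

## Seed-driven lesion extraction

Operators pick up to 3 pixels per region per slice: the darkest pixels of a
metastasis or uniform necrosis, the brightest of an HCC or of a hyperdense
coagulation area. The mean cluster index of the tumor seeds decides the
kind: below 3.5 a (hypodense) metastasis, otherwise an HCC — a mean of
exactly 3.5 goes to the HCC branch, since only "inferior to 3.5" selects
the metastasis.

Tumors of the kinds treated by RFA are compact in the center and vanish at
the periphery, so in the label map they form concentric rings: indexes rise
from center to periphery for a metastasis and fall for an HCC.
`extract_tumor()` grows regions per slice (8-connectivity): a neighbour is
accepted when its label does not break that monotonicity and stays within a
band of `delta = 3` clusters anchored at the seeds' extreme index (e.g.
clusters 1–4 for a metastasis seeded in cluster 1, matching the observed
span of such lesions in 7-cluster maps). The monotone rule doubles as a
leak barrier: entering the surrounding parenchyma requires walking uphill,
and descending into darker parenchyma pockets is forbidden. Seeds that fall
outside the band (typically picked on faint, partial-volume edge slices)
are warned about and ignored as growth points; hard rejection is reserved
for grossly inconsistent seed sets (all metastasis seeds in the brightest
clusters, or vice versa). Slices without seeds are grown from the projection
of the adjacent slice's component, so the ROI stays connected through the
stack.

`extract_necrosis()` implements the two-cluster rule: a uniformly hypodense
necrosis is the seeded connected component of clusters {1, 2}. When a seed
has label > 2 it marks a hyperdense coagulation area: the connected
hyperdense component containing it is relabelled to cluster 1 first, after
which the uniform procedure applies unchanged.

`morphological_cleanup()` separates real ROIs from artificial extensions:
per-slice binary opening (square element, radius `r_open = 1`), interior
hole filling, retention of the component containing a seed (or overlapping
the adjacent slice's retained component), and clipping to the liver eroded
by one voxel — which also removes partial-volume shells at the liver
periphery. If cleanup would empty the mask, the input is returned with a
warning. Hole filling is our addition to the opening: isolated
noise-flipped interior voxels otherwise become pinholes that depress the
match score without any anatomical meaning.

## Registration

The post-treatment volume (moving) is mapped onto the pre-treatment volume
(fixed): $T(x) = A x + D(x)$ with $A$ a 12-parameter global affine and $D$
a cubic B-spline FFD on a regular control grid (default spacing one slice
through-plane, 16 voxels in-plane). Registering post→pre — rather than the
reverse — means the tumor mask is never resampled; this is our convention.
The similarity is Studholme's overlap-normalised mutual information
$(H_f + H_m)/H_{fm}$ with 128-bin histograms: on the 12-bit scale that is a
32-unit bin, fine enough for the parenchymal texture to contribute — with
coarse bins the deformation is driven almost entirely by organ boundaries
and drifts in the organ interior.

Because tumor (pre) and necrosis (post) are different tissues at almost the
same location, a free deformation will happily warp one onto the other —
a fictitious deformation that would corrupt every coverage index. Both ROIs
are therefore replaced, before registration, by a 19×19 patch of uniform
parenchyma (the minimal-variance admissible window, ties towards the lowest
index), replicated across the ROI dilated by 2 voxels. The default
replication is periodic tiling anchored at the ROI bounding box; a
reflected, center-anchored variant is available (`style = "radial"`). The
estimated transform is then applied to the original images.

The optimiser is ours (no deformable-registration engine is required):

* **Affine stage**: Nelder-Mead over translation, then translation +
  in-plane rotation + scale, on an in-plane 2× downsampled level first and
  polished at full resolution.
* **FFD stage**: a coordinate pattern search over control-point
  displacements (steps 2, 1, 0.5 voxels coarse; 0.5 fine) with incremental
  joint-histogram updates, so a trial touches only the 4×4×4 control-cell
  support. A small smoothness penalty (deviation from the 6-neighbour mean,
  weight `5e-4` in NMI units) stops the search from chasing histogram noise.
* **Information-weighted relaxation**: after the search, control points
  whose support carries little fixed-image gradient — the pattern-replaced
  lesion neighbourhood (passed explicitly as an `ignore` mask by the
  pipeline: the tumor dilated by the pattern margin + 8 voxels), uniform
  parenchyma, background — are relaxed towards their neighbours' mean, so
  the deformation there is the smooth interpolation of the surrounding,
  well-determined field. This encodes the physical prior that nothing about
  the local deformation can be learned where the image content was replaced;
  local coagulation-induced deformation inside the ablation zone is
  consequently *not* corrected, a stated limitation of the approach.

Every successful registration satisfies NMI(result) ≥ NMI(identity);
otherwise the identity is returned with a warning. The pipeline registers
the median-denoised, pattern-replaced volumes: measured end-to-end on
phantoms, feeding the contrast-enhanced volumes instead re-amplifies the
unsegmented remnants of the lesions' vanishing edges and degrades recovery.

## Coverage indexes

All four indexes are computed slice-wise in 2D with in-plane mm scaling;
only volumes use the 3D voxel volume. The 5 mm slice thickness makes
through-plane geometry too coarse for margins and orientations, and the
clinical reporting convention is per-slice mean ± SD or min–max.

* **Residual tumor**: voxels of the pre-treatment tumor not inside the
  (realigned) necrosis; reported in cm³ and as % of the tumor. The lesion is
  *totally treated* iff no slice carries a residual voxel; partial-volume
  boundary voxels count as tumor (conservative).
* **Tumor-free margin (T.F.M.)**: per slice, the tumor is dilated by the
  unit 8-connected element until it escapes the necrosis; the margin is the
  number of complete dilations × in-plane pixel size. A slice whose tumor
  is not fully covered scores 0. With the 3×3 element, one dilation grows
  the mask by one Chebyshev unit, so the count equals the minimum Chebyshev
  distance from tumor to non-necrosis minus one — the brute-force oracle
  the tests check against.
* **Inter-barycentric distance** $|B_T - B_N|$: Euclidean in-plane distance
  between the two centroids, per slice, mean ± SD over slices carrying both.
* **Orientation index (O.I.)**: each cross-section gets the ellipse with
  equal second-order central moments; the index is
  $|\theta_T - \theta_N|$ with each major-axis angle
  $\theta = \tfrac12\,\mathrm{atan2}(2\mu_{11}, \mu_{20}-\mu_{02})$ taken
  in [0°, 180°). The [0°, 180°) convention is required for the clinically
  critical 60°–120° band to be expressible (a [0°, 90°] line-angle
  convention could not exceed 90°); its price is a discontinuity at the
  0/180 wrap, where joint-rotation invariance holds only up to that fold.
  Near-circular sections ($\sqrt{(\mu_{20}-\mu_{02})^2 + 4\mu_{11}^2} <
  0.02\,(\mu_{20}+\mu_{02})$) have no defined axis: the slice is flagged
  and excluded from the summary.

`ideal_margin_mask()` renders the 1 cm-margin contour a guideline-conform
ablation should have reached, for overlay figures.

## Segmentation validation

`confusion_counts()` tallies TP/FP/TN/FN of an algorithm mask against a
ground-truth mask *within the liver* — counting the whole image would let
the background inflate the negative classes. The four indexes are
PM = 100·TP/(TP+FN) (sensitivity), P+ = 100·TP/(TP+FP) (precision),
SPEC = 100·TN/(TN+FP), P− = 100·TN/(TN+FN). An index with a zero
denominator is reported as undefined (`NA`), never as 0. A formula variant
with the specificity denominator TP+FP circulates in print; it is available
behind `printed_variant = TRUE`, the standard definition being the default.

## The phantom generator

Every stage above is testable without patient data through
`make_phantom_pair()`, which renders a pre/post pair with known geometry,
noise and deformation:

* **Liver**: an ellipsoid whose through-plane radius exceeds the 12-slice
  stack, as in real abdominal acquisitions where the organ extends beyond
  the imaged section (an ellipsoid "pole" inside the stack would make
  whole-slice mask content flip under sub-voxel through-plane shifts, which
  no registration could represent). Base intensity 2200.
* **Intra-liver texture**: a triangle-wave field (amplitude 50, vessel-scale
  wavelengths ~17–22 voxels in-plane, a dominant and a minor component)
  tied to the anatomy so it deforms between visits. Real livers are not
  flat: perfusion and vessel structure broaden the intensity histogram and
  give the registration something to grip. Without it, the 2.5%-of-peak
  range collapses to a razor around the parenchyma peak and no lesion
  survives the remapping; triangle waves specifically give a flat (uniform)
  intensity distribution rather than piling mass onto singular histogram
  peaks the way sinusoids do.
* **Tumor**: three concentric ellipsoidal rings (fractions 0.35/0.78/1 of
  the outer radii, ~2.6–3.4 cm lesions), intensities rising outward for a
  metastasis (1000/1450/1850) and falling for an HCC (3400/2950/2550), with
  a 1.5-voxel "vanishing edge" on the outermost ring — the gradual fade
  into parenchyma these lesions show, whose partial-volume shell is also
  what anchors the intermediate FCM clusters.
* **Necrosis**: a hypodense ellipsoid (900) replacing the tumor, optionally
  containing a hyperdense coagulation patch; its offset and margin relative
  to the tumor set the ground-truth residual.
* **Noise**: Gaussian σ = 12 (≈0.6% of the dynamic range, a smooth-kernel
  5 mm reconstruction) plus 0.5% salt-and-pepper impulses to exercise the
  median filter.
* **Deformation**: an affine (1.2° in-plane rotation, 0.4% scale, 2–2.5
  voxel translation) composed with a low-frequency sinusoidal displacement
  (1.8 voxels in-plane, 0.2 slices through-plane, wavelengths ≥ 110
  voxels) — smooth, invertible, and exactly representable by the B-spline
  model class. Through-plane translation defaults to 0: sub-slice-thickness
  z motion is unresolvable at 5 mm and would only inject irreducible error.
  The post volume is rendered by numerically inverting this map at every
  voxel (fixed-point iteration on the analytic field), so the stored
  ground-truth transform *is* the fixed→moving resampling map to well under
  0.1 voxel.

`phantom_study_specs()` freezes ten phantoms — alternating metastases and
HCCs, necrosis margins from +4 to 0 voxels and offsets up to (7, 6) —
spanning ground-truth residual 0–40%, used by the end-to-end tests and the
acceptance script.

What the phantom does **not** emulate: CT physics beyond linear
partial-volume mixing (no beam hardening, no streaks), discrete vessels and
bile ducts, ablation-induced tissue contraction, ascites, breathing motion
within a scan. Passing the phantom suite therefore demonstrates the
pipeline's internal consistency and its behaviour under known geometry and
smooth deformation — not clinical performance on patient data.

## Problem sizes and tolerances

The reference phantom grid is 160×160×12 at 1×1×5 mm (a full 512-grid is a
`phantom_spec` parameter away); unit tests use a 96×96×8 variant. FCM runs
to `tol = 1e-5` relative objective change; registration uses 128 NMI bins,
one coarse level at 2× in-plane downsampling, pattern-search steps down to
half a voxel, and a minimum accepted NMI gain of `2e-6` per move.
End-to-end on the ten-phantom schedule, the pipeline tracks ground-truth
residual within 5 percentage points with exact totally-treated
classification — the property the acceptance tests assert; the tests also
hold tumor PM/P+ and SPEC/P− above 90/94/96/92 and necrosis PM/P+ above
90/94 at default settings.

## Known limitations

* Local deformation inside the ablation zone is interpolated, not measured
  (by design — the content there was replaced); coagulation-induced
  contraction is not modelled.
* The liver mask is an input: its quality bounds everything downstream.
* The orientation index inherits the 0/180 wrap discontinuity of its
  convention.
* Segmentation is 2D-slice-based with overlap linking; a 3D clustering with
  spatial regularisation would be the natural extension for thin-slice
  data.
* DICOM series input is not supported in this implementation; convert to
  NIfTI first.
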