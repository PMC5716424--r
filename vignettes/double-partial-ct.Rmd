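---
title: "Stitching double partial CT acquisitions: method and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stitching double partial CT acquisitions: method and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctstitch)
```

## The problem

A planning CT must show the patient in a natural, uncompressed posture,
because radiotherapy dose calculation integrates CT numbers along every
candidate beam path. Oversized patients exceed the reconstruction field of
view (and sometimes the bore) of many scanners: a single scan then truncates
one lateral side and compresses the tissue pressed against the bore.
Interpolating the missing anatomy fabricates CT numbers and is not a safe
basis for dose calculation.

The alternative implemented here is to scan the patient twice with identical
imaging parameters — once shifted so the **left** half of the body is
complete and uncompressed, once so the **right** half is — and to merge the
two partial volumes into one complete volume. Markers and constant couch
height keep the residual anterior–posterior (AP) and superior–inferior (SI)
misalignment to a voxel or two; the substantial unknown is the lateral
(right–left, RL) overlap between the two scans.

## The model

Both scans image the same rigid anatomy, so the transformation between them
is a pure integer translation `(ΔSI, ΔAP, ΔRL)`. The registration objective
is the mean-square CT-number difference over the overlap region of interest:

$$\Delta I_{ROI} = \frac{1}{N}\sum_{V\in ROI}\big[I_L(V) - I_R(V)\big]^2,$$

minimized over the three overlap parameters. Evaluating this on full 3D
blocks for every candidate would be wasteful; because both scans contain the
spine — a bright, high-contrast, anatomically fixed structure — a 1D
surrogate suffices. A horizontal **line profile** through the middle of the
spine is extracted from each scan,

$$\vec L(y_c, z_c) = \{I_L(y_c, z_c, x_i)\},\qquad
  \vec R(y_c, z_c) = \{I_R(y_c, z_c, x_j)\},$$

and candidate overlaps are scored by the RMSE between the facing segments:
the last $\Delta x$ samples of the left profile against the first
$\Delta x$ samples of the right profile,

$$\mathrm{RMSE}(\Delta x) = \sqrt{\frac{1}{\Delta x}
  \sum_{i=0}^{\Delta x - 1}
  \big[L_{N_L-\Delta x+i} - R_i\big]^2}.$$

The true overlap minimizes this curve. Two search strategies are provided:

* **Varied-length matching** (`match_varied()`): scan every overlap width
  from `delta_min` up to the shorter profile. This is the general tool and
  exact on clean data.
* **Fixed-length matching** (`match_fixed()`): slide a fixed window
  (`query_len` samples, centered on the spine column) along the right
  profile. Because the query always contains bone, every candidate score is
  informative; this is the robust choice on noisy scans (see "matcher
  choice" below). The best shift is converted to an equivalent overlap so
  both matchers report on one scale.

Residual AP/SI misalignment is resolved by an exhaustive neighbourhood
search (`estimate_offsets()`): the left profile at `(y_c, z_c)` is matched
against right profiles at `(y_c - Δy, z_c - Δz)` for all `Δy`, `Δz` in small
windows, and the candidate with the globally smallest profile RMSE wins.

## Subtraction-and-merge fusion

The columns at each scan's truncated edge may be deformed by contact with
the bore. Those bands face each other inside the overlap, so they are
**subtracted once, before matching**: `margin` columns are removed from the
right end of the left profile/volume and the left end of the right
profile/volume, and the same trimmed geometry feeds both the matcher and
`fuse()`. The reported `delta_rl` is on the scale of the volumes as given
(`matcher optimum + 2·margin`), so the ground-truth overlap is recovered
unchanged whatever margin is configured, and nothing is subtracted twice.

After SI alignment (`align_si()`, dropping unpaired edge slices) and AP
alignment (`align_ap()`, whole-row shift with air fill), merging copies each
non-overlap column from its only source and fills the overlap by one of
three modes: left-centered, right-centered, or average. Averaging two scans
with independent noise $\sigma$ reduces the overlap noise toward
$\sigma/\sqrt 2$; with integer-valued inputs the average is rounded
half-to-even so reruns are bit-identical. No feathering or histogram
matching is applied — the three modes are deliberate hard rules, and a seam
in left-/right-centered mode is visible exactly where the two scans
disagree.

## Axis and orientation conventions

Volumes are stored `[slice, row, column]` with rows increasing
anterior→posterior and columns running across the displayed image. The
left-sided scan occupies the **low-column** end of the stitched field with
its right-facing edge truncated; the right-sided scan occupies the
high-column end with its left-facing edge truncated. This is the geometry in
which "the right portion of the left-sided scan overlaps the left portion of
the right-sided scan", and it makes the RMSE pairing above exact. Positive
`delta_ap` means the left scan's content sits that many rows lower
(posterior) than the right scan's; positive `delta_si` means a structure on
left slice `y` appears on right slice `y - delta_si`.

## Tunable parameters

| key | default | meaning |
|---|---|---|
| `bone_threshold_hu` | 150 | bone/soft-tissue cutoff for spine scoring and profile preprocessing; a standard cortical/cancellous boundary |
| `rect_half_width/height` | 8 | spine rectangle half-extents (voxels); customizable per patient |
| `delta_min` | 8 | smallest overlap the varied matcher considers; tiny windows are noise-dominated |
| `margin` | 0 | columns subtracted from each truncated edge; set to at least the visible deformed band width |
| `ap_window`, `si_window` | 3, 2 | exhaustive search half-widths; markers keep true shifts within a voxel or two |
| `preprocess` | TRUE | match on bone-floored profile copies; fusion always uses originals |
| `query_len` | 32 | fixed-matcher window; must exceed the spine width and fit inside the overlap |
| `mode` | average | fusion rule for the overlap |

## Numerical and design choices

**Index direction and sample count.** The RMSE pairing runs both profiles in
the same spatial direction (left suffix against right prefix, in order) and
averages over exactly $\Delta x$ samples. The square root is applied; since
$\sqrt{\cdot}$ is monotone the minimizing overlap is the same either way,
which the test suite checks explicitly.

**Tie-breaking.** Within one match curve, exact RMSE ties resolve to the
*largest* overlap. On bone-preprocessed profiles this matters: a narrow
window containing no bone on either side is exactly zero and ties with the
true overlap on clean data; the widest consistent overlap is the true one.
Across AP/SI candidates, ties resolve to the largest overlap first, then to
the smallest `(|ΔSI|, |ΔAP|)`. Spine-rectangle score ties resolve to the
most anterior, then most leftward admissible center.

**Matcher choice.** With bone preprocessing enabled, the floored segments of
a profile are exactly zero, so the varied matcher's short no-bone windows
score zero RMSE regardless of noise; on *noisy* data they beat the true
(noisy, nonzero) overlap and the varied matcher underestimates. The fixed
matcher is immune because its query always contains the bone plateau. Hence
the working rule implemented in the defaults and exercised by the tests:
varied matching for clean or raw-profile work, fixed matching for noisy
scans. Both are exact on clean data.

**Spine search.** The score is the rectangle sum of `max(I - threshold, 0)`,
computed with a summed-area table that is exactly equal to (and tested
against) the brute-force scan over all admissible centers. One reference
slice (the middle one by default) anchors a single rigid offset; per-slice
detection would add nothing under a rigid-translation model.

**Degenerate inputs.** Volumes without any voxel above the bone threshold in
the search region are refused with instructions to supply `manual_center`
(the rectangle is per-patient customizable). Crops below two columns,
overlaps consumed by margins, and SI shifts consuming all slices are
errors, not silent clamps.

## What the synthetic phantom does and does not emulate

`generate_phantom()` builds an air background, an elliptical soft-tissue
body (HU ≈ 40) nearly filling the field laterally, and a bright posterior
bony insert (HU ≈ 700) standing in for the spine. Two features carry the
identifiability of the alignment problem and are on by default:

* a smooth random texture (sd 10 HU, bilinearly upsampled from a coarse
  grid, applied to the whole body *including* the bone — trabecular bone is
  heterogeneous in reality, and a texture-free plateau would make bone-only
  profiles constant and slices indistinguishable);
* a ±1-column per-slice jitter of the insert.

`split_phantom()` then produces the two partial scans with exactly known
offsets, optional linear edge compression over a configurable band
(nearest-neighbour index compression — the simplest model that makes the
subtraction margin necessary and testable), and independent per-scan
Gaussian noise, everything rounded to integer HU.

The phantom does **not** model beam hardening, scatter, reconstruction
artifacts, partial-volume effects at tissue boundaries, couch or
immobilization hardware, or realistic deformation mechanics of compressed
tissue. Passing the phantom suite therefore demonstrates the correctness of
the geometry, the matching arithmetic and the fusion bookkeeping — not
clinical performance on real scanners, where profile shapes are richer and
deformation is not a simple lateral compression.

## Problem sizes and what the tests compute

The crop-and-reconstruct identity runs on a 20 × 128 × 192 phantom (the
full validation volume, roughly half-resolution relative to a clinical
512-matrix scan); parameter sweeps run on an 8 × 64 × 160 phantom so that a
105-point offset grid, 100 noise trials and 20 deformation trials complete
in seconds. The acceptance script repeats the same computations at slightly
reduced trial counts and reports: the mismatch count of the identity check
(expected 0), the recovered crop overlap (expected 96 of 192 columns), the
percentage of exactly recovered clean splits (expected 100), the percentage
of noisy trials with the overlap within ±1 column (σ = 20 HU), the
percentage of deformed-edge trials recovered exactly under `margin = 8`,
and the average-fusion residual ratio (expected ≈ 0.71 = 1/√2).

## Known limitations

* Translation-only: no rotation, no deformable registration, no sub-voxel
  estimation. Mismatched voxel spacing between the scans is an error, not a
  resampling trigger.
* The method requires the spine (or another bright rigid structure) inside
  the overlap; `query_len` must fit inside the overlap for the fixed
  matcher.
* Under noise the AP/SI components may land a voxel or two off even when
  the overlap is right: neighbouring rows and slices of smooth anatomy (and
  especially of this phantom, whose slices differ only by texture and
  insert jitter) are nearly identical, and the profile RMSE difference
  between them falls below the noise floor. The overlap itself is anchored
  by the high-contrast bone plateau and stays within a column.
* DICOM support covers uncompressed little-endian single-frame CT series
  only; the deformed-edge model is a stand-in, not a validated model of
  bore compression.
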