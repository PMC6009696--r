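---
title: "Measuring chromosome territory radial position: model, simulator and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring chromosome territory radial position}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ctRadial)
```

## The measurement

`ctRadial` quantifies where a chromosome territory sits between the
nuclear centre and the nuclear periphery. The construction is purely
geometric. The nucleus counterstain channel is thresholded, reduced to
its largest 3D connected component, hole-filled, and its unweighted
voxel-centroid *N* taken as the nuclear centre. Each territory paint
channel is thresholded, clipped to the nucleus mask, and its connected
components above a volume floor give territory objects with centroids
*C*. The ray from *N* through *C* is marched in physical-space steps of
half the smallest voxel dimension until it leaves the mask; the midpoint
of the last-inside and first-outside samples is the boundary point *B*.
With *R* = |NC| and *Y* = |NB|,

$$\%RD = 100 \cdot \frac{R}{Y},$$

so 0% means the territory centre coincides with the nuclear centre and
100% means it lies on the periphery along its own ray. All coordinates
are physical micrometres — voxel `(i, j, k)` has its centre at
`(i - 0.5, j - 0.5, k - 0.5) * voxelSize` — so the anisotropic z
spacing of confocal stacks (0.105 × 0.105 × 0.34 µm by default) never
biases a distance.

Downstream, pooled %RD values per condition × chromosome are reduced to
the sample median (mean of the middle pair for even n), a five-bin
frequency distribution on 20-point bins (left-closed, final bin closed
at 100, a value of exactly 20 counting toward [20,40)), a two-sided
Mann–Whitney comparison between conditions, and a shift table
Δ = median(condition) − median(reference) in percentage points, with
`+` meaning movement toward the periphery, plus the within-condition
between-chromosome shift Δ(CT~a~ − CT~b~).

### Assumptions

* One nucleus per stack (fields are cropped per nucleus upstream).
* The nucleus mask is star-shaped enough around *N* that the first mask
  exit along a ray is the relevant boundary; for convex-ish interphase
  nuclei this holds.
* Each territory object is one homolog; the two largest objects per
  paint channel are kept by default (diploid), and each homolog counts
  as one independent observation in tests — sample sizes count
  territories, not nuclei.

## Tunable parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `voxelSize` | 0.105, 0.105, 0.34 | µm | physical scaling of all distances |
| nucleus threshold | Otsu | DN | counterstain is bimodal; Otsu is stable |
| territory threshold | half-maximum | fraction | see below |
| `minVolume` | 0.5 | µm³ | speckle rejection floor |
| `maxObjects` | 2 | — | homologs per paint channel |
| `minContrast` | 2 | ratio | object mean vs channel median; rejects background artefacts |
| march `step` | min(voxelSize)/2 | µm | sub-voxel boundary localization |
| `log2fcMin` | 2 | log₂ | deregulation call threshold (\|log₂FC\| ≥ 2) |
| `fpkmMin` | 1.0 | FPKM | transcribing filter, strict inequality |
| `rimFraction` | 0.1 | — | profile band counted as periphery |

Two defaults deserve their rationale:

**Territory thresholding is half-maximum, not Otsu.** Otsu maximizes
between-class variance over the intensity histogram, which works for the
counterstain (the nucleus occupies a large voxel fraction, the histogram
is genuinely bimodal). A painted territory occupies well under 1% of the
frame; its contribution to the histogram is negligible and Otsu
degenerates to splitting the background noise in two, flooding the
channel with a percolating noise mask. Thresholding at half the channel
maximum (the full-width-half-maximum convention used for compact bright
signals) is insensitive to the background mode and recovers the blob
boundary symmetrically under symmetric blur. Otsu, fixed and
fraction-of-max remain selectable per call for reproducibility studies.

**Deregulation thresholds.** The transcribing filter is FPKM strictly
greater than 1.0, evaluated in the reference condition by default (an
`anyCondition` switch widens it); the call threshold is \|log₂FC\| ≥ 2
inclusive at the boundary. Deregulated genes are not required to pass
the transcribing filter — the two counts are computed independently and
one normalized by the other — with a `strict` mode that intersects them.
When several conditions are pooled, the deregulated set is the union of
the per-condition sets, so a gene deregulated on both counts once.

## The simulator: what it emulates, what it does not

`renderScene()` builds an axis-aligned ellipsoidal nucleus (optional z
rotation), default semiaxes 6 × 4.5 × 2.8 µm — a DLD-1-like ~12 µm
nucleus — filled at 70% of an 8-bit dynamic range, with ellipsoidal
territory blobs (default semiaxes 1.2 × 1.2 × 1.0 µm at 80% intensity).
Ground truth for a blob's position is defined through the same ray
construction the measurement uses: the centre is placed so that
|NC| / |NB| equals the requested fraction along a chosen direction,
which closes the loop between the generator and the estimator — the
requested value is exactly what a perfect measurement should recover.
Rendering then applies a separable Gaussian PSF (σ = 0.2, 0.2, 0.4 µm,
specified in micrometres and converted to per-axis voxel sigmas), adds
a background pedestal (5% of dynamic range), Gaussian read noise
(σ = 2% of dynamic range; Poisson shot noise available), and quantizes
with clipping to the bit depth. Blobs that would cross the nuclear
boundary at high fractional positions are shrunk to fit (recorded in
the truth) unless strict placement is requested, in which case
placement errors are raised.

The noise and intensity levels are chosen for plausibility and
testability: published acquisitions come with no intensity statistics,
so these values are a design choice, fixed once, not fitted. Likewise
the simulator deliberately omits optics-accurate PSFs, spectral
bleed-through, chromatin texture inside the nucleus, irregular nuclear
shapes and touching nuclei. Passing recovery tests therefore
demonstrates that the geometry and segmentation chain is unbiased and
accurate on well-formed single nuclei — not that segmentation would be
robust on crowded or dim real fields.

The expression simulator plants per-chromosome up/down fractions as
independent Bernoulli draws over transcribing genes, gives planted genes
a |log₂FC| of the call threshold plus an exponential excess (they always
clear the call), and unplanted genes Gaussian log-fold noise (σ = 0.2,
which cannot reach the threshold at realistic gene counts); silent genes
get FPKM ≤ 1 everywhere. The envelope-section simulator draws disks with
a rim annulus at a controlled rim-to-interior intensity ratio.

## Numerical choices and degenerate inputs

* **Boundary interpolation.** The midpoint of the straddling ray
  samples gives B with error bounded by half a step; a finer step
  trades time for accuracy linearly.
* **Clamping.** Blur can push a centroid marginally past the
  interpolated boundary; %RD is clamped at 100 and the event logged as
  a warning, never silently.
* **Ties in the rank-sum test.** Midranks with the tie-corrected
  normal approximation; exact enumeration is used automatically for
  untied samples up to n₁ + n₂ = 50. The U convention counts pairs
  with a > b, so `a = 1,2,3` vs `b = 4,5,6` gives U = 0.
* **Degenerate channels.** An all-zero or constant channel is an error
  for direct thresholding; territory extraction returns an empty table
  for an all-zero channel (a nucleus with no paint signal is data, not
  a crash).
* **C = N.** A territory centroid exactly at the nucleus centre has
  %RD 0 by definition; the ray direction is undefined, so no boundary
  point is reported for that row.
* **Line profiles.** Sampling endpoints are inset 1.5 px (at most a
  quarter of the chord) inside the interpolated mask crossings so that
  endpoint intensities are supported entirely by nuclear pixels; the
  profile then reports the peripheral signal itself rather than the
  edge falloff. The reference periphery (mean of the reference mean
  profile's two endpoints) maps to exactly 1.0 after normalization.
* **Determinism.** Every generator is a pure function of its
  parameters including the seed (the caller's RNG stream is untouched);
  the pipeline expands one global seed into per-scene seeds by a fixed
  affine-modular rule, so serial and restarted runs agree bit-for-bit.

## Problem sizes used in the tests

Unit tests run on compact scenes (nucleus 3 × 2.4 × 1.8 µm at
0.15/0.3 µm voxels) so the suite stays fast; the recovery study in the
acceptance tests uses the full acquisition geometry (0.105 × 0.105 ×
0.34 µm voxels, default nucleus) over fractional positions
{0.2, 0.4, 0.6, 0.8} × 20 seeds, asserting mean absolute recovery error
under 3 percentage points with mean signed bias under 1 point. The
expression recovery test plants a chr1-like 16% deregulation against a
9% background at 500 genes per chromosome and requires agreement within
twice the binomial standard error.

## Known limitations

* Ray-based %RD assumes the segmented boundary is meaningful along the
  specific ray; deep invaginations or mask noise on the boundary inject
  error that the erosion-shell family of radial statistics would
  average away (that alternative is out of scope here).
* Territory centroids ignore intensity weighting by default
  ("geometric centre"); an intensity-weighted option exists at the
  segmentation layer but is not the reported statistic.
* The Mann–Whitney treatment regards homologs as independent
  observations; if homolog positions are correlated within a nucleus,
  effective sample sizes are smaller than the reported n.
* The pipeline measures one nucleus per stack and does not correct
  chromatic shift between channels.
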