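---
title: "Measuring interobserver agreement in organ-at-risk delineation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring interobserver agreement in organ-at-risk delineation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(oarconcord)
```

## The problem

Radiotherapy treatment planning requires every organ at risk (OAR) near the
target to be outlined on the planning CT. Different clinicians outline the
same organ differently — interobserver variability (IOV) — which changes
dose-volume statistics, complicates toxicity modelling, and can bias
multicentre trials. A standard way to audit IOV is to have many observers
contour the same cases, compare each contour against a guideline-conformant
reference, and ask (a) how well each organ is delineated, (b) how often it
is delineated at all, and (c) whether observers following consensus
guidelines agree better with the reference than those who do not.

`oarconcord` implements that audit pipeline and, because real contour sets
are rarely shareable, couples it to a synthetic cohort generator so the
whole analysis can be exercised and validated end-to-end.

## Data model

All masks of one patient live on one axis-aligned voxel grid
(`image_grid`): shape, anisotropic spacing in mm, world origin. The world
coordinate of 0-based voxel `(i, j, k)` is `origin + (i sx, j sy, k sz)`;
the third axis is the cranio-caudal (axial slice) axis. Masks are strictly
binary (`structure_mask`). Three states are distinguished and never
conflated: a present, nonempty contour; a contour that was drawn but is
empty (legal, scored `TEST_EMPTY`/`REF_EMPTY`); and an organ that was never
contoured (absent, scored `NOT_DELINEATED`). Cross-grid comparisons raise an
error (`assert_same_grid`) — nothing is ever resampled silently.

NIfTI-1 is the mask interchange format. On reading, geometry comes from the
coded qform/sform; the rotation part must be axis-aligned (identity up to
axis permutation and sign), and oblique volumes are rejected: the metrics
need consistent mm geometry, and guessing a resampling would silently change
them. Float volumes are binarized at > 0.5, which tolerates interpolated or
lossily stored files while staying deterministic.

## Agreement metrics

For a reference A and a test contour B on the same grid:

* **DSC** `= 2|A∩B| / (|A|+|B|)` on voxel counts.
* **Surface**: the centers of occupied voxels with at least one
  face-adjacent (6-connectivity) background or out-of-volume neighbour.
  Counting the volume edge as "outside" keeps the surface closed for
  structures cropped by the scan, such as a spinal cord reaching the most
  caudal slice.
* **MSD**: the mean of the pooled multiset {d(a, ∂B)} ∪ {d(b, ∂A)} of
  nearest-point Euclidean mm distances, both directions pooled. The
  symmetric pooled mean is the package's definition because a metric used
  for ranking observers should not depend on argument order; the two
  directed means remain available via `msd(a, b, directed = TRUE)` for
  sensitivity analysis, since some software reports the one-directional
  variant.
* **HD95**: the 95th percentile of the same pooled multiset, with linear
  interpolation between order statistics (R's `quantile` type 7). This is
  one of several percentile conventions in circulation; it is fixed and
  documented here so results are reproducible bit-for-bit. By construction
  HD95 never exceeds the exact maximum Hausdorff distance.

Correctness of the distance computation is *defined* by an O(n²)
brute-force nearest-point scan over the two surface point sets. The
production kernel is exactly that scan, compiled (with floating-point
contraction disabled so its arithmetic is bit-identical to the plain R
formulation used as the oracle in the test suite). No sub-voxel surface
model is used: the surface is a point set of voxel centers, which is
deterministic, convention-explicit, and cheap to verify.

Degenerate pairs are mapped to explicit statuses rather than imputed
"penalty" distances: an audit should count missing delineations, not fold
them into distance statistics with an arbitrary constant.

DSC's volume bias — at equal absolute boundary error, bigger structures
score higher — is treated as a property to demonstrate, not a nuisance to
correct: the test suite checks that digitized spheres of radius 5, 10 and
20 voxels against their one-voxel dilation give strictly increasing DSC
while MSD stays near 1 voxel throughout.

## The synthetic cohort

### Phantoms

Ten parametric solids stand in for head-and-neck OARs: ellipsoids (parotid,
submandibular gland, cochlea), a tapered cylinder (brainstem), a thin
cylinder deliberately cropped at the caudal grid edge (spinal cord), a
horseshoe arch (mandible), elliptical slab stacks with a lumen carve-out
(oral cavity, glottic area, supraglottic larynx), and a thin curved shell
(pharyngeal constrictors). Sizes put the digitized volumes on the right
order of magnitude (cochlea ≈ 0.1 cc, parotid ≈ 23 cc, oral cavity
≈ 70 cc). The default grid is 64 × 64 × 48 voxels at (2, 2, 3) mm — CT-like
axial anisotropy at a resolution where a full default cohort simulates and
scores in well under a minute per seed. Per patient, every size parameter
is scaled by a seeded uniform ±15% factor so the statistics are not
artifacts of one fixed shape.

### Observer errors

Each observer is an `observer_profile`: group (`ICG` = follows the
consensus guidelines, `OTHER`), per-organ delineation probability, a
per-organ catalogue of gross `error_mode`s, and a boundary-jitter scale and
correlation length. `perturb()` applies modes in a fixed order (omission,
wrong location, surrogate structure, systematic shift, extent errors,
substructure inclusion, boundary jitter), each firing independently with
its configured probability:

* **Boundary jitter** is the everyday disagreement channel: the mask's
  signed distance field is perturbed by a smooth zero-mean Gaussian random
  field and re-thresholded at zero. The field is synthesized spectrally
  (white noise, FFT, Gaussian low-pass with the stated correlation length,
  inverse FFT, normalized to unit sd and scaled to the jitter scale in mm).
  An SDF perturbation guarantees closed, voxel-consistent outputs with a
  single magnitude knob; the SDF itself comes from an exact anisotropic
  Euclidean distance transform, with half the smallest voxel size
  subtracted from both sides because center-to-center distances overshoot
  the face-located surface by half a voxel — without that correction,
  sub-voxel jitter scales could never flip a voxel on a coarse grid.
  Measured MSD tracks the jitter scale closely (≈ σ for σ in 0.5–2.5 mm).
* **Extent errors** add or remove whole axial slices at the cranial or
  caudal end (added slices replicate the current end slice), leaving
  mid-structure slices untouched — the signature of a cranio-caudal border
  disagreement.
* **Systematic shift** translates by a rounded integer-voxel offset along a
  random direction of the configured mm length.
* **Substructure inclusion** unions an adjacent spherical blob just outside
  the structure along a random direction (teeth in a mandible, petrous bone
  around a cochlea).
* **Wrong location** translates the whole structure by a large displacement
  (a contour that does not contain the organ); **surrogate structure** is a
  uniform mm dilation (spinal canal contoured instead of the cord);
  **omission** yields an absent contour.

All randomness derives from one integer seed through per-(patient,
observer, organ) hashed substreams, so a cohort is a pure function of
(specs, profiles, seed) and adding an observer never changes another
observer's draws.

### Default calibration

The default roster is 7 ICG + 7 OTHER observers over 5 patients and six
organs (brainstem, cochlea, mandible, parotid, submandibular gland, spinal
cord). The groups differ in jitter — 1.0 mm (ICG) vs 2.5 mm (OTHER), both
with 10 mm correlation — and in per-organ delineation probabilities set to
per-group percentages reported in multi-centre head-and-neck audits
(e.g. cochlea 59% vs 26%, spinal cord 63% vs 97%, parotid 100% both).
Gross-error probabilities are set an order of magnitude rarer than jitter
(0.03–0.10 per contour), extrapolating small published error counts
("2 observers did X") to per-contour rates. These defaults are
configuration chosen to reproduce the *qualitative* pattern — the
guideline group agrees better with the reference, strongly significant
under a pooled Welch test — not fitted estimates of any study's effect
sizes.

## Cohort statistics

`build_table()` scores every (patient, observer, organ) slot into a
long-format table with explicit statuses. `summarize_per_organ()` gives
per-organ medians and (min, max) ranges over status-OK rows only, with
delineation counts per group reported alongside — missing contours are
counted, never imputed. `delineation_rate()` counts empty-but-drawn
contours as delineated. `group_ttest()` compares ICG vs OTHER with an
independent two-sided t-test; Welch's unequal-variance form is the default
(robust when group variances differ, as they do by construction here), a
pooled Student option is exposed for sensitivity. Two units of analysis are
reported because neither is innocent: `PER_DELINEATION` pools all OK rows
(pseudo-replicated — one observer contributes many rows), `PER_OBSERVER`
first averages each observer's rows. The package reports both and treats
neither as the canonical reading.

## Numerical choices and edge cases

* Median of an even-sized sample: midpoint of the two central order
  statistics (`stats::median`).
* Grid-equality tolerance: 1e-6 mm on spacing; NIfTI stores geometry in
  float32, so round-tripped spacings agree to ~1e-7 relative.
* Empty masks: legal everywhere; any distance metric on an empty surface is
  an error at the metric layer and an explicit status at the cohort layer.
* Surfaces cropped by the volume edge are closed (edge voxels are
  boundary).
* Translation by integer voxels leaves all metrics exactly invariant;
  scaling the spacing by c scales MSD/HD95 by exactly c and leaves DSC
  unchanged — both are enforced as tests.
* The jitter field is synthesized on a padded bounding-box crop of the
  structure (pad = 4 jitter scales), so perturbation cost scales with
  structure size, not grid size; the spectral field wraps periodically at
  the crop border, which is harmless because the field there cannot exceed
  the pad threshold.

## What the synthetic validation does and does not show

Passing cohorts demonstrate that the metric engine is exact (oracle-equal),
that the statistics recover configured generative parameters (delineation
probabilities within binomial confidence bounds, MSD monotone in jitter
scale), and that the two-group analysis detects a built-in group difference
with the expected direction in every seed. The phantoms, however, are
geometric stand-ins: they have no CT contrast, no truly ambiguous borders,
and error modes are independent across organs and observers. Agreement
numbers from real contour cohorts depend on anatomy and image quality in
ways no phantom captures, so the synthetic cohort validates the *pipeline*,
not any claim about clinical effect sizes.

## Problem sizes

The shipped tests and the acceptance script use: oracle comparisons on
random blob masks up to 20³ voxels (200 pairs); spheres up to radius 20
voxels on 48³ grids; default cohorts of 5 × 14 × 6 slots on the
64 × 64 × 48 grid, 20 seeds for the group-direction check and 5 seeds in
the acceptance script; and 500-draw rate-recovery runs. These sizes were
chosen so each property is measured with comfortable statistical margin
while a full run stays in the minutes range on a single CPU.
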