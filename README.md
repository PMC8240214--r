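# oarconcord

Interobserver agreement analysis for 3D organ-at-risk (OAR) delineations in
radiotherapy quality assurance.

When several radiation oncologists contour the same organs on the same
planning CT, their contours disagree — in everyday boundary placement, in
the cranio-caudal extent of the structure, and occasionally grossly (a
spinal canal contoured instead of the cord, a region that does not contain
the cochlea at all, or the organ simply not contoured). `oarconcord`
quantifies this interobserver variability (IOV) and tests whether observers
following a common set of delineation guidelines agree better with a
reference contour than observers who do not.

## What it computes

For each (reference, test) pair of binary masks A and B on a shared voxel
grid:

- **DSC** (Dice similarity coefficient): `2|A ∩ B| / (|A| + |B|)`;
  1 = perfect overlap, 0 = disjoint. DSC is biased with respect to volume —
  large structures score higher at the same absolute boundary error — so
  two distance metrics are reported alongside.
- **MSD** (mean surface distance, mm): the mean of all nearest-point
  distances between the two boundary surfaces, pooled symmetrically over
  both directions.
- **HD95** (95th-percentile Hausdorff distance, mm): the 95th percentile
  (linear interpolation) of the same pooled distance multiset — a robust
  variant of the maximum Hausdorff distance.

Surfaces are the world-mm centers of 6-connectivity boundary voxels;
distances respect anisotropic voxel spacing. Missing or empty contours get
an explicit status (`NOT_DELINEATED`, `TEST_EMPTY`, ...) instead of imputed
penalty values.

On top of the pairwise metrics the package provides per-organ cohort
summaries (median and range per metric, delineation counts per guideline
group), per-organ delineation rates, and an independent two-sided t-test
(Welch by default) comparing the two observer groups, either pooling all
delineations or testing per-observer means.

Because real multi-observer contour sets are rarely shareable, the package
includes a synthetic cohort generator: parametric organ phantoms (ten
head-and-neck OAR stand-ins) plus an observer-error simulator with the
error modes seen in delineation audits — smooth boundary jitter realized as
a signed-distance-field perturbation, whole-slice cranio-caudal extent
errors, systematic shifts, substructure inclusion, wrong-location and
surrogate-structure gross errors, and omission — with two observer groups
of configurable error magnitude and per-organ delineation probability.

## Worked example

```r
library(oarconcord)

res <- run_demo(out_dir = "demo_run", seed = 7, quiet = TRUE)
res$comparisons$msd_per_delineation
#> <MSD PER_DELINEATION comparison (welch): ICG mean 0.643 (n=12) vs
#>  OTHER 1.867 (n=10), t=-7.967, df=18.8, p=1.953e-07>
res$summary[, c("organ", "n_ok", "dsc_median", "msd_median", "hd95_median")]
#>       organ n_ok dsc_median msd_median hd95_median
#> 1 brainstem    7  0.8861124  0.9447082    3.000000
#> 2   parotid    8  0.8671309  1.4480042    3.802776
#> 3       smg    7  0.9125413  0.6591588    2.000000
```

The demo simulates 2 patients × 4 observers (2 per group) × 3 organs,
scores every delineation against its reference, and writes `scored.csv`,
`summary.csv`, `group_comparison.json` and `provenance.json` into
`demo_run/`. The comparison above says: observers simulated with the
smaller guideline-group jitter (1.0 mm) sit ~1.2 mm closer to the reference
surface on average than the other group (2.5 mm jitter), and the pooled
Welch test flags the difference (p < 0.05) even at this toy size. The
summary medians are the per-organ cohort statistics: e.g. the brainstem's
median DSC of 0.89 and median MSD of 0.94 mm over its 7 delineated
contours.

A full-size cohort (5 patients, 7 + 7 observers, 6 organs) is one call:

```r
ds  <- simulate_cohort(5, default_profiles(7, 7), seed = 1)
tab <- build_table(ds)
summarize_per_organ(tab)
group_ttest(tab, metric = "MSD", unit = "PER_DELINEATION")
```

Real data enter through NIfTI masks plus a JSON/CSV manifest
(`read_mask()`, `load_cohort()`, `score_manifest()`); a thin CLI wrapping
the same functions is installed at `exec/oarconcord`
(`simulate | score | summarize | compare-groups | demo`).

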