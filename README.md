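# amyquant

Quantification of amyloid-beta plaque pathology and plaque-associated
microglia in multichannel fluorescence sections of mouse brain, for
histopathology groups who need the whole chain — segmentation, per-cell
measurement, image QC, stereology, hierarchical pooling and group
statistics — as reproducible, tested code rather than a pile of one-off
macros.

## What it computes

* **Segmentation.** Nuclei: Gaussian blur of the DAPI channel (sigma
  0.72 µm) → Otsu threshold → watershed on the Euclidean distance map.
  Plaques: blur of the 4G8 channel (sigma 7.2 µm) → Otsu → 8-connected
  components, keeping only objects with area > 720 µm². The Otsu threshold
  is the exact between-class-variance maximiser over all distinct values:
  for intensities with class split {x ≤ t} vs {x > t},
  t\* = argmax w₁(t)·w₂(t)·(μ₁(t) − μ₂(t))².
* **Per-cell metrics.** Mean Iba1/Clec7a intensity over each nuclear
  region; per-image Iba1⁺ calls by Otsu on the cell means; Euclidean
  distance from nucleus centre of mass to the nearest plaque border;
  plaque association within 30 µm (inclusive); associated-cell counts
  normalised per cell by nearest-plaque area; radial intensity profiles in
  annular bins around the nucleus centre, integral-normalised for pooling;
  image-wise Clec7a histograms.
* **Area-ratio workflow.** One fixed threshold per channel for the whole
  run (pooled mean + k·SD, k = 2), stained-pixel fractions, per-image
  BACE1/4G8 ratio, leave-one-out 2·SD image QC against same-animal and
  same-group comparison sets, per-animal medians.
* **Stereology.** Cavalieri point counting of percent area covered
  (90 × 90 µm frames on a 450 × 450 µm grid, 10 µm point lattice, SURS
  offsets) and an optical-fractionator-style density estimator
  (75 × 75 µm frames, 500 × 500 µm grid, half-open counting-frame rule,
  population / (ROI area × thickness)).
* **Pooling and statistics.** Animal value = median over that animal's
  images (element-wise for curves); group value = mean ± SEM over animals.
  Two-tailed unpaired Student t-test, per-bin Bonferroni, Pearson
  correlation, one-way ANOVA + Tukey HSD, iterative Grubbs outlier
  removal; stars at p ≤ 0.05 / 0.01 / 0.001.
* **Synthetic cohorts.** A seeded generator renders ground-truthed
  DAPI/4G8/Iba1/Clec7a/BACE1 sections (Poisson-placed log-normal plaques,
  a quarter with compact cores; microglia clustered within 30 µm of
  borders; 6 µm Iba1 halos; intracellular 4G8 blobs peaking ~4 µm from the
  nucleus centre; bimodal Clec7a; Poisson + Gaussian camera noise) and
  full cohorts with group multipliers (female 2×; an IL12p40-KO arm at
  0.42×).

## Worked example

```r
library(amyquant)

scene  <- scene_params(image_px = 128, pixel_size_um = 2.88)
cohort <- cohort_params(groups = c(female = 2, male = 1),
                        animals_per_group = 3, images_per_animal = 4)
res <- run_pipeline(run_config(cohort = cohort, scene = scene, seed = 42,
                               stages = c("cells", "stats")))
subset(res$groups, metric %in% c("g8_stained_fraction_pct", "n_associated"))
```

```
   group                  metric  mean   sem n_animals
1 female g8_stained_fraction_pct  9.65 0.847         3
2   male g8_stained_fraction_pct  3.81 0.382         3
3 female            n_associated 44.17 0.928         3
4   male            n_associated 19.83 2.682         3
```

The simulated female arm carries twice the male plaque burden; the
shared-threshold 4G8 stained fraction (percent of image area, pooled by
per-animal medians) recovers roughly that factor, and plaque-associated
Iba1⁺ microglia scale with it. The pairwise statistics table reports the
corresponding test:

```r
subset(res$stats, metric == "g8_stained_fraction_pct")
```

```
                   metric group_a group_b n_a n_b mean_a mean_b sem_a sem_b
3 g8_stained_fraction_pct  female    male   3   3   9.65   3.81 0.847 0.382
  statistic df       p stars
3      6.28  4 0.00328    **
```

i.e. a two-tailed unpaired t-test on 3 animals per group, t = 6.28,
df = 4, p = 0.0033 (\*\*). A full run additionally writes `cells.csv`,
`images.csv`, `animals.csv`, `groups.csv`, `qc.csv`, `profiles.csv`,
`histograms.csv`, `stereology.csv`, `stats.csv`, a JSON run summary and a
log of every exclusion to `outdir`.

A thin command-line front-end is installed with the package
(`inst/cli/amyquant`) with `simulate` and `all` subcommands.

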