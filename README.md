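# vesselphen

Tumor-vessel phenotyping for multiplexed immunofluorescence tissue
microarrays, with a ground-truthed synthetic-data backbone.

## What problem this solves, and for whom

Quantitative pathology groups profile tumor vasculature by staining
tissue-microarray (TMA) cores with an endothelial marker panel — DAPI,
ACKR1 (DARC), CD34, CD36, KDR (VEGFR2), LAMB1 (laminin β1), MADCAM1, and
KRT — and asking how vessel phenotypes vary with clinical variables such as
age at colorectal-cancer diagnosis. `vesselphen` implements that entire
analysis as a reusable, tested R pipeline:

* **Image preprocessing** — per channel: 9×9 averaging filter → Otsu
  binarization (mask strictly above threshold) → morphological closing then
  opening with a Euclidean-disk structuring element (radius 2 px = 1 µm by
  default).
* **Vessel phenotyping** — CD34⁺ connected components (8-connectivity,
  ≥12 px) are vessel objects; a vessel is *positive* for an auxiliary
  marker when the marker mask covers **strictly more than 5%** of the
  vessel area; core/epithelial(KRT)/stromal areas yield nine density
  variables in vessels/mm².
* **Morphometry** — ten regionprops-style features (Area, Perimeter,
  Circularity = 4πA/P², ConvexArea, Eccentricity, EquivDiameter, Extent,
  Major/MinorAxisLength, Solidity), with the perimeter and hull dialects
  fixed and tested against geometry.
* **Morphology classification** — a 1000-tree random forest (4 candidate
  features per split; 100 vessels per class for training and validation)
  sorts vessels into *micro*, *collapsed*, *patent*, *irregular*; Cohen's κ
  quantifies interobserver agreement.
* **Cohort statistics** — per-case pooled densities, median-based
  dichotomization (LAMB1: high = above the median of non-zero values,
  zeros negative), Spearman age trends, and inverse-probability-weighted
  (IPW) multivariable logistic regression with backward elimination
  (threshold p = 0.1, age forced in), sandwich variances, and a
  multiplicity-adjusted α = 0.005 (≈ 0.05/9).

Because the motivating study's data are not public, a first-class simulator
generates 8-channel core images with planted vessel classes, marker rates
(ACKR1 4.2%, CD36 6.7%, KDR 14%, LAMB1 6.8%, MADCAM1 1.4%), density
197/mm², and a 4476-case cohort (~843 with tissue) with planted age–density
odds ratios (e.g. overall-density OR 0.63 and LAMB1 OR 0.28 for age <55 vs
≥70). Every stage is validated by recovering what was planted.

## Worked example

Simulate a core, run the pipeline, and compare against ground truth:

```r
library(vesselphen)
cores <- simulate_cores(2, image_sim_config(image_size = 800), seed = 9)
ph <- phenotype_core(cores[[1]]$stack)
ph$areas
#>   core_mm2 epithelial_mm2 stromal_mm2 flagged
#> 1     0.16         0.0658      0.0942 FALSE

v <- match_ground_truth(ph$vessels, cores[[1]]$truth)
dplyr::select(v, vessel_id, area_px, Eccentricity, Solidity,
              KDR_pos, LAMB1_pos, true_class)
#>   vessel_id area_px Eccentricity Solidity KDR_pos LAMB1_pos true_class
#> 1         1    1431        0.863    0.754 FALSE   FALSE     irregular
#> 2         2     311        0.433    1     FALSE   FALSE     micro
#> 3         3     127        0.245    1     FALSE   FALSE     micro
#> 4         4    1391        0.887    0.766 TRUE    FALSE     irregular
#> 5         5     223        0.190    1     FALSE   FALSE     micro
#> # 24 more rows
```

The 0.16 mm² core carries 29 recovered vessels — exactly the planted count —
with marker flags matching the planted flags vessel for vessel. Densities
follow as counts over core area (here 181 vessels/mm² overall against the
planted rate of 197/mm², within Poisson noise for one small core).

Cohort analysis on the simulated full cohort, with IPW weights estimated
from all 4476 cases:

```r
coh <- generate_cohort(cohort_sim_config(seed = 7))
res <- run_full_analysis(coh)
dplyr::filter(tidy(res), stratum == "all", outcome == "high_lamb1",
              model == "multivariable")
#>   stratum outcome    model         term        or conf.low conf.high p.value p.trend
#> 1 all     high_lamb1 multivariable age 55-69 0.691    0.513     0.931 1.50e-2 1.32e-4
#> 2 all     high_lamb1 multivariable age <55   0.237    0.104     0.540 6.09e-4 1.32e-4
```

One replicate recovers the planted LAMB1 odds ratios (0.56 for 55–69, 0.28
for <55 vs ≥70) within its confidence intervals; averaging over replicates
(see below) recovers them to two decimals. `autoplot()`, `plot_importance()`,
`plot_density_by_age()` and `plot_age_or()` give the standard figures;
`tidy()`/`glance()` methods return tibbles for every fitted object.

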