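# slicequant

Quantification pipeline for irradiated tissue slice cultures.

Thin-cut tumor slice cultures (TSC) and organotypic brain slice cultures
(OBSC) are 300–500 µm vibratome sections kept on membrane inserts; they
preserve the original 3-D tissue architecture and are used to test radiation
(including proton-beam) and drug response ex vivo. Evaluating such
experiments needs a chain of image and plate quantifications, and
`slicequant` implements that chain end to end for researchers running slice
irradiation experiments:

- **γH2AX focus assay** — nuclei segmented from the DAPI channel (Otsu +
  distance-transform watershed), strict area filter (> 65 µm²),
  exclusion-list handling of mitotic/apoptotic cells, and focus counting as
  local intensity maxima of the Gaussian-blurred γH2AX channel with a
  prominence criterion. Counts are area-corrected:
  `cfoci_i = foci_i × (group mean nucleus area / area_i)`, removing the
  sampling bias of enlarged nuclei; a binary positive/negative score covers
  tissue where distinct foci are unresolvable.
- **Histomorphology** — Beer–Lambert color deconvolution in OD space,
  necrotic fraction from H&E, DAB/CD44 and DAPI positive-area fractions, and
  depth profiles (depth = slice rank × 500 µm).
- **Plate assays** — LDH cytotoxicity: `total = lysis + Σ daily`,
  `death_i = daily_i / total`, `surviving_i = 1 − Σ_{j≤i} death_j`;
  resazurin (PrestoBlue) correction
  `A_corr = A_s(571) − A_s(601) − (A_m(571) − A_m(601))`; day-1
  normalization.
- **Statistics** — Bland–Altman agreement (bias, SD of differences, 95%
  limits), Pearson correlation matrices with t-distribution p-values, and a
  slice-clustered permutation test for treatment effects on nested
  per-nucleus data.
- **Film dose QA** — net optical density → dose via a monotone calibration
  curve; lateral homogeneity `H = 100 × D2 / D98` within an ROI.
- **Synthetic data** — seeded generators for every input (fluorescence
  scenes, stained sections, assay plates, paired counts, depth profiles with
  a correlation-calibrated Gaussian copula) with exact ground truth, so the
  whole pipeline is testable without specimens.

## Worked example

```r
library(slicequant)

# a synthetic two-channel scene: 12 nuclei, ~8 foci each, 15% apoptotic
sc <- generate_foci_scene(12, width = 384, foci_mean = 8, seed = 101,
                          class_probs = c(normal = 0.85, apoptotic = 0.15,
                                          mitotic = 0))
res <- foci_pipeline(sc$dapi, sc$gamma,
                     params = foci_params(pixel_size = 0.25),
                     exclusion_list =
                       sc$truth$nuclei$label[sc$truth$nuclei$class != "normal"])
head(res$records[, c("label", "area_um2", "included", "exclusion_reason",
                     "foci_count", "cfoci")])
#>   label area_um2 included exclusion_reason foci_count cfoci
#> 1     1      144     TRUE             none          5  4.27
#> 2     2      149    FALSE  listed_excluded          0  0.00
#> 3     3      135     TRUE             none         10  9.05
#> ...
res$summary
#>   group n_included mean_area mean_foci mean_cfoci
#> 1   all         11     122.5     10.45      10.51
```

Nucleus 2 was on the exclusion list (a pan-bright apoptotic cell), so it is
not evaluated; each included nucleus reports its raw count and its
area-corrected `cfoci` (nucleus 1 is larger than the group mean, so its 5
foci correct down to 4.27).

```r
# counter agreement: two observers with 3-count error each
pc <- generate_paired_counts(rpois(300, 12), sd_a = 3, sd_b = 3, seed = 2)
bland_altman(pc$a, pc$b)
#> Bland-Altman agreement (n = 300)
#>   bias        -0.260
#>   sd(diff)     4.503
#>   95% limits of agreement [-9.087, 8.567]

# LDH arithmetic, closed form
survival_series(c(25, 25), 50)
#>   day cell_death surviving surviving_clipped
#> 1   1       0.25      0.75              0.75
#> 2   2       0.25      0.50              0.50

# film QA: a 5% lateral dose ramp
homogeneity(matrix(rep(seq(9.5, 10, length.out = 200), each = 50), 50, 200))
#> Dose homogeneity: 95.2% (D_low 9.510 Gy / D_high 9.990 Gy, 10000 px)
```

The bias near zero with a difference SD of ~4.5 counts is the expected
agreement for two counters with 3-count error each; the survival table shows
the exact death/survival fractions for 25 + 25 AU daily release against a
50 AU lysis pool; and the ramp map sits at the 95% homogeneity acceptance
threshold used for slice irradiation plates.

See the vignette (`vignettes/slice-culture-quantification.Rmd`) for the full
description of the models, parameters and design choices.

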