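---
title: "Quantifying irradiated tissue slice cultures: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying irradiated tissue slice cultures: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(slicequant)
```

# Scope

`slicequant` implements the quantification chain used to evaluate thin-cut
tumor slice cultures (TSC) and organotypic brain slice cultures (OBSC) after
irradiation: segmentation of cell nuclei from the DAPI channel and counting
of gamma-H2AX DNA damage foci; area-corrected foci (cfoci) and binary
positivity scoring; histomorphology fractions (necrosis from H&E, CD44/DAB
and DAPI positive area) assembled into depth profiles; LDH cytotoxicity and
resazurin (PrestoBlue) plate arithmetic; agreement and group statistics; and
radiochromic-film dose-map homogeneity QA. Because no real specimen images
ship with the package, a synthetic-data module generates every input with
exact ground truth; all quantitative claims made by the test suite are
claims about recovery of that truth.

# The gamma-H2AX focus assay

## Model

After irradiation, phosphorylated histone H2AX accumulates at DNA double
strand breaks as punctate nuclear foci; residual foci at 24 h mark
unrepaired damage and predict radiosensitivity. The assay counts foci per
nucleus:

1. **Segmentation.** The DAPI channel is Gaussian-blurred and thresholded
   (Otsu by default; the method is configurable because the original
   acquisition software is not specified by the underlying macro set), then
   connected components are labeled. With `split_touching = TRUE` a
   distance-transform watershed separates merged nuclei.
2. **Inclusion.** Only nuclei with area strictly above `area_min`
   (default 65 um^2) are evaluated; an area of exactly 65 um^2 is excluded
   ("above" read as a strict inequality). Mitotic and apoptotic cells —
   rendered pan-bright in the focus channel, with no resolvable spots —
   are excluded via an explicit exclusion-list file rather than an
   interactive review step, so analyses are reproducible and headless.
   Border-touching nuclei are dropped by default since their area estimate
   is incomplete.
3. **Counting.** The focus channel is blurred with `blur_sigma`
   (default 1.5 px at 40x sampling) and local intensity maxima are counted
   inside each included nucleus. A maximum is a pixel whose blurred value is
   greater than or equal to all of its 8 in-image neighbors; a connected
   plateau of equal-valued maximal pixels counts once (this follows from the
   maximum definition: adjacent maximal pixels are necessarily equal), and
   only when the whole plateau lies inside one nucleus.

## The prominence rule

Counting raw local maxima is ill-posed on noisy data, so a maximum counts as
a focus only when its height above the within-nucleus background (the
minimum blurred value inside the nucleus) exceeds
`maxima_prominence x (nucleus max - nucleus background)`, default 0.2. This
relative rule has one known blind spot: any nucleus with non-zero intensity
variation contains at least one passing maximum (its own global maximum), so
a spot-free but noisy nucleus reports one focus. For screening settings
where empty nuclei are common, `min_abs_prominence` adds an absolute
intensity floor; it defaults to 0 (off) so that the documented relative rule
is exactly what runs.

Under the default rendering conditions (spot amplitude 0.5, relative noise
SD 0.02, spot sigma 2 px) the margin between true spots and blurred noise
extrema is large (roughly five-fold), which is what the perfect-recovery
tests exercise; recovery degrades as spot separation approaches the blur
scale, and two spots closer than about 2 sigma merge into one maximum.

## cfoci

Irradiation enlarges nuclear cross-sections (cell cycle arrest), and larger
sections collect more foci in a 2-D sample of a 3-D nucleus. The
area-corrected count removes this sampling bias:

cfoci_i = foci_i x (mean area of the treatment group / area_i).

Two identities pin the definition down and are tested numerically: cfoci
equals the raw count when a nucleus has exactly the group mean area, and
`sum(cfoci_i x area_i / mean area) = sum(foci_i)` within a group.

## Binary positivity

In tissue where the spot-like appearance is lost (adult brain slices),
foci cannot be counted and nuclei are scored positive/negative instead: a
nucleus is positive when its mean (or a configurable upper-quantile) signal
exceeds a multiple of the slide background, the background being the median
signal outside all nuclei.

# Histomorphology

Brightfield stains are unmixed in optical-density space: for transmitted
intensity I against a white reference, OD = -log10(I / white) is linear in
stain concentration (Beer–Lambert), and per-pixel concentrations are the
least-squares solution onto unit stain vectors (standard
hematoxylin/eosin/DAB triplets by default, overridable for scanner
calibration). Negative concentrations are clipped at zero.

The necrotic fraction of an H&E section is the fraction of tissue pixels
(total OD above `tissue_od_min`) that are eosinophilic and nucleus-poor:
hematoxylin concentration below `hematoxylin_max` and eosin above
`eosin_min`, cleaned by a morphological opening/closing with a 2 px disc.
The same positive-area operator serves CD44/DAB concentration maps and DAPI
fluorescence. Per-slice fractions are assembled into a depth profile with
`depth = (slice rank - 1) x thickness` (500 um for tumor slices); the first,
skin-side slice sits at depth 0 — the cutting protocol defines the order but
no absolute origin, so the package anchors it at the first slice.

# Plate assays

For the LDH cytotoxicity assay, the blank-corrected signal is A490 - A680.
With daily supernatant signals and a terminal-lysis signal releasing the
residual intracellular pool:

- total = lysis + sum of daily signals,
- cell death on day i = daily_i / total,
- surviving fraction on day i = 1 - cumulative death.

These are exact ratios: `sum(cell_death) + final surviving = 1` to machine
precision, which the tests assert at 1e-12. Negative blank-corrected
readings (noise near blank) are retained with a warning rather than floored,
precisely so this identity survives; the `[0, 1]` clip is applied only to
the separately reported `surviving_clipped` column.

The resazurin (PrestoBlue) correction is
`corrected = sample(571) - sample(601) - (medium(571) - medium(601))`, and
because slice sizes vary, series are reported relative to day 1 in culture
(`normalize_to_day1()`).

# Statistics

**Bland–Altman agreement** summarizes paired counters by the mean difference
(bias), the n-1 sample SD of differences and the 95% limits of agreement
(bias -+ 1.96 SD). Automated-versus-manual focus counting is validated this
way; well-calibrated counters show bias near zero and a difference SD of a
few foci.

**Correlation matrices** use Pearson R with two-sided p-values from the
t-distribution on n-2 degrees of freedom and listwise deletion; zero
variance columns yield flagged `NA`s.

**Treatment comparison** uses a slice-clustered permutation test. Nuclei are
nested in slices and slices carry the treatment, so nuclei are not
exchangeable across groups while slices are. The statistic is the difference
of group means of slice means; slice labels are permuted respecting group
sizes, and the two-sided p-value is `(1 + #{|T*| >= |T|}) / (n_perm + 1)`
(the +1 correction avoids reporting zero). A mixed-effects model answers the
same question through explicit variance components; the permutation test
was chosen as a defined, assumption-light procedure whose calibration can be
verified by direct Monte-Carlo simulation (type-I error at nominal 0.05 is
checked to lie in [0.03, 0.07] over 1000 null data sets), and the tests also
cross-check it against a slice-level t-test on a clear effect.

# Film dose QA

Scanned-film net optical density converts to dose through a user-supplied
strictly monotone calibration table, interpolated piecewise-linearly
(default) or with a monotone Hyman spline; calibration nodes map exactly and
out-of-range densities are clamped with a warning. Lateral homogeneity over
a region of interest is scored as `H = 100 x D_low / D_high` with
`D_low`/`D_high` the 2nd/98th-percentile doses — percentile clipping makes
the index robust to dust and film-edge artifacts; the metric itself is this
package's definition, since the acceptance criterion (>= 95% across the
plate) is commonly stated without one. H is invariant under global dose
scaling and equals 100 for a flat field.

# The synthetic-data module

The generators define the study conditions for every test:

- **Fluorescence scenes**: elliptical nuclei (area law normal,
  120 +/- 25 um^2 truncated at 40, pixel size 0.25 um/px at 40x), edges
  softened by a 1 px blur; optional touching pairs placed closer than the
  radius sum to stress the watershed; foci as additive Gaussian spots
  (sigma 2 px, amplitude 0.5) with a minimum separation enforced by
  rejection sampling — an unsatisfiable separation is an explicit error,
  never silent crowding. Apoptotic/mitotic nuclei render pan-bright with no
  spots. Shot noise is approximated as Gaussian with intensity-proportional
  SD (default 2%), sufficient for testing thresholding and maxima logic
  without full Poisson rendering.
- **Stained scenes**: class layouts (halves, central disc, scattered blobs)
  mixed per Beer–Lambert with Gaussian noise in OD space (default SD 0.02).
  Truth fractions are exact pixel counts of the class mask.
- **Assay series**: daily lysed fractions plus a terminal lysis residual,
  scaled into absorbance with additive noise; paired counters with additive
  Gaussian error and rounding; depth profiles from a Gaussian copula.
- **Copula correction**: feeding target correlations directly to the latent
  normal would attenuate the post-transform Pearson correlation
  (r_u = (6/pi) asin(rho/2) for uniform marginals), so latent correlations
  are pre-adjusted by `rho_z = 2 sin(pi rho / 6)`; the depth variable is
  realized as the fixed slice grid by rank-ordering the latent depth
  coordinate. Empirical correlations then converge to the stated targets.
  The default target matrix encodes a necrotic core: necrosis falls with
  depth (rho = -0.88) while cell density (0.83) and CD44 (0.67) rise.

Every generator routes all randomness through its explicit `seed` argument
and restores the caller's RNG state, so identical calls are bit-identical
and nothing leaks into the global stream.

What the generators do *not* emulate — chromatic aberration, uneven
illumination, out-of-focus planes, true Poisson statistics at low photon
counts, nuclear texture, partial-volume staining — bounds what passing
tests show about real specimens: they validate the arithmetic and the
detection rules, not robustness to acquisition artifacts.

# Numerical and interface conventions

- Rasters are numeric matrices (row = y, column = x) with 1-based indices,
  the native R convention; areas are always converted to um^2 via
  `pixel_size^2` before any filtering.
- Exclusion reasons are reported with precedence
  listed_excluded > below_area > border when several rules apply.
- Problem sizes in the routine test suite (rasters of 96–512 px, 4–40
  nuclei per scene, 500-slice profiles, 300–1000 permutation/simulation
  replicates) were chosen so each statistical check has the power its
  tolerance requires while the whole suite stays interactive.
- Ties in the permutation statistic are compared with a 1e-12 slack so
  exact ties count as at least as extreme.

# Known limitations

- The relative prominence rule guarantees one focus in any non-flat nucleus
  (see above); use `min_abs_prominence` or the exclusion list when empty
  nuclei are expected.
- Watershed splitting uses the default distance-transform tolerance; deeply
  overlapping nuclei (centers closer than ~0.5 radius sums) may not split.
- Stain unmixing assumes at most three known stain vectors and no
  chromogen saturation.
- The homogeneity index summarizes only the dose range within the ROI; it
  does not localize cold or hot spots.
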