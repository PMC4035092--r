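---
title: "Quantifying white-matter myelin pathology with wmquant"
author: "wmquant authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying white-matter myelin pathology with wmquant}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(wmquant)
```

wmquant implements the quantitative image-analysis workflow of a preclinical
small-vessel-disease (CADASIL-model) white-matter study: counting
hyperintense myelin-debris foci on MBP-stained wide-field images, counting
Olig2-positive oligodendrocyte nuclei, measuring microglial stained-area
fractions, classifying axon presence inside damaged sheaths from two-channel
confocal line profiles, computing g-ratios, and reducing electron-microscopy
lesion annotations to census statistics. Because tissue micrographs of this
kind are not publicly deposited, every estimator is paired with a synthetic
generator that produces images or tables with *known* ground truth; all
claims the test suite makes are recovery claims against that realized truth.

## Conventions

Images are `ChannelImage` objects: a non-negative intensity matrix plus a
physical pixel size in micrometres. Coordinates are 1-based `(row, col)`
with the pixel-center convention, matching R matrix indexing; pixel `(i, j)`
is the unit square centred at `(i, j)`. A polygon ROI is rasterized by the
even-odd rule applied to pixel centers, so an axis-aligned square with
corners half a pixel outside a 10 x 10 block masks exactly 100 pixels, and
physical areas are `sum(mask) * pixel_size_um^2`. All stochastic steps are
driven by one global seed; per-stage streams are derived with
`stage_seed()` so a stage can be re-run in isolation.

## Debris focus detection by topographic prominence

Wide-field MBP images have a smooth but strongly non-uniform background, so
a global threshold cannot isolate the hyperintense debris foci. `detect_foci()`
instead finds all regional maxima (8-connected; plateau maxima collapse to
one detection at the plateau pixel nearest its centroid, preventing double
counts on saturated foci) and keeps those whose *topographic prominence*
exceeds a noise tolerance. Prominence is the height of a maximum above the
highest saddle that connects it to a higher maximum; maxima never dominated
are referenced to the ROI minimum. This is the quantitative reading of a
maximum "standing out from its surroundings": it is invariant to adding a
constant and insensitive to smooth background, which is exactly the failure
mode of plain thresholding. Ties between equal-height maxima are broken
deterministically by the smaller minimum linear index. The engine is a
single watershed-by-flooding pass with union-find over plateau regions
(C++); the test suite checks it exactly against an independent
flood-from-each-maximum enumeration on hundreds of small random images.

The noise tolerance is not hand-picked per image: `calibrate_tolerance()`
scans a grid on a batch of annotated fields and returns the value
maximizing mean F1 (detections matched one-to-one to true centers within
3 px, greedily by distance), with ties broken toward the *larger* tolerance
— the conservative end of a flat plateau. Densities are reported per mm^2
of the delineated region; nothing is excluded at ROI edges by default
(`exclude_border_px = 0`).

## Oligodendrocyte counting

`segment_nuclei()` binarizes the DAPI channel inside the ROI with the Otsu
threshold, fills holes, drops components below `min_nucleus_area_um2`
(default 10 um^2 — the original workflow leaves this unstated; the value
rejects staining specks while keeping any plausible nucleus), and splits
touching nuclei by a watershed on the distance transform. A nucleus is
Olig2-positive when its mean marker intensity is at least 1.1 times the
mean over the nucleus *enlarged* isotropically by `margin_px` (default
70 px, stored in pixels as the original protocol states, with a documented
physical-units override since a pixel margin is scale-dependent). The
enlarged region includes the nucleus pixels themselves — the verbatim
reading of "the nucleus ROI enlarged by N pixels"; an annulus-only mode is
provided (`surround_mode = "annulus"`) but is not the default. Ratios
exactly at the threshold count as positive ("at least 1.1 times"), and the
rule is scale-free by construction.

## Microglial area fractions

`otsu_threshold()` maximizes the between-class variance of the intensity
histogram computed over ROI pixels only (the region outside the delineated
area is excluded, matching the workflow's masking step; whether the original
macro used the ROI-restricted or whole-frame histogram is unstated, so the
choice is flagged here). When several cuts tie, the lowest is returned —
a deterministic rule the brute-force oracle shares. `area_fraction()`
reports the fraction of ROI pixels above the threshold, used identically
for Iba-1 (total) and CD68 (reactive) staining.

## Axon presence from perpendicular line profiles

For each debris focus selected on the red channel — and only the red
channel; the selection function never receives the green raster, so
blindness holds by construction — two perpendicular 1-px-wide lines are
sampled at unit steps with nearest-pixel lookup (a discrete 1-px line, not
an interpolated one). The phrase "a green peak within the red profile
curve" is operationalized as: the red support is the contiguous interval
around the profile center where the red profile stays at or above
background plus half the red peak prominence (background = mean of the
outer 10% of samples at each end); a qualifying green peak is a 1-D local
maximum with prominence at least `peak_prominence` whose index falls in
that interval. The call is axon-present if either line qualifies. This
formulation is offset-free and scale-robust, and it is monotone: raising
the green prominence threshold can only remove calls. Line orientations
default to 0 and 90 degrees and the default length is about four red-focus
diameters; both are configurable, and no claim is made that this exactly
reproduces the original interactive macro, which left these quantities
undefined.

## g-ratios

`compute_gratio()` is the axon diameter over the outer sheath diameter;
records with `d_axon >= d_fiber` are rejected as measurement errors rather
than clipped. Diameters may come directly from a CSV or from segmented
cross-section masks as equivalent-circle diameters (`gratio_from_areas()`,
an extension of the direct-measurement workflow and labelled as such).
`gratio_scatter()` bins g against axon diameter (default 6 equal-width bins
over the pooled range — the original report shows a scatter, not bins, so
the bin count is a presentation choice) and the group comparison runs on
per-mouse mean g through the same Student machinery as everything else.

## EM lesion census

Census axes (lesion type, subcellular location, sheath layer, axon status,
microglial contact) are reduced to per-mouse percentages first — each
mouse's percentages sum to 100 exactly — and then averaged across mice
(mean +/- SEM), making the animal the statistical unit throughout. Vacuole
profile areas become equivalent-circle diameters `2 * sqrt(A / pi)`;
the size distribution reports per-mouse and pooled histograms (default bin
width 0.25 um), the pooled median, and the sub-micrometre fraction.

Lesion densities use the unbiased counting frame: a 400 um^2 square whose
left and bottom borders are forbidden (the two-forbidden-edges convention
is the only one that makes contiguous tiling count every object exactly
once, which the tests verify on 10^4 simulated points). Densities are
reported per 1000 um^2, per mouse first.

**Eccentric-sectioning correction.** A random thin section through a sphere
of diameter D shows a profile of diameter `D * sqrt(1 - u^2)` with the
plane offset u uniform; the median profile is `D * sqrt(3)/2 ~ 0.866 D`.
`correct_section_median()` therefore multiplies an observed median by
`2/sqrt(3) ~ 1.1547` by default, and the factor used is always part of the
output. This monodisperse-sphere model is self-consistent — sectioning
simulated spheres and correcting the observed median recovers D within 2%
— but it is deliberately minimal: no Wicksell unfolding of polydisperse
populations is attempted, and corrections quoted elsewhere from richer or
unstated models will differ from the default factor. An observed median of
0.83 um maps to 0.958 um under this model.

## Group statistics

Summaries are mean +/- SEM (sd with n-1 over sqrt(n)); a single animal
yields an undefined SEM reported as `NA`, never 0. Comparisons are
classical pooled-variance two-sided Student t tests (`welch = TRUE`
switches to Welch; sidedness of the original tests is unstated and
two-sided is assumed), with fold change attached and significance flagged
at 0.05. No multiple-testing correction is applied, matching the original
analysis; reports carry the comparison count so users can adjust
themselves. Zero-variance corner cases are handled explicitly: equal
constant groups give t = 0, p = 1; unequal constant groups are flagged
degenerate with p reported as 0.

The suite calibrates the test empirically (type-I error within [0.03,
0.07] over 1000 null replicates at n = 5 per group) and compares its p
values with an exact permutation oracle that enumerates every split of the
pooled sample. That comparison uses n = 10 per group: at n = 5 the
randomization distribution has only 126 support points, so its p is
granular and genuinely differs from the t-distribution p by up to ~0.06 in
the mid-range; by n = 10 the two agree within 0.02 everywhere, which is
what the check asserts.

## What the synthetic data do and do not show

The generators reproduce the statistical structure each estimator assumes:
smooth quadratic-polynomial backgrounds with amplitude comparable to the
foci (so plain thresholding fails while prominence does not), isotropic
Gaussian foci with a minimum separation, disk nuclei with a bounded
touching fraction placed at center distance 1.8 r (overlapping by up to
20% of the radius yet guaranteed separable by the distance-transform
watershed), ramified dilated-random-walk microglia shapes accumulated to a
target coverage, debris as a bright core with an annular rim (the core is
the regional maximum so red-channel detection lands on the debris center,
and the profile trough stays above half-prominence so the red support is
contiguous), categorical lesion mixtures whose defaults encode the
composition the pipeline was built around (about three-quarters vacuoles,
predominantly intramyelinic and innermost, half with an intact axon,
sparse microglial contact, log-normal diameters with median 0.83 um over
4 mice x 200 lesions), and a debris experiment of 5 mutant vs 8 control
mice with a 3.9-fold density difference.

They are parametric idealizations, not photorealistic microscopy: no PSF
stack, no shot noise chain, no irregular debris shapes, no intensity decay
with depth. Passing recovery tests therefore demonstrates that the
estimators are correct under their stated assumptions and calibrated
noise, not that they are robust to every artifact of real tissue. Every
generator returns the ground truth it actually realized, and all recovery
tests compare against realized — not requested — values.

## Problem sizes and numerical choices

Test and acceptance runs use desk-scale sizes chosen to exercise each
stage meaningfully: 256 x 256 px foci fields (20-200 foci), 400 x 400 px
nucleus fields (200 nuclei), 80-debris colocalization fields, 10^5 sphere
sections, 10^4 points for the counting-frame tiling, and 1000 null
replicates for test calibration. Tolerance grids run 5..100 in steps of 5
intensity units. Floating-point ties in the Otsu objective are grouped
within a 1e-12 relative band before applying the lowest-threshold rule;
the maxima engine breaks equal-height ties by minimum linear index; greedy
F1 matching resolves distance ties by scan order. Degenerate inputs
(constant ROIs, empty masks, zero-area polygons, flat profiles, empty
tables) raise informative errors or flagged absent calls rather than
silent results.
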