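# wmquant

Quantitative image analysis of early white-matter myelin pathology, as
studied in preclinical models of cerebral small-vessel disease (CADASIL).
The package is aimed at neuropathology groups who quantify myelin damage on
light, confocal and electron micrographs and want every step of that
quantification to be scripted, seeded and testable.

It implements the full measurement workflow:

- **Myelin-debris focus detection** — regional local maxima kept by
  *topographic prominence* (the height of a maximum above the highest
  saddle linking it to a higher maximum) above a noise tolerance, so foci
  are found against the non-uniform background that defeats plain
  thresholding; densities are reported per mm² of a hand-delineated region.
  The tolerance is calibrated on annotated fields by maximizing F1.
- **Oligodendrocyte counting** — DAPI nuclei segmented by Otsu
  thresholding, hole filling and a distance-transform watershed; a nucleus
  is Olig2⁺ when its mean marker intensity ≥ 1.1 × the mean over the
  nucleus enlarged by a pixel margin; densities per mm².
- **Microglial reaction** — stained-area fraction of a region after Otsu
  binarization (Iba-1 for total, CD68 for reactive microglia).
- **Axon presence in damaged sheaths** — debris selected on the red channel
  (blind to green), two perpendicular 1-px line profiles per debris, and an
  object-based call: axon present iff a prominent green peak lies within
  the half-prominence support of the red curve on at least one line.
- **g-ratios** — axon / outer sheath diameter with a binned
  g-versus-diameter scattergram and a per-mouse group comparison.
- **EM lesion census** — per-mouse percentages of lesion type, location,
  sheath layer, axon status and microglial contact; vacuole
  equivalent-diameter distributions with an eccentric-sectioning
  correction (random sphere sections have median profile √3/2 of the true
  diameter, so observed medians are multiplied by 2/√3 by default); lesion
  densities from 400 µm² unbiased counting frames (two forbidden borders)
  per 1000 µm².
- **Group statistics** — mean ± SEM with the mouse as the unit of
  analysis, pooled-variance Student's t tests, fold changes, and report
  tables.

No micrographs from the original study are deposited anywhere, so the
package ships a synthetic-data module (`gen_foci_image()`,
`gen_nuclei_image()`, `gen_microglia_image()`, `gen_coloc_image()`,
`gen_lesion_table()`, `sample_sphere_sections()`, `gen_gratio_table()`)
that generates every input with known ground truth; the test suite
validates each estimator by recovering what the generator realized.

## Worked example

Detect debris foci on a synthetic wide-field image, calibrating the noise
tolerance on three annotated fields first:

```r
library(wmquant)

f <- gen_foci_image(n_foci = 60, seed = 42)        # 256x256 px, 0.32 um/px
cal <- lapply(1:3, function(s) {
  g <- gen_foci_image(50, seed = s)
  list(image = g$image, centers = g$truth$centers)
})
tol <- calibrate_tolerance(cal, grid = seq(5, 100, by = 5))
tol$noise_tolerance
#> [1] 35

roi <- rect_roi(c(2, 255), c(2, 255), name = "corpus_callosum")
detect_foci(f$image, roi, detection_params(tol$noise_tolerance))
#> FocusSet: 60 foci in 0.006606 mm^2 (9082 / mm^2)
```

All 60 planted foci are recovered; the density is the exact count over the
physical ROI area (256² px at 0.32 µm/px ≈ 0.0066 mm²). A full two-group
in-silico experiment — 5 "mutant" mice carrying a 3.9-fold debris load
versus 8 controls, three fields per mouse, analyzed per mouse and compared
with a Student's t test:

```r
exp <- simulate_debris_experiment(seed = 42)
exp$test
#> mutant 1.667e+04 +/- 213.4 (n=5) vs control 3907 +/- 261.6 (n=8)
#>   t = 34.1, df = 11, p = 1.65e-12 (*); fold change 4.27
```

The fold change estimates the simulated 3.9-fold excess from the detected
densities (field-to-field Poisson variation makes any one realization
scatter around it).

A command-line front end (`wmq_cli()`, wrapper script in `inst/cli/`)
exposes the stages as subcommands: `simulate`, `detect-debris`,
`count-olig2`, `microglia-area`, `coloc`, `gratio`, `census`, `report`,
each accepting `--config`, `--seed`, `--out`.

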