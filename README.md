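# magrule

Simulation and morphometry toolkit for the **optical basis of the
"magnification rule"** used in semi-quantitative HER2 immunohistochemistry
(IHC) scoring.

## The problem

HER2-IHC of breast and gastric carcinoma is scored 0/1+/2+/3+ from the
intensity and pattern of membranous DAB (3,3'-diaminobenzidine) staining.
Human intensity judgment is unreliable — perceived brightness depends on the
surround — so a practical heuristic ties the score to the *lowest microscope
objective at which the stained membrane is recognizable*: visible at 5x means
3+, needing 10–20x means 2+, visible only at 40x means 1+. The physical
explanation is that the DAB precipitate is a thin linear band at the cell
boundary whose **width** per score category matches the diffraction-limited
resolution of the corresponding objective,

```
d = lambda / (2 NA),    NA = n sin(alpha)
```

so the set of objectives acts as a bank of physical band-width filters
(lambda = 600 nm: 5x/NA 0.14 -> 2.0 um, 10x/NA 0.3 -> 1.0 um, 20x/NA 0.5 ->
0.6 um, 100x/NA 0.75 -> 0.4 um). Reported per-category band widths are
1+: 0.64 ± 0.1 um, 2+: 1.0 ± 0.23 um, 3+: 2.14 ± 0.4 um, with width and
DAB color intensity linearly correlated (Pearson r = 0.73 pooled over 1+/2+)
and intensity saturated in 3+.

Since the underlying clinical slides are not publicly available, this package
implements the complete analysis as a *simulation + measurement* pipeline
with known ground truth:

- **synthesizer** — renders tumor cells with annular membranous DAB bands of
  known width and optical density (Beer–Lambert stain mixing, Gaussian PSF,
  8-bit RGB quantization at 5.11 px/um), with per-cell ground-truth manifests;
- **stain model** — Ruifrok–Johnston color deconvolution (base-10 optical
  density, H-DAB vectors) shared by rendering (forward) and analysis
  (inverse), plus the inverted relative intensity scale (0% white, 100% black);
- **morphometry** — the measurement protocol: 10 cells/specimen, 4 line
  profiles perpendicular to the membrane per cell, band width as the full
  width at half maximum (FWHM) with sub-pixel (0.25 px) bilinear sampling,
  aggregation to cells and specimens;
- **optics** — Abbe's law and the resolution-window classifier mapping a
  specimen's mean band width to its IHC score;
- **cohort statistics** — Welch two-sample t-tests at alpha = 1%, per-category
  summaries and histograms, width–intensity Pearson correlation, and the
  ISH-subgroup negative control within the equivocal 2+ category.

## Worked example

```r
library(magrule)

abbe_resolution(600, c(0.14, 0.30, 0.50, 0.75))
#> [1] 2.1428571 1.0000000 0.6000000 0.4000000

cfg  <- specimen_config("2+", seed = 42)     # one equivocal specimen
spec <- render_specimen(cfg)                 # 715 x 715 px, 5.11 px/um
cells <- measure_specimen(spec$image, spec$truth, seed = 43)
head(cells[, c("true_width_um", "mean_width_um", "mean_intensity_pct")], 3)
#>   true_width_um mean_width_um mean_intensity_pct
#> 1     0.5902991     0.5933000           59.21569
#> 2     0.9604590     0.9573568           72.54902
#> 3     1.2793752     1.2748557           73.33333

summarize_specimen(cells)
#>   mean_width_um sd_width_um mean_intensity_pct n_cells n_measured assigned_score
#> 1     0.9727861   0.2674267           67.17647      10         10             1+
```

The measured FWHM tracks the true band width to a few nanometers; this
specimen's mean (0.97 um) falls just below the 1.0 um (10x) window edge and
classifies 1+ — the intrinsic boundary ambiguity of the equivocal category,
whose generative mean sits exactly on the 10x resolution limit.

A full default cohort (3 categories x 40 specimens x 10 cells x 4 ROIs =
4800 measurement slots) runs in about a minute:

```r
res <- run_cohort(cohort_config(master_seed = 1))
cohort_statistics(res$cells, res$specimens)$category$summary
```

With master seed 1 the per-category grand means of the measured per-cell
widths are 0.645 / 0.990 / 2.112 um (targets 0.64 / 1.0 / 2.14) and the
pooled 1+/2+ width–intensity Pearson r is 0.725 (target 0.73); all three
pairwise Welch tests reject at alpha = 1%, while the 20/20 ISH split of the
2+ cohort does not separate (negative control).

## CLI

```sh
Rscript inst/cli/magrule.R run-all --config cfg.json --out run1   # or:
Rscript inst/cli/magrule.R synth   --config cfg.json --out imgs
Rscript inst/cli/magrule.R measure --images imgs --manifest imgs/manifest.csv --out meas
Rscript inst/cli/magrule.R stats   --cells meas/cells.csv --specimens meas/specimens.csv --out report
```

Images are written as lossless 8-bit PPM with the pixel scale recorded in the
header. See `vignettes/magnification-rule.Rmd` for the model, parameter and
calibration details and the package's known limitations.
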