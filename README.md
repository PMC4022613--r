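# echostruct

Quantification of left-ventricular (LV) myocardial **microstructure** from
ordinary B-mode echocardiograms, for researchers studying hypertensive heart
disease and other conditions in which tissue-level remodeling precedes
visible changes in chamber geometry.

## The measurement

Ultrasound reaching the pericardium has passed through the overlying
myocardium, so the brightness of the pericardial line carries information
about scattering and attenuation inside the muscle. On an 8-bit B-mode
frame (pixels 0–255), the package computes the **Signal Intensity
Coefficient**

```
SIC = 1 - p / 256
```

where `p` is the 25th-percentile (nearest-rank) intensity of a
user-delineated **pericardial** region of interest adjacent and parallel to
the inferolateral mid-to-basal myocardial segment in the parasternal
long-axis view. Darker pericardial reflection — the signature of a
heterogeneous, fibrotic myocardium upstream — gives a higher SIC.

The microstructural SIC is combined with the macrostructural relative wall
thickness `RWT = (IVS + PW) / LVDD` into the **Myocardial Structural
Index**

```
MSI = SIC / 0.13 + RWT / 0.05
```

Alongside these, the package provides the conventional measures (LV wall
thickness, Teichholz volumes and ejection fraction, fractional shortening,
linear-method LV mass, E/A and E/e′ ratios, mean arterial pressure
`MAP = DBP + (SBP − DBP)/3`), a layered Rayleigh-speckle **phantom
generator** with a disease-severity dial θ ∈ [0, 1], a clinical-style
**cohort simulator**, and the **statistical pipeline** used to evaluate
such an index: pooled t tests, chi-square, standardized (per-1-SD)
regressions with age/sex adjustment, nearest-rank tertiles with the Cuzick
rank test for trend, tie-corrected Kruskal-Wallis, Pearson correlation, and
ICC(2,1) reader-reproducibility analysis.

## Worked example

```r
library(echostruct)

# a synthetic B-mode frame at intermediate disease severity
ph  <- generate_phantom(phantom_spec(severity = 0.5, seed = 42))
res <- compute_sic(extract_pixels(ph$frame, ph$pericardial_roi))
res
#> <SIC 0.4414 (p25 = 143, n = 7680, pericardial ROI)>

msi <- compute_msi(res$sic, rwt(lvwt(0.9, 0.9), 4.0))
sprintf("MSI = %.3f", msi$msi)
#> "MSI = 12.395"
```

The pericardial ROI's 25th-percentile intensity is 143, so
SIC = 1 − 143/256 ≈ 0.441; with RWT = 1.8/4.0 = 0.45 the composite index is
0.441/0.13 + 0.45/0.05 ≈ 12.4. At severity 0 the same phantom seed gives a
brighter pericardium (SIC ≈ 0.30); severity monotonically raises the SIC.

A simulated two-group cohort run through the analysis grid:

```r
tab <- attach_derived(simulate_cohort(cohort_params_clinical(seed = 1)))
b   <- run_clinical_analysis(tab)            # t tests, regressions, trends
subset(b$status_regression, variable %in% c("sic", "msi"))
#>  outcome variable      model coefficient     se       p  n
#>   status      sic unadjusted       0.111 0.0657 0.09762 58
#>   status      sic   adjusted       0.109 0.0663 0.10714 58
#>   status      msi unadjusted       0.184 0.0627 0.00495 58
#>   status      msi   adjusted       0.197 0.0642 0.00335 58
```

Coefficients are the change in group status (0/1) per 1-SD of each
echocardiographic measure; at n = 58 a single simulated draw may or may not
reach significance for SIC alone (the power at the preset group separation
is ≈ 0.7), while the composite MSI separates groups more strongly — the
qualitative pattern the index was designed for.

## Command line

```sh
Rscript inst/cli/echostruct.R cohort  --preset clinical --seed 1 --out cohort.csv
Rscript inst/cli/echostruct.R stats   --cohort cohort.csv --out-dir results/
Rscript inst/cli/echostruct.R phantom --config spec.json --out-prefix ph/scene
Rscript inst/cli/echostruct.R measure --manifest ph/scene_manifest.csv --out sic.csv
Rscript inst/cli/echostruct.R demo    --seed 1 --out-dir demo/
```

## Documentation

The methods vignette (`vignettes/echostruct-methods.Rmd`) describes the
model and its assumptions, what the phantom and cohort simulators do and do
not emulate, all numerical conventions (nearest-rank percentiles, the
divisor 256, rasterization rules), and known limitations.
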