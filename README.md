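# adchist

Tumor ADC measurement from diffusion-weighted MRI, with histogram
post-processing of non-precise delineations — exercised end-to-end on a
synthetic rectal-tumor phantom cohort.

## The problem

The mean apparent diffusion coefficient (ADC) of a rectal tumor, measured
over a whole-volume expert delineation on high-b-value DWI, is a candidate
prognostic imaging marker. Precise tracing is slow; a quick circular/oval
VOI with a margin admits surrounding tissue (rectal wall, bladder,
mesorectal fat, air), inflating and widening the ADC histogram. `adchist`
implements and evaluates the histogram-based rescue: extract first-order
statistics from the contaminated VOI and find the percentile that best
reproduces the precise mean ADC, judged by the intraclass correlation for
absolute agreement. It also asks whether any histogram metric separates
binary prognostic subgroups once tests are Holm-corrected.

Patient data of this kind are not public, so the package ships a digital
phantom: 4-D multi-b-value DWI volumes (mono-exponential signal, Rician
noise) of a pelvic geometry with known per-voxel ground-truth ADC, two
simulated readers per delineation method, and prognostic labels whose only
true imaging signal is on tumor volume.

## What is implemented

* **Phantom** (`phantom_config()`, `build_phantom_case()`,
  `generate_cohort()`): b = 0, 25, 50, 100, 500, 1000 s/mm²;
  1.82 × 2.26 mm in-plane, 5.5 mm slice spacing; tumor ADC
  1.44 ± 0.40 × 10⁻³ mm²/s over contaminating tissues; NIfTI + FSL-style
  bval export.
* **ADC fitting** (`fit_adc_voxel()`, `compute_adc_map()`): voxelwise
  log-linear OLS of ln S on b — `ln S(b) = ln S₀ − b·ADC` — over all
  positive signals; negative fits clipped to 0 and flagged; optional
  nonlinear variant.
* **Histogram metrics** (`voi_metrics()`, `compute_histogram_metrics()`):
  min, max, mean, median, SD, skewness, Pearson kurtosis (normal → 3),
  every fifth percentile (5th–95th), VOI volume in cm³.
* **Agreement** (`icc_absolute_single()`, `bland_altman()`,
  `percentile_sweep()`, `interreader_table()`): ICC(A,1) from variance
  components, Bland–Altman bias and limits of agreement, and the sweep
  identifying the non-precise surrogate of the precise mean ADC.
* **Group statistics** (`choose_and_run_test()`, `holm_bonferroni()`,
  `outcome_table()`): Shapiro–Wilk-gated Welch t / Mann–Whitney U
  comparisons with step-down Holm correction per outcome family.
* **Pipeline** (`run_config()`, `run_all()`): one seeded, bit-reproducible
  run writing metrics, agreement tables and outcome tables plus a manifest.

The numbered scripts under `analysis/` run the same workflow stage by
stage (simulate → fit → metrics → agreement → group comparisons), writing
NIfTI volumes under `scratch/cohort/` and tables under `results/`.

## Worked example

```r
library(adchist)

cohort  <- generate_cohort(phantom_config(seed = 1), n_cases = 37)
metrics <- cohort_metrics(cohort$cases)

avg <- reader_average(metrics)
sapply(split(avg$mean, avg$method), mean)
#> nonprecise    precise
#>   1.497100   1.418845

it <- interreader_table(metrics)
it[it$metric == "mean", ]
#>   metric icc_precise icc_nonprecise icc_between
#> 4   mean   0.9941115      0.9842821   0.5275521

sw <- percentile_sweep(metrics)
attr(sw, "best_metric");  attr(sw, "best_icc_range")
#> [1] "p40"
#> [1] 0.7316614 0.7429138
```

Reading these numbers: contamination lifts the non-precise cohort mean ADC
(1.50 vs 1.42 × 10⁻³ mm²/s, both within-method reader agreements ≈ 0.98+),
drops the between-method agreement on the mean to 0.53, and the sweep finds
that the 40th percentile of the non-precise histogram — not its mean —
best reproduces the precise mean ADC (ICC 0.73–0.74 across the four reader
pairings). Group comparisons on the same cohort leave only VOI volume
significant after Holm correction for the volume-linked outcomes.

## Scope

No realistic anatomy, EPI distortion or perfusion (IVIM) modelling; no
DICOM ingestion; no texture features beyond first-order histogram
statistics; no survival or multivariable modelling. The methods vignette
(`vignettes/adc-histogram-phantom.Rmd`) documents the model, every
calibrated default, and what phantom results do and do not say about
patient data.
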