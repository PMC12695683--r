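# rtimagerisk

Radiobiological risk modelling of daily MV-CBCT imaging dose in
radiotherapy.

Image-guided radiotherapy platforms that use the treatment beam for
volumetric setup imaging (megavoltage cone-beam CT) deposit a small dose in
normal tissue at every fraction. Over a 25–35-fraction course this
accumulates to the 1–2 Gy range, and the choice between a low-dose (e.g.
5 MU) and a high-quality (e.g. 10 MU) acquisition protocol doubles it.
`rtimagerisk` is for medical physicists and modelling researchers who want to
turn that dosimetric difference into organ-level risk estimates:

* **rtio** — read/write DICOM RTDOSE and RTSTRUCT, rasterize contours to
  voxel masks, resample dose grids, and accumulate treatment plus MU-scaled
  per-fraction imaging dose over the course;
* **dvh** — differential and cumulative dose-volume histograms and
  voxel-exact organ mean dose;
* **risk models** — logistic NTCP
  `NTCP = 1 / (1 + exp(γ(D50 − D)))` on mean dose, LKB NTCP
  `Φ((gEUD − D50)/(m·D50))` on the generalized equivalent uniform dose,
  Schneider organ equivalent dose `OED = Σ vᵢ Dᵢ exp(−α′Dᵢ)` (α′ = 0.085
  Gy⁻¹), and excess absolute risk `EAR = EAR₀ · OED · μ(e, a)` in cases per
  10 000 person-years with the age modifier
  `μ(e,a) = exp(γₑ(e − 30)) · (a/70)^{γₐ}`, all driven by a citable,
  user-overridable parameter registry;
* **cohort** — per-patient pipeline, paired two-tailed t-tests between
  protocols, age stratification (<40 / 40–60 / >60), sensitivity sweeps,
  CSV/JSON/plot export, and a small CLI (`inst/cli/rtimagerisk.R`);
* **synthdata** — seeded synthetic DICOM-RT phantom cohorts (breast, pelvic,
  head & neck) with realistic dose magnitudes, so the whole pipeline runs
  and is testable without any patient data.

## Worked example

Generate a synthetic 10-patient breast cohort and compare the 5 and 10 MU
daily imaging protocols over 25 fractions:

```r
library(rtimagerisk)
library(dplyr)

spec <- cohort_spec("breast", n_patients = 10, seed = 42)
man  <- generate_cohort(spec, file.path(tempdir(), "phantoms"))

rep <- compare_protocols(man,
                         protocol_spec("5MU", 5, 25),
                         protocol_spec("10MU", 10, 25))
rep
#> <cohort_report> 10 patient(s), protocols 5MU vs 10MU (total mode)
#>   4 ROI(s); 12 of 12 comparisons significant at p < 0.05

tidy(rep, "summaries") |> filter(metric == "mean_dose_gy")
#> # A tibble: 8 × 6
#>   roi         protocol metric           n  mean    sd
#>   <chr>       <chr>    <chr>        <int> <dbl> <dbl>
#> 1 Breast_CNTR 10MU     mean_dose_gy    10  4.53 0.243
#> 2 Breast_CNTR 5MU      mean_dose_gy    10  3.74 0.232
#> 3 Heart       10MU     mean_dose_gy    10  7.55 0.448
#> 4 Heart       5MU      mean_dose_gy    10  6.74 0.441
#> 5 Lung_CNTR   10MU     mean_dose_gy    10  4.66 0.249
#> 6 Lung_CNTR   5MU      mean_dose_gy    10  3.84 0.237
#> 7 Lung_IPSI   10MU     mean_dose_gy    10 18.8  1.11
#> 8 Lung_IPSI   5MU      mean_dose_gy    10 17.9  1.11
```

Every organ's course-total mean dose rises by ~0.8 Gy when the imaging
protocol doubles from 5 to 10 MU (25 fractions × ~0.03 Gy per extra
acquisition), and the paired t-test flags each of the twelve ROI × metric
comparisons at p < 0.05. Age stratification shows the inverse gradient of
secondary-cancer risk with age at exposure:

```r
stratify_by_age(rep) |> filter(roi == "Breast_CNTR", protocol == "10MU")
#> # A tibble: 3 × 6
#>   age_group roi         protocol     n mean_ear sd_ear
#>   <fct>     <chr>       <chr>    <int>    <dbl>  <dbl>
#> 1 <40       Breast_CNTR 10MU         2    23.4   0.380
#> 2 40-60     Breast_CNTR 10MU         3    13.8   3.94
#> 3 >60       Breast_CNTR 10MU         5     6.05  1.19
```

(`mean_ear` is in cases per 10 000 person-years.) `export_report(rep, dir)`
writes the per-patient, summary, comparison and strata tables as CSV plus a
JSON run manifest; `autoplot(rep, "ear_per_10k_py", log_scale = TRUE)` draws
the protocol-comparison boxplots. A caveat worth knowing: the
linear-exponential OED peaks at 1/α′ ≈ 11.8 Gy, so for organs already above
that dose (here the ipsilateral lung at ~19 Gy) adding imaging dose can
slightly *lower* the modelled EAR — isolate the imaging contribution with
`run_config(mode = "imaging_only")` when that is the quantity of interest.

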