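# radsurvey

Population-exposure surveys from medical imaging, as a tested R pipeline.

National dosimetry surveys estimate the average annual effective dose per
inhabitant from diagnostic radiology by combining, for each modality *m*,
the examination frequency per 1000 inhabitants *f<sub>m</sub>* with the
effective-dose vector *Ē<sub>m</sub>* (mean effective dose per examination,
mSv):

&nbsp;&nbsp;&nbsp;&nbsp;*D* = Σ<sub>m</sub> *f<sub>m</sub>* · *Ē<sub>m</sub>* / 1000&nbsp;&nbsp;[mSv per inhabitant per year]

`radsurvey` is aimed at medical physicists and public-health analysts who
run or audit such surveys. It covers the full chain:

* **Examination building** — invoice-level billing acts are grouped into
  examinations (one modality + region per patient, facility and calendar
  day), with co-billed CT regions merged into combined examinations
  (`build_examinations()`, `merge_rule()`), and verified against a RIS
  reference (`verify_against_ris()`).
* **Frequency estimation** — national frequencies from partially observed
  sources: billing coverage scaling by population share or by medical
  activity ratio (`extrapolate_billing()`), questionnaire response-rate
  scaling (`extrapolate_survey()`), per-1000 conversion (`per_1000()`), and
  multi-channel precedence (`combine_frequencies()`).
* **CT dosimetry** — per-region median DLP from dose-archive records, pooled
  and per facility stratum, converted to effective dose (*E = k ·* median
  DLP) and frequency-weighted into the CT dose vector with a stratum-spread
  uncertainty (`summarize_dlp()`, `ct_dose_vector()`,
  `stratum_uncertainty()`).
* **Dose-vector assembly** — literature/DRL-based scalars per modality plus
  a nuclear-medicine vector computed from a procedure mix including the CT
  component of hybrid imaging (`nm_effective_dose()`,
  `assemble_dose_tables()`).
* **Reporting** — per-inhabitant dose, contribution shares, between-survey
  trends, CSV/JSON/chart output (`build_result()`, `compare_surveys()`,
  `render_report()`), with broom-style `tidy()`/`glance()` and
  `autoplot()` methods.
* **Synthetic data** — `generator_config()` + `simulate_survey_data()` draw
  invoice, RIS, DACS and survey-response tables with the statistical
  structure the analysis assumes (Poisson counts, log-normal DLPs,
  configurable RIS discrepancies and combined-CT rate), so everything above
  is testable without confidential hospital data.

The packaged reference tables (`swiss_modalities_2018()`,
`swiss_ct_regions_2018()`, `swiss_survey_2013()`,
`swiss_verification_2018()`) are the published summary figures of the
2013/2018 Swiss national surveys and make the published results reproducible
out of the box.

## Worked example

```r
library(radsurvey)
library(dplyr)

res <- build_result(swiss_modalities_2018(), year = 2018)
res
#> <survey_result 2018>
#>   12 modalities; 1.23 examinations per inhabitant
#>   dose per inhabitant: 1.486 mSv (1.379 without nuclear medicine)
```

The average inhabitant receives about 1.49 mSv per year from medical
imaging (1.38 mSv excluding nuclear medicine), from about 1.2 examinations.
Where does it come from?

```r
share_of(res, "CT", "dose")
#> [1] 64.31703
share_of(res, c("dental radiography (without CBCT)", "CBCT"), "frequency")
#> [1] 47.89294
```

CT delivers 64.3% of the collective dose despite being only ~11% of the
examinations; dental imaging is almost half of all examinations but a
negligible dose share. The CT dose vector itself comes from dose-archive
DLP records; on the published per-region table:

```r
ct <- swiss_ct_regions_2018()
ct_dose_vector(ct, ct)
#> <ct_dose_vector>
#>   dose vector: 7.18 mSv over 15 regions
stratum_uncertainty(swiss_ct_stratum_2018())  # university vs non-university
#> [1] 0.07652456  (~8%)
```

Trends against the previous survey:

```r
compare_surveys(swiss_survey_2013(), res) |>
  filter(modality %in% c("CT", "Total")) |>
  select(modality, frequency_change_pct, dose_per_exam_change_pct)
#> # A tibble: 2 × 3
#>   modality frequency_change_pct dose_per_exam_change_pct
#> 1 CT                     15.4                     -17.2
#> 2 Total                  -0.254                    -2.49
```

CT examinations rose ~15% in five years while the dose per CT examination
fell ~17% — total exposure stayed stable. `render_report()` writes these
tables, a JSON summary and a contribution chart to a directory.

A fully synthetic run (generate → build → extrapolate → dose vectors →
report) is shown in the vignette
`vignettes/population-dose-surveys.Rmd`, which also documents the model
assumptions, parameter defaults and their limits.

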