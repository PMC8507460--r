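---
title: "Estimating population exposure from medical imaging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating population exposure from medical imaging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(radsurvey)
library(dplyr)
```

Nationwide surveys of medical-imaging exposure answer one question: how much
effective dose does the average inhabitant receive per year from diagnostic
radiology, and which modalities drive it? The answer is assembled from two
ingredients that no single data source provides together — the *frequency* of
examinations per 1000 inhabitants, and the *effective-dose vector* (mean
effective dose per examination, in mSv) of each modality:

$$
D \;=\; \sum_m \frac{f_m \, \bar E_m}{1000}
\qquad \text{[mSv per inhabitant per year]}
$$

where $f_m$ is the annual frequency of modality $m$ per 1000 inhabitants and
$\bar E_m$ its dose vector. `radsurvey` implements the whole chain from raw
invoice-level billing records and dose-archive (DACS) extracts to $D$, its
contribution breakdown, and between-survey trends, together with a synthetic
generator that emulates the (confidential) hospital sources so the pipeline
is testable end to end.

## The counting unit: examinations, not invoice lines

Billing systems record *acts*; surveys count *examinations*: one or more
exposures of an anatomical region with a single modality during a single
visit, answering one clinical question. Two conventions close the gap, both
implemented in `build_examinations()`:

* **Session key.** A visit is identified as one (patient, facility, calendar
  date) triple. Billing data carry no finer visit identifier that is
  comparable across institutions, and a calendar day is the coarsest key that
  still separates a chest CT on Monday from an abdomen CT on Tuesday.
  Repeated identical codes inside a session collapse into one examination
  (the `n_source_codes` column preserves the invoice-line count, so no
  information is destroyed).
* **Merge rules.** Combined acquisitions — above all chest + abdomen CT —
  are billed as two codes but are one examination with its own, higher,
  dose. A `merge_rule()` lists the component regions and the combined label;
  within a CT session holding *all* components, the components are replaced
  by one combined examination. Rules apply greedily in their given order and
  each region is consumed at most once: a chest + abdomen + pelvis session
  under the default rule becomes one combined chest-and-abdomen examination
  plus a separate pelvis examination. No transitive closure is invented —
  only explicitly configured combinations merge. Merging is restricted to
  CT, where combined protocols are routine practice; nothing in the
  machinery forbids rules for other modalities if a user configures them.

Counting is verified against the radiology information system (RIS) of the
same facilities with `verify_against_ris()`. The relative difference is
anchored on the billing-derived figure, $(f_\mathrm{billing} -
f_\mathrm{RIS})/f_\mathrm{billing}$, reported to two decimals; for the 2018
Swiss data this gives 4.10% for radiography, 19.26% for CT and 7.73%
overall — the verification table doubles as a subjective uncertainty
statement for the frequency side.

```{r verification}
verification_summary(swiss_verification_2018())
```

## From observed counts to national frequencies

Billing extracts cover part of the population (10.7% in the 2018 survey —
one canton's complete data). `extrapolate_billing()` supports two modes and
always reports both:

* **population scaling** — divide by the covered population fraction
  (0.107);
* **activity ratio** — divide by the covered share of *general medical
  activity* (0.101), under the hypothesis that the indication for
  radiological examinations is homogeneous across the country.

The activity-ratio factor is an exogenous input: deriving it needs
general-consultation volumes outside this pipeline's scope. Modalities
outside the billing extract are collected by questionnaire and scaled by the
observed response rates (`extrapolate_survey()`; 18.1% diagnostic
mammography, 29.1% dental, 27% CBCT, 94.1% nuclear medicine), and a few
(screening mammography, interventional cardiology) come from medical-society
reports as ready-made national figures. `combine_frequencies()` resolves
modalities estimated by several channels through a configured precedence
order, mirroring that hybrid design.

## The CT dose vector from dose-archive records

CT dominates the collective dose, so its dose vector is estimated from real
dose data rather than reference levels. `summarize_dlp()` takes per-
acquisition dose-length-product (DLP) records, computes the median per
region — pooled and per facility stratum — and converts it to effective dose
with region-specific factors $k$ (mSv per mGy·cm): $E_r = k_r \cdot
\mathrm{median}(\mathrm{DLP}_r)$, exactly. Conventions:

* the **median**, not the mean, is the location estimate (dose-indicator
  distributions are right-skewed; the median matches reference-level
  practice); even record counts use the mean of the two central order
  statistics;
* the **pooled** (all-records) median per region gives the central estimate;
  the university / non-university strata are used for the uncertainty only;
* the conversion factors are **configuration**, not science owned by this
  package: the shipped `default_conversion_factors()` are an illustrative
  set in the range of published adult factors, and any real analysis should
  substitute the user's preferred published table.

`ct_dose_vector()` then weights region doses by the region frequencies
obtained from the examination builder:
$\bar E_\mathrm{CT} = \sum_r s_r E_r$ with $s_r = f_r / \sum_r f_r$.
On the published 2018 per-region table this gives 7.18 mSv (printed
per-region contributions sum to 7.11; the survey reports 7.1 ± 0.5 — the
spread reflects rounding of the printed inputs).

**Uncertainty.** Re-estimating the vector with university-only and
non-university-only dose data gave 6.73 and 7.5 mSv in 2018;
`stratum_uncertainty()` summarises such stratum estimates as the sample
standard deviation (n − 1 denominator) over the mean — about 8% here. The
mean of the *stratum values* is used as denominator (a self-contained ratio
of the same two numbers); with two strata differing by ~11% the choice of
denominator moves the ratio by well under a point. With fewer than two
strata the ratio is reported as `NA`, not zero: an absent spread is not
evidence of no uncertainty.

```{r ct}
ct <- swiss_ct_regions_2018()
glance(ct_dose_vector(ct, ct))
stratum_uncertainty(swiss_ct_stratum_2018())
```

## Non-CT dose vectors and nuclear medicine

Radiography, fluoroscopy, mammography, dental and interventional dose
vectors come from national dose-survey compilations and enter as configured
scalars with mandatory provenance notes (`default_modality_doses()` ships
the published 2018 values). Nuclear medicine combines two components per
procedure: the radiopharmaceutical dose (administered activity × dose
coefficient) and, for hybrid SPECT-CT / PET-CT acquisitions, the CT dose
(DLP × $k$), whether that CT is an attenuation-correction map or a
diagnostic series. `nm_effective_dose()` takes the share-weighted mean over
the procedure mix. The shipped `default_nm_procedures()` mix is
*illustrative*: the published survey prints only the modality-level 8.04 mSv
vector, so four realistic procedures are calibrated to that total — the
combination rule, not the mix, is the tested contract.

`assemble_dose_tables()` joins the three sources into one table. Configured
values pass through bit-for-bit, and a configured CT or nuclear-medicine
scalar *overrides* the computed value with an explicit provenance flag —
overriding silently would hide a disagreement between configuration and
data.

## Headline results and trends

`build_result()` produces the per-modality dose per inhabitant, the totals
with and without nuclear medicine, examinations per inhabitant, and
contribution shares. Shares use the all-modality (nuclear-medicine-
inclusive) totals as denominator so that all shares sum to 100%; pooled
shares (dental including CBCT: 47.89% of examinations in 2018) come from
`share_of()`. `compare_surveys()` anchors percentage changes on the earlier
survey and also derives the mean dose per examination
(dose per inhabitant ÷ frequency × 1000) — between 2013 and 2018 the CT
frequency rose 15% while the CT dose per examination fell 17%, leaving the
total exposure stable. A modality present in only one survey is kept with
`NA` changes rather than dropped. All computation is carried at full
precision; rounding to presentation precision (one decimal for frequencies,
two for vectors and shares, three for per-inhabitant doses) happens only in
`render_report()`.

```{r result}
res <- build_result(swiss_modalities_2018(), year = 2018)
res
trend <- compare_surveys(swiss_survey_2013(), res)
trend |>
  filter(modality %in% c("CT", "conventional radioscopy", "Total")) |>
  select(modality, frequency_change_pct, dose_per_exam_change_pct)
```

## What the synthetic generator emulates — and what it does not

Real invoice, RIS and DACS extracts are confidential, so
`simulate_survey_data()` draws datasets with the statistical structure the
analysis assumes:

* per-facility examination counts are independent Poisson with mean
  frequency × population / 1000, scaled by the billing coverage and
  allocated by facility volume shares — a simple, variance-honest null for
  frequency-recovery tests;
* a configured share of CT sessions (16.4% by default, the 2018 combined
  chest-abdomen share) carries both a chest and an abdomen code, which the
  examination builder must re-merge;
* DLPs are log-normal per (region, stratum) — standard for dose-indicator
  distributions, and it makes the configured medians exact distribution
  parameters; default medians are chosen so that median × $k$ reproduces the
  published per-region doses, with university facilities lower and
  non-university higher (markedly so for chest CT, 2.9 vs 4.7 mSv);
* the RIS mirrors the billing-derived examinations except for a configured
  discrepancy rate (half deletions, half duplications by default);
* web-survey responses are Bernoulli *per facility* at the published
  response rates.

Defaults reproduce the 2018 Swiss study conditions: the published
frequencies as ground truth, 10.7% coverage, 8.5 million inhabitants
(population size is an explicit parameter — per-1000 figures are
meaningless without a stated denominator). One base seed drives
deterministic per-table sub-streams, so bundles are bit-for-bit reproducible
and the caller's RNG state is untouched. Identical draws within one session
are collapsed at generation time: by the examination definition they are one
examination.

What the generator does **not** emulate — and hence what green tests do not
certify about real data: age- and sex-dependent dose, seasonal and weekday
structure, coding errors and code-list drift in real tariff data,
facility-size correlation with case mix, patient-level longitudinal
correlation, and any DICOM-level detail. The generator validates the
*arithmetic* of the pipeline, not the fidelity of real billing practice.

One statistical consequence of facility-level response worth knowing: for a
modality with response rate $r$ the sampling variance of the extrapolated
count is $\Lambda/r + \tfrac{1-r}{r}\sum_j \lambda_j^2$ (facilities $j$ with
means $\lambda_j$, $\Lambda = \sum_j \lambda_j$), which for low $r$ and a
concentrated facility panel far exceeds the naive Poisson term. The
recovery tests use this exact variance for the survey channel; with the
2018 dental response rate of 29.1% the resulting coefficient of variation
is large unless the facility panel is large — which is faithful to how such
surveys behave.

## Numerical choices and problem sizes

* Relative differences and percentage changes divide by the *reference*
  figure (billing for verification, the earlier survey for trends); a zero
  reference yields `NA`, never an error or an infinity.
* Region/modality set mismatches between tables are hard errors listing the
  offending labels; silent dropping is reserved for nothing.
* Merge-rule ambiguity (two rules over the same component set) is rejected;
  rule order is the explicit tie-break for overlapping rules.
* Test problem sizes are chosen so the full suite runs in well under a
  minute: populations of 2–10 × 10⁵ with coverage 0.25–1 for frequency
  recovery (Poisson/Bernoulli 3-standard-error bounds), 2000 DLP records per
  (region, stratum) for median recovery within 5%, and 10–25 random invoice
  sets of ≤ 20 lines against a brute-force grouping oracle.

## Limitations

The package reproduces a survey *methodology*, not a survey: real TARMED
code lists, the METAXA-style extraction tooling, DICOM/DACS connectivity,
Monte-Carlo derivation of DLP-to-dose conversion factors, and
nuclear-medicine reference-level surveys are all upstream of its inputs.
Extrapolation rests on the homogeneity hypothesis discussed above; the
package reports both modes side by side precisely because that hypothesis is
untestable from billing data alone. Uncertainty reporting is deliberately
modest — a verification table and a stratum-spread ratio — matching what the
source data support; it is not a full error propagation.
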