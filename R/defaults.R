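# Shipped default configuration tables. These are package defaults for the
# synthetic pipeline, documented where they are externally sourced or
# illustrative; every one of them can be replaced by the user.

#' Default billing-code map
#'
#' A synthetic code map associating one invented billing code with each
#' (modality, anatomical region) pair used by the synthetic generator,
#' including the merged "chest and abdomen" CT label so that already-merged
#' examinations can be re-expressed as single codes. Real tariff systems
#' (such as the Swiss TARMED) use their own code lists; this table stands in
#' for such a mapping and is flagged synthetic.
#'
#' @return A tibble with columns `billing_code`, `modality`, `region`.
#' @examples
#' default_code_map()
#' @export
default_code_map <- function() {
  mix <- default_region_mix()
  pairs <- dplyr::distinct(mix, .data$modality, .data$region)
  pairs <- dplyr::bind_rows(
    pairs,
    tibble::tibble(modality = "CT", region = "chest and abdomen")
  )
  pairs <- dplyr::distinct(pairs, .data$modality, .data$region)
  pairs <- dplyr::arrange(pairs, .data$modality, .data$region)
  prefix <- toupper(substr(gsub("[^a-zA-Z]", "", pairs$modality), 1, 3))
  pairs$billing_code <- sprintf("%s.%04d", prefix, seq_len(nrow(pairs)))
  dplyr::select(pairs, "billing_code", "modality", "region")
}

#' Default CT merge rules
#'
#' Co-billed chest and abdomen CT codes in one session are counted as a
#' single combined "chest and abdomen" examination; surveys that do not
#' separate combined acquisitions overstate the examination count and
#' misattribute dose. Additional rules can be created with [merge_rule()].
#'
#' @return A tibble of merge rules (see [merge_rule()]).
#' @examples
#' default_merge_rules()
#' @export
default_merge_rules <- function() {
  merge_rule(c("chest", "abdomen"), "chest and abdomen")
}

#' Default per-modality true frequencies for the generator
#'
#' Per-1000-inhabitant annual examination frequencies matching the published
#' 2018 Swiss survey estimates (see [swiss_modalities_2018()]), used as the
#' generator's ground truth so that synthetic data reproduce the national
#' frequency structure.
#'
#' @return A named numeric vector, examinations per 1000 inhabitants per year.
#' @export
default_modality_frequencies <- function() {
  tbl <- swiss_modalities_2018()
  setNames(tbl$frequency_per_1000, tbl$modality)
}

#' Default facility strata
#'
#' Three facility classes with counts and volume shares: a few university
#' hospitals carrying a large share of the billed volume, regional hospitals
#' and private imaging centres. Shares are illustrative but mirror the
#' concentration of imaging volume in large providers.
#'
#' @return A tibble with columns `stratum`, `n_facilities`, `volume_share`.
#' @export
default_facility_strata <- function() {
  tibble::tibble(
    stratum      = c("university", "regional", "private"),
    n_facilities = c(5L, 10L, 15L),
    volume_share = c(0.45, 0.30, 0.25)
  )
}

#' Default region mix per modality
#'
#' Shares of each modality's examinations by anatomical region. For CT the
#' shares follow the published 2018 per-region frequencies, excluding the
#' combined "chest and abdomen" label (combined sessions are produced by the
#' generator's `combined_ct_rate` and rebuilt downstream by the merge rules).
#' Non-CT modalities use a single "all" region: their dose vectors are
#' scalars, so a region split adds nothing.
#'
#' @return A tibble with columns `modality`, `region`, `share`; shares sum to
#'   1 within each modality.
#' @export
default_region_mix <- function() {
  ct <- swiss_ct_regions_2018()
  ct <- ct[ct$region != "chest and abdomen", ]
  ct_mix <- tibble::tibble(
    modality = "CT",
    region   = ct$region,
    share    = ct$frequency_per_1000 / sum(ct$frequency_per_1000)
  )
  other <- setdiff(names(default_modality_frequencies()), "CT")
  dplyr::bind_rows(
    ct_mix,
    tibble::tibble(modality = other, region = "all", share = 1)
  )
}

#' Default DLP-to-effective-dose conversion factors
#'
#' Region-specific factors k (mSv per mGy.cm) multiplying a CT dose length
#' product to give effective dose. Published conversion-factor tables are the
#' usual source in practice; the values shipped here are an illustrative
#' synthetic set in the range of adult body-region factors, keyed by the CT
#' region labels of [swiss_ct_regions_2018()], and should be replaced by the
#' user's preferred published table for real analyses.
#'
#' @return A named numeric vector, mSv per mGy.cm.
#' @export
default_conversion_factors <- function() {
  c(
    "head"              = 0.0021,
    "face and sinus"    = 0.0021,
    "dental CT"         = 0.0021,
    "neck"              = 0.0059,
    "chest"             = 0.0140,
    "abdomen"           = 0.0150,
    "chest and abdomen" = 0.0147,
    "pelvis"            = 0.0150,
    "spine"             = 0.0150,
    "shoulder"          = 0.0110,
    "elbow"             = 0.0080,
    "wrist and hand"    = 0.0080,
    "hip"               = 0.0150,
    "knee"              = 0.0080,
    "ankle and foot"    = 0.0008
  )
}

#' Default log-normal DLP models per CT region and facility stratum
#'
#' Median DLP (mGy.cm) and log-scale spread for each CT region, split by
#' facility stratum (university vs non-university). Pooled medians are chosen
#' so that median DLP times the default conversion factor reproduces the
#' published 2018 per-region median effective doses; university facilities
#' run slightly lower and non-university facilities slightly higher, with a
#' markedly larger split for chest CT where the published survey reports a
#' 2.9 vs 4.7 mSv difference.
#'
#' @param log_sd Log-scale standard deviation applied to every region
#'   (default 0.45, a typical spread for per-protocol DLP distributions).
#' @return A tibble with columns `region`, `stratum`, `median_dlp`, `log_sd`.
#' @export
default_dlp_models <- function(log_sd = 0.45) {
  ct <- swiss_ct_regions_2018()
  k <- default_conversion_factors()
  pooled <- ct$median_effective_dose_msv / unname(k[ct$region])
  uni_mult <- ifelse(ct$region == "chest", 2.9 / 3.8, 0.95)
  non_mult <- ifelse(ct$region == "chest", 4.7 / 3.8, 1.06)
  tibble::tibble(
    region     = rep(ct$region, 2),
    stratum    = rep(c("university", "nonuniversity"), each = nrow(ct)),
    median_dlp = c(pooled * uni_mult, pooled * non_mult),
    log_sd     = log_sd
  )
}

#' Default web-survey response rates per modality
#'
#' Response proportions of facility owners to the web/paper questionnaire,
#' as observed in the 2018 survey: 18.1% for diagnostic mammography, 29.1%
#' for dental radiography excluding CBCT, 27% for CBCT and 94.1% for nuclear
#' medicine.
#'
#' @return A named numeric vector of proportions in (0, 1].
#' @export
default_response_rates <- function() {
  c(
    "diagnostic mammography"            = 0.181,
    "dental radiography (without CBCT)" = 0.291,
    "CBCT"                              = 0.270,
    "nuclear medicine"                  = 0.941
  )
}

#' Default per-modality effective-dose vectors (non-CT, non-nuclear-medicine)
#'
#' Scalar effective-dose vectors (mSv per examination) for the modalities
#' whose doses come from national dose-survey compilations rather than from
#' dose-archive records, with a provenance note per entry. Values are the
#' published 2018 figures; CT and nuclear medicine are excluded because the
#' package computes them ([ct_dose_vector()], [nm_effective_dose()]).
#'
#' @return A tibble with columns `modality`, `dose_vector`, `provenance`.
#' @export
default_modality_doses <- function() {
  tbl <- swiss_modalities_2018()
  tbl <- tbl[!tbl$modality %in% c("CT", "nuclear medicine"), ]
  tibble::tibble(
    modality    = tbl$modality,
    dose_vector = tbl$dose_vector_msv,
    provenance  = "national dose-survey compilation (published 2018 figures)"
  )
}

#' Default nuclear-medicine procedure mix
#'
#' An illustrative four-procedure mix (bone scintigraphy, FDG PET-CT,
#' myocardial perfusion, thyroid scintigraphy) with administered activities
#' and dose coefficients in realistic ranges, including the CT component of
#' hybrid acquisitions (attenuation-correction map vs additional diagnostic
#' CT). Shares are calibrated so the share-weighted modality vector equals
#' the published 8.04 mSv; the published survey does not print its own
#' per-procedure breakdown, so this mix is illustrative, not observed.
#'
#' @return A tibble of procedures; see [nm_effective_dose()] for the columns.
#' @examples
#' nm_effective_dose(default_nm_procedures())
#' @export
default_nm_procedures <- function() {
  tibble::tibble(
    label = c(
      "bone scintigraphy (Tc-99m HDP)",
      "FDG PET-CT",
      "myocardial perfusion (Tc-99m, stress + rest)",
      "thyroid scintigraphy (Tc-99m pertechnetate)"
    ),
    activity_mbq     = c(700, 240, 1164, 80),
    dose_coefficient = c(0.0057, 0.019, 0.0079, 0.013),
    ct_component     = c("attenuation_map", "diagnostic", "attenuation_map", "none"),
    ct_dlp           = c(190, 450, 100, NA_real_),
    ct_k             = c(0.015, 0.015, 0.014, NA_real_),
    share            = c(0.35, 0.27, 0.23, 0.15)
  )
}
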