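ref_path <- function(file) {
  system.file("extdata", file, package = "radsurvey", mustWork = TRUE)
}

read_ref <- function(file) {
  readr::read_csv(ref_path(file), show_col_types = FALSE, progress = FALSE)
}

#' Published reference tables from the Swiss national exposure surveys
#'
#' Digitised summary tables from the published 2018 Swiss nationwide survey of
#' population exposure from medical imaging, plus the corresponding 2013
#' figures used for trend analysis. These are the printed survey outputs, not
#' raw data; the package uses them as worked-example inputs and as the prior
#' survey for [compare_surveys()].
#'
#' * `swiss_modalities_2018()`: per-modality frequency per 1000 inhabitants and
#'   effective-dose vector (mSv) for 2018.
#' * `swiss_ct_regions_2018()`: per-region CT frequency per 1000 inhabitants
#'   and pooled median effective dose (mSv).
#' * `swiss_survey_2013()`: per-modality frequency and dose per inhabitant from
#'   the 2013 survey (nuclear medicine was surveyed separately and is absent).
#' * `swiss_verification_2018()`: billing-derived versus RIS-derived
#'   frequencies per 1000 inhabitants for the modalities that were
#'   cross-checked.
#'
#' @return A tibble; see above for the columns of each table.
#' @examples
#' swiss_modalities_2018()
#' @export
swiss_modalities_2018 <- function() read_ref("swiss_modalities_2018.csv")

#' @rdname swiss_modalities_2018
#' @export
swiss_ct_regions_2018 <- function() read_ref("swiss_ct_regions_2018.csv")

#' @rdname swiss_modalities_2018
#' @export
swiss_survey_2013 <- function() read_ref("swiss_survey_2013.csv")

#' @rdname swiss_modalities_2018
#' @export
swiss_verification_2018 <- function() read_ref("swiss_verification_2018.csv")

#' Effective-dose estimates of the 2018 CT vector by facility stratum
#'
#' The 2018 survey re-estimated the CT dose vector restricting the dose data
#' to university hospitals only (6.73 mSv) or to non-university facilities
#' only (7.5 mSv); the spread between the two drives the published relative
#' uncertainty of about 8% (see [stratum_uncertainty()]).
#'
#' @return A named numeric vector of length two, in mSv.
#' @examples
#' stratum_uncertainty(swiss_ct_stratum_2018())
#' @export
swiss_ct_stratum_2018 <- function() {
  c(university = 6.73, nonuniversity = 7.5)
}
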