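check_nm_procedures <- function(procedures) {
  needed <- c("activity_mbq", "dose_coefficient", "ct_component", "ct_dlp",
              "ct_k", "share")
  if (!all(needed %in% names(procedures))) {
    abort(paste0("`procedures` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (any(procedures$activity_mbq < 0, na.rm = TRUE) ||
      any(procedures$dose_coefficient < 0, na.rm = TRUE)) {
    abort("administered activity and dose coefficient must be >= 0")
  }
  bad_ct <- procedures$ct_component != "none" &
    (!is.finite(procedures$ct_dlp) | !is.finite(procedures$ct_k))
  if (any(bad_ct)) {
    abort(paste0(
      "missing CT DLP or conversion factor for procedures with a CT component: ",
      paste(procedures$label[bad_ct], collapse = ", ")
    ))
  }
  if (abs(sum(procedures$share) - 1) > 1e-9) {
    abort("procedure shares must sum to 1")
  }
  invisible(procedures)
}

#' Per-procedure nuclear-medicine effective doses
#'
#' For each procedure the effective dose is the radiopharmaceutical part
#' (administered activity in MBq times the dose coefficient in mSv/MBq) plus,
#' for hybrid acquisitions, the CT part (DLP times the region conversion
#' factor) — whether the CT provides an attenuation-correction map or
#' additional diagnostic information only changes the configured DLP, not the
#' combination rule.
#'
#' @param procedures Tibble with columns `label`, `activity_mbq`,
#'   `dose_coefficient` (mSv/MBq), `ct_component` (`"none"`,
#'   `"attenuation_map"` or `"diagnostic"`), `ct_dlp` (mGy.cm), `ct_k`
#'   (mSv per mGy.cm), `share` (procedure mix shares summing to 1). See
#'   [default_nm_procedures()].
#' @return `nm_dose_breakdown()`: the input with columns
#'   `pharmaceutical_msv`, `ct_msv`, `effective_dose` and the share-weighted
#'   `contribution`. `nm_effective_dose()`: the modality dose vector in mSv
#'   (the share-weighted mean effective dose).
#' @examples
#' nm_effective_dose(default_nm_procedures())  # ~8.04 mSv
#' @export
nm_dose_breakdown <- function(procedures) {
  procedures <- check_nm_procedures(tibble::as_tibble(procedures))
  out <- procedures
  out$pharmaceutical_msv <- out$activity_mbq * out$dose_coefficient
  out$ct_msv <- ifelse(out$ct_component == "none", 0, out$ct_dlp * out$ct_k)
  out$effective_dose <- out$pharmaceutical_msv + out$ct_msv
  out$contribution <- out$share * out$effective_dose
  out
}

#' @rdname nm_dose_breakdown
#' @export
nm_effective_dose <- function(procedures) {
  sum(nm_dose_breakdown(procedures)$contribution)
}

#' Assemble the complete per-modality effective-dose table
#'
#' Joins the configured literature-derived dose vectors (radiography,
#' fluoroscopy, dental, interventional, ...) with the CT vector computed from
#' dose-archive records and the nuclear-medicine vector computed from the
#' procedure mix. Every configured value passes through bit-for-bit. If the
#' configured table itself contains a CT (or nuclear medicine) row, that
#' configured scalar wins over the computed value and the override is flagged
#' in `provenance`.
#'
#' @param modality_table Tibble with columns `modality`, `dose_vector` (mSv)
#'   and optionally `provenance`; see [default_modality_doses()]. Duplicated
#'   modalities are an error.
#' @param ct A [ct_dose_vector()] object or a scalar mSv value, or `NULL`.
#' @param nm Nuclear-medicine dose vector in mSv (e.g. from
#'   [nm_effective_dose()]), or `NULL`.
#' @param ct_label,nm_label Modality labels under which the computed vectors
#'   are filed.
#' @return A tibble `modality`, `dose_vector`, `provenance` with one row per
#'   modality.
#' @examples
#' assemble_dose_tables(default_modality_doses(),
#'                      ct = 7.08,
#'                      nm = nm_effective_dose(default_nm_procedures()))
#' @export
assemble_dose_tables <- function(modality_table, ct = NULL, nm = NULL,
                                 ct_label = "CT",
                                 nm_label = "nuclear medicine") {
  tbl <- tibble::as_tibble(modality_table)
  if (!all(c("modality", "dose_vector") %in% names(tbl))) {
    abort("`modality_table` needs columns `modality` and `dose_vector`")
  }
  if (anyDuplicated(tbl$modality)) {
    abort(paste0("duplicated modality in dose table: ",
                 paste(unique(tbl$modality[duplicated(tbl$modality)]),
                       collapse = ", ")))
  }
  if (any(tbl$dose_vector <= 0)) {
    abort("dose vectors must be > 0")
  }
  if (!"provenance" %in% names(tbl)) tbl$provenance <- "configured"

  add_computed <- function(tbl, label, value, origin) {
    if (is.null(value)) return(tbl)
    if (inherits(value, "ct_dose_vector")) value <- value$vector_msv
    if (label %in% tbl$modality) {
      i <- which(tbl$modality == label)
      tbl$provenance[i] <- paste0("configured override (computed ",
                                  origin, " value ",
                                  format(value, digits = 6), " mSv ignored)")
      return(tbl)
    }
    dplyr::bind_rows(tbl, tibble::tibble(modality = label,
                                         dose_vector = value,
                                         provenance = origin))
  }
  tbl <- add_computed(tbl, ct_label, ct, "CT dosimetry from DLP records")
  tbl <- add_computed(tbl, nm_label, nm, "nuclear-medicine procedure mix")
  tbl
}
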