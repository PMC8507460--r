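#' Define a CT merge rule
#'
#' A merge rule says that when one CT session (same patient, facility and
#' calendar date) contains examinations of every region in `components`, those
#' component examinations are counted as a single combined examination labelled
#' `merged`. Merging matters because combined acquisitions (typically chest
#' plus abdomen) are billed as several codes but constitute one examination
#' with its own, higher, effective dose.
#'
#' @param components Character vector of at least two region labels.
#' @param merged Label of the combined region; must not be a component.
#' @param modality Modality the rule applies to (merging is motivated by CT
#'   practice and defaults to `"CT"`).
#' @return A one-row tibble with a list-column `components`.
#' @examples
#' merge_rule(c("chest", "abdomen"), "chest and abdomen")
#' @export
merge_rule <- function(components, merged, modality = "CT") {
  if (length(components) < 2) {
    abort("a merge rule needs at least two component regions")
  }
  if (merged %in% components) {
    abort("the merged label must not be one of the components")
  }
  tibble::tibble(modality = modality, components = list(components),
                 merged = merged)
}

check_merge_rules <- function(merge_rules) {
  if (is.null(merge_rules) || nrow(merge_rules) == 0) return(invisible(NULL))
  keys <- purrr::map_chr(merge_rules$components,
                         ~ paste(sort(.x), collapse = "\r"))
  dup <- duplicated(paste(merge_rules$modality, keys))
  if (any(dup)) {
    abort(paste0("ambiguous merge rules: several rules share the component set {",
                 paste(merge_rules$components[[which(dup)[1]]], collapse = ", "),
                 "}"))
  }
  invisible(NULL)
}

#' Build examinations from invoice-level billing records
#'
#' Converts billed radiology acts into examinations — the survey's counting
#' unit: one or more exposures of an anatomical region with a single modality
#' during a single visit. A visit is taken as one (patient, facility, calendar
#' date) session. Invoice lines are mapped to (modality, region) through the
#' code map, grouped per session, and repeated codes collapse into one
#' examination (`n_source_codes` keeps the number of absorbed invoice lines).
#' Within a CT session, if every component region of a merge rule is present,
#' the components are replaced by one combined-region examination; rules are
#' applied greedily in order, each region being consumed at most once, so a
#' chest+abdomen+pelvis session under the default rule yields one combined
#' chest-and-abdomen examination plus a separate pelvis examination.
#'
#' @param invoices Tibble with columns `patient_id`, `facility_id`, `date`,
#'   `billing_code`.
#' @param code_map Tibble mapping `billing_code` to `modality` and `region`
#'   (each code maps to exactly one pair); see [default_code_map()].
#' @param merge_rules Tibble of [merge_rule()] rows, or `NULL` for no merging.
#' @param on_unmapped `"error"` (default) to fail listing unmapped codes, or
#'   `"drop"` to discard unmapped invoice lines with a warning.
#' @return A tibble of examinations: `patient_id`, `facility_id`, `date`,
#'   `modality`, `region`, `n_source_codes`, sorted by those keys.
#' @examples
#' inv <- tibble::tibble(
#'   patient_id = "P1", facility_id = "U01", date = as.Date("2018-03-01"),
#'   billing_code = c("CT.0004", "CT.0001")  # chest + abdomen, same session
#' )
#' build_examinations(inv, default_code_map())
#' @export
build_examinations <- function(invoices, code_map,
                               merge_rules = default_merge_rules(),
                               on_unmapped = c("error", "drop")) {
  on_unmapped <- match.arg(on_unmapped)
  needed <- c("patient_id", "facility_id", "date", "billing_code")
  if (!all(needed %in% names(invoices))) {
    abort(paste0("`invoices` needs columns: ", paste(needed, collapse = ", ")))
  }
  if (anyDuplicated(code_map$billing_code)) {
    abort("`code_map` maps some billing code to more than one (modality, region)")
  }
  check_merge_rules(merge_rules)

  mapped <- dplyr::left_join(invoices, code_map, by = "billing_code")
  unmapped <- unique(mapped$billing_code[is.na(mapped$modality)])
  if (length(unmapped) > 0) {
    if (on_unmapped == "error") {
      abort(paste0("unmapped billing codes: ",
                   paste(sort(unmapped), collapse = ", ")),
            class = "radsurvey_mapping_error")
    }
    warn(paste0("dropping ", sum(is.na(mapped$modality)),
                " invoice lines with unmapped codes"))
    mapped <- mapped[!is.na(mapped$modality), ]
  }

  exams <- mapped |>
    dplyr::count(.data$patient_id, .data$facility_id, .data$date,
                 .data$modality, .data$region, name = "n_source_codes")

  if (!is.null(merge_rules) && nrow(merge_rules) > 0) {
    for (i in seq_len(nrow(merge_rules))) {
      exams <- apply_merge_rule(exams,
                                modality = merge_rules$modality[[i]],
                                components = merge_rules$components[[i]],
                                merged = merge_rules$merged[[i]])
    }
  }

  dplyr::arrange(exams, .data$patient_id, .data$facility_id, .data$date,
                 .data$modality, .data$region)
}

# Replace, in every session holding all `components`, those component
# examinations by one merged examination. Vectorised over sessions.
apply_merge_rule <- function(exams, modality, components, merged) {
  rule_modality <- modality
  rule_merged <- merged
  cand <- exams$modality == rule_modality & exams$region %in% components
  if (!any(cand)) return(exams)
  hits <- exams[cand, ] |>
    dplyr::group_by(.data$patient_id, .data$facility_id, .data$date) |>
    dplyr::filter(dplyr::n_distinct(.data$region) == length(components)) |>
    dplyr::ungroup()
  if (nrow(hits) == 0) return(exams)
  merged_rows <- hits |>
    dplyr::group_by(.data$patient_id, .data$facility_id, .data$date) |>
    dplyr::summarise(modality = rule_modality, region = rule_merged,
                     n_source_codes = sum(.data$n_source_codes),
                     .groups = "drop")
  dplyr::bind_rows(dplyr::anti_join(
    exams, hits,
    by = c("patient_id", "facility_id", "date", "modality", "region")
  ), merged_rows)
}

#' Verify billing-derived examinations against a RIS reference
#'
#' Compares the examination counts obtained from billing codes with the
#' counts recorded in the radiology information system of the same
#' facilities, per modality and in total. The relative difference is anchored
#' on the billing-derived figure: `(billing - ris) / billing * 100`, reported
#' to two decimals.
#'
#' @param exams Tibble of examinations (needs a `modality` column), as from
#'   [build_examinations()].
#' @param ris Tibble of RIS examination rows (needs a `modality` column).
#' @param population If supplied, counts are converted to frequencies per
#'   1000 inhabitants before comparison (the comparison is scale-invariant;
#'   this only changes the reported unit).
#' @return A tibble `modality`, `billing`, `ris`, `difference_pct` with a
#'   final `Total` row computed on the summed frequencies. A modality with no
#'   billing-derived count gets `NA` as its difference.
#' @seealso [verification_summary()] for pre-aggregated frequencies.
#' @export
verify_against_ris <- function(exams, ris, population = NULL) {
  counts <- dplyr::full_join(
    dplyr::count(exams, .data$modality, name = "billing"),
    dplyr::count(ris, .data$modality, name = "ris"),
    by = "modality"
  )
  counts$billing[is.na(counts$billing)] <- 0
  counts$ris[is.na(counts$ris)] <- 0
  if (!is.null(population)) {
    counts$billing <- counts$billing / population * 1000
    counts$ris <- counts$ris / population * 1000
  }
  verification_summary(counts)
}

#' Verification table from pre-aggregated frequencies
#'
#' Adds the `Total` row (summed frequencies) and the relative difference
#' `(billing - ris) / billing * 100`, rounded to two decimals, to a
#' per-modality table of billing-derived and RIS frequencies.
#'
#' @param freq Tibble with columns `modality`, `billing`, `ris` (counts or
#'   frequencies per 1000; the difference is unit-free).
#' @return The input with a `Total` row appended and a `difference_pct`
#'   column; a zero billing figure yields `NA` rather than an error.
#' @examples
#' verification_summary(swiss_verification_2018())
#' @export
verification_summary <- function(freq) {
  if (!all(c("modality", "billing", "ris") %in% names(freq))) {
    abort("`freq` needs columns `modality`, `billing`, `ris`")
  }
  out <- dplyr::bind_rows(
    freq,
    tibble::tibble(modality = "Total", billing = sum(freq$billing),
                   ris = sum(freq$ris))
  )
  out$difference_pct <- ifelse(
    out$billing == 0, NA_real_,
    round((out$billing - out$ris) / out$billing * 100, 2)
  )
  out
}
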