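#' Combine frequencies and dose vectors into the survey headline result
#'
#' Computes, per modality, the annual effective dose per inhabitant
#' (frequency per 1000 x dose vector / 1000) and the contribution shares in
#' frequency and in dose; and, overall, the totals with and without nuclear
#' medicine and the number of examinations per inhabitant. Contribution
#' shares use the all-modality (nuclear-medicine-inclusive) totals as
#' denominator, so the shares of all rows sum to 100%.
#'
#' @param freq Frequency table: columns `modality` and `frequency` (or
#'   `frequency_per_1000`); `Total` rows are ignored. A table that also
#'   carries the dose-vector column — such as [swiss_modalities_2018()] —
#'   can be given alone.
#' @param doses Dose-vector table: columns `modality` and `dose_vector` (or
#'   `dose_vector_msv`), e.g. from [assemble_dose_tables()]. Defaults to
#'   `freq`. The modality sets must coincide.
#' @param year Optional survey year, carried into the result.
#' @param nm_label Modality label treated as nuclear medicine when forming
#'   the without-NM totals.
#' @return A `survey_result`: per-modality table (`tidy()`), totals
#'   (`glance()`), and a contribution chart (`autoplot()`).
#' @examples
#' res <- build_result(swiss_modalities_2018(), year = 2018)
#' glance(res)
#' @export
build_result <- function(freq, doses = freq, year = NULL,
                         nm_label = "nuclear medicine") {
  f_col <- pick_col(freq, c("frequency", "frequency_per_1000"), "frequency")
  d_col <- pick_col(doses, c("dose_vector", "dose_vector_msv"), "dose vector")
  f <- tibble::tibble(modality = freq$modality, frequency = freq[[f_col]])
  f <- f[!f$modality %in% "Total", ]
  d <- tibble::tibble(modality = doses$modality, dose_vector = doses[[d_col]])
  d <- d[!d$modality %in% "Total", ]
  if (anyDuplicated(f$modality) || anyDuplicated(d$modality)) {
    abort("modalities must be unique in both tables")
  }
  miss_d <- setdiff(f$modality, d$modality)
  miss_f <- setdiff(d$modality, f$modality)
  if (length(miss_d) > 0 || length(miss_f) > 0) {
    abort(paste0(
      "modality sets differ",
      if (length(miss_d)) paste0("; no dose vector for: ",
                                 paste(miss_d, collapse = ", ")),
      if (length(miss_f)) paste0("; no frequency for: ",
                                 paste(miss_f, collapse = ", "))
    ))
  }

  rows <- dplyr::left_join(f, d, by = "modality")
  rows$dose_per_inhabitant <- rows$frequency * rows$dose_vector / 1000
  freq_total <- sum(rows$frequency)
  dose_total <- sum(rows$dose_per_inhabitant)
  if (freq_total <= 0) abort("total frequency must be positive")
  rows$frequency_share_pct <- rows$frequency / freq_total * 100
  rows$dose_share_pct <- rows$dose_per_inhabitant / dose_total * 100

  is_nm <- rows$modality %in% nm_label
  totals <- tibble::tibble(
    frequency_with_nm = freq_total,
    frequency_without_nm = sum(rows$frequency[!is_nm]),
    dose_with_nm = dose_total,
    dose_without_nm = sum(rows$dose_per_inhabitant[!is_nm]),
    exams_per_inhabitant = freq_total / 1000
  )

  structure(list(year = year, modalities = rows, totals = totals,
                 nm_label = nm_label),
            class = "survey_result")
}

#' @export
print.survey_result <- function(x, ...) {
  cat("<survey_result",
      if (!is.null(x$year)) paste0(" ", x$year), ">\n", sep = "")
  cat(sprintf("  %d modalities; %.2f examinations per inhabitant\n",
              nrow(x$modalities), x$totals$exams_per_inhabitant))
  cat(sprintf("  dose per inhabitant: %.3f mSv (%.3f without %s)\n",
              x$totals$dose_with_nm, x$totals$dose_without_nm, x$nm_label))
  invisible(x)
}

#' @rdname build_result
#' @param x A `survey_result`.
#' @param ... Unused.
#' @export
tidy.survey_result <- function(x, ...) {
  x$modalities
}

#' @rdname build_result
#' @export
glance.survey_result <- function(x, ...) {
  out <- x$totals
  out$year <- x$year %||% NA_integer_
  dplyr::relocate(out, "year")
}

#' Pooled contribution share of a set of modalities
#'
#' Sums contribution shares across modalities: e.g. dental radiography and
#' CBCT are reported jointly as the dental share of all examinations.
#'
#' @param result A `survey_result` from [build_result()].
#' @param modalities Character vector of modality labels to pool.
#' @param type `"frequency"` or `"dose"` share.
#' @return A percentage of the all-modality total.
#' @examples
#' res <- build_result(swiss_modalities_2018())
#' share_of(res, c("dental radiography (without CBCT)", "CBCT"))
#' @export
share_of <- function(result, modalities, type = c("frequency", "dose")) {
  type <- match.arg(type)
  if (!inherits(result, "survey_result")) {
    abort("`result` must be a survey_result")
  }
  missing <- setdiff(modalities, result$modalities$modality)
  if (length(missing) > 0) {
    abort(paste0("unknown modality: ", paste(missing, collapse = ", ")))
  }
  col <- paste0(type, "_share_pct")
  sum(result$modalities[[col]][result$modalities$modality %in% modalities])
}

as_survey_table <- function(x, arg) {
  if (inherits(x, "survey_result")) {
    return(dplyr::select(x$modalities, "modality", "frequency",
                         "dose_per_inhabitant"))
  }
  f_col <- pick_col(x, c("frequency", "frequency_per_1000"), "frequency")
  d_col <- pick_col(x, c("dose_per_inhabitant", "dose_per_inhabitant_msv"),
                    "dose per inhabitant")
  out <- tibble::tibble(modality = x$modality, frequency = x[[f_col]],
                        dose_per_inhabitant = x[[d_col]])
  out[!out$modality %in% "Total", ]
}

pct_change <- function(new, old) {
  ifelse(is.na(old) | is.na(new) | old == 0, NA_real_,
         (new - old) / old * 100)
}

#' Compare two surveys: frequency and dose trends
#'
#' Per-modality percentage changes between an earlier and a later survey in
#' examination frequency, effective dose per inhabitant, and mean dose per
#' examination (dose per inhabitant / frequency x 1000). Changes are
#' anchored on the earlier survey. A modality present in only one survey is
#' kept with `NA` changes, never dropped silently. A final `Total` row gives
#' the overall changes, computed on modalities present in both surveys.
#'
#' @param old,new A `survey_result` or a tibble with columns `modality`,
#'   `frequency` (or `frequency_per_1000`) and `dose_per_inhabitant` (or
#'   `dose_per_inhabitant_msv`), e.g. [swiss_survey_2013()].
#' @return A `survey_trend` tibble with old/new values and
#'   `frequency_change_pct`, `dose_change_pct`, `dose_per_exam_change_pct`.
#' @examples
#' res18 <- build_result(swiss_modalities_2018())
#' trend <- compare_surveys(swiss_survey_2013(), res18)
#' trend[trend$modality == "CT", ]
#' @export
compare_surveys <- function(old, new) {
  o <- as_survey_table(old, "old")
  n <- as_survey_table(new, "new")
  both <- dplyr::full_join(o, n, by = "modality",
                           suffix = c("_old", "_new"))
  shared <- !is.na(both$frequency_old) & !is.na(both$frequency_new)
  totals <- tibble::tibble(
    modality = "Total",
    frequency_old = sum(both$frequency_old[shared]),
    dose_per_inhabitant_old = sum(both$dose_per_inhabitant_old[shared]),
    frequency_new = sum(both$frequency_new[shared]),
    dose_per_inhabitant_new = sum(both$dose_per_inhabitant_new[shared])
  )
  out <- dplyr::bind_rows(both, totals)
  out$dose_per_exam_old <- ifelse(out$frequency_old > 0,
    out$dose_per_inhabitant_old / out$frequency_old * 1000, NA_real_)
  out$dose_per_exam_new <- ifelse(out$frequency_new > 0,
    out$dose_per_inhabitant_new / out$frequency_new * 1000, NA_real_)
  out$frequency_change_pct <- pct_change(out$frequency_new, out$frequency_old)
  out$dose_change_pct <- pct_change(out$dose_per_inhabitant_new,
                                    out$dose_per_inhabitant_old)
  out$dose_per_exam_change_pct <- pct_change(out$dose_per_exam_new,
                                             out$dose_per_exam_old)
  class(out) <- c("survey_trend", class(out))
  out
}

#' Contribution chart for a survey result
#'
#' Paired horizontal bars of each modality's share of all examinations and
#' of the collective dose, the standard presentation of how infrequent,
#' high-dose modalities (CT above all) dominate population exposure.
#'
#' @param object A `survey_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.survey_result <- function(object, ...) {
  long <- tidyr::pivot_longer(
    object$modalities,
    cols = c("frequency_share_pct", "dose_share_pct"),
    names_to = "share_type", values_to = "share"
  )
  long$share_type <- ifelse(long$share_type == "frequency_share_pct",
                            "Frequency", "Dose")
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$modality, .data$share),
                               y = .data$share, fill = .data$share_type)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Share of total (%)", fill = NULL,
                  title = "Contribution of imaging modalities",
                  subtitle = "Share of examinations vs share of collective dose") +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.survey_result
#' @export
autoplot.survey_trend <- function(object, ...) {
  df <- object[object$modality != "Total" &
                 !is.na(object$frequency_change_pct), ]
  ggplot2::ggplot(df,
                  ggplot2::aes(x = stats::reorder(.data$modality,
                                                  .data$frequency_change_pct),
                               y = .data$frequency_change_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "Change in frequency (%)",
                  title = "Between-survey change in examination frequency") +
    ggplot2::theme_minimal()
}

round_cols <- function(tbl, digits) {
  for (col in names(digits)) {
    if (col %in% names(tbl)) tbl[[col]] <- round(tbl[[col]], digits[[col]])
  }
  tbl
}

#' Write the survey report to disk
#'
#' Renders the result tables as CSV files plus a JSON summary and a
#' contribution chart. All numbers are carried at full precision internally;
#' rounding to presentation precision happens only here.
#'
#' @param result A `survey_result`.
#' @param comparison Optional `survey_trend` from [compare_surveys()]; when
#'   omitted the trend section is omitted.
#' @param verification Optional verification table from
#'   [verify_against_ris()] / [verification_summary()].
#' @param dir Output directory (created if missing).
#' @param chart Write the contribution chart as PNG (default `TRUE`); if no
#'   graphics device is available the chart is skipped with a warning.
#' @return Invisibly, the paths written.
#' @export
render_report <- function(result, comparison = NULL, verification = NULL,
                          dir, chart = TRUE) {
  if (!inherits(result, "survey_result")) {
    abort("`result` must be a survey_result")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character()

  modalities <- dplyr::bind_rows(
    result$modalities,
    tibble::tibble(
      modality = c("Total (without nuclear medicine)",
                   "Total (with nuclear medicine)"),
      frequency = c(result$totals$frequency_without_nm,
                    result$totals$frequency_with_nm),
      dose_per_inhabitant = c(result$totals$dose_without_nm,
                              result$totals$dose_with_nm)
    )
  )
  modalities <- round_cols(modalities, c(
    frequency = 1, dose_vector = 2, dose_per_inhabitant = 3,
    frequency_share_pct = 2, dose_share_pct = 2
  ))
  paths["modalities"] <- file.path(dir, "modalities.csv")
  readr::write_csv(modalities, paths[["modalities"]], na = "", progress = FALSE)

  summary <- list(
    year = result$year,
    exams_per_inhabitant = result$totals$exams_per_inhabitant,
    dose_per_inhabitant_msv = result$totals$dose_with_nm,
    dose_per_inhabitant_without_nm_msv = result$totals$dose_without_nm,
    frequency_per_1000 = result$totals$frequency_with_nm,
    frequency_per_1000_without_nm = result$totals$frequency_without_nm
  )
  paths["summary"] <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, paths[["summary"]], auto_unbox = TRUE,
                       digits = NA, null = "null")

  if (!is.null(comparison)) {
    trend <- round_cols(tibble::as_tibble(comparison), c(
      frequency_change_pct = 1, dose_change_pct = 1,
      dose_per_exam_change_pct = 1, dose_per_exam_old = 3,
      dose_per_exam_new = 3
    ))
    paths["trend"] <- file.path(dir, "trend.csv")
    readr::write_csv(trend, paths[["trend"]], na = "", progress = FALSE)
  }
  if (!is.null(verification)) {
    paths["verification"] <- file.path(dir, "verification.csv")
    readr::write_csv(verification, paths[["verification"]], na = "",
                     progress = FALSE)
  }
  if (chart) {
    paths["chart"] <- file.path(dir, "contributions.png")
    ok <- tryCatch({
      ggplot2::ggsave(paths[["chart"]], autoplot(result),
                      width = 8, height = 5, dpi = 150)
      TRUE
    }, error = function(e) {
      warn(paste0("could not write chart: ", conditionMessage(e)))
      FALSE
    })
    if (!ok) paths <- paths[names(paths) != "chart"]
  }
  invisible(paths)
}
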