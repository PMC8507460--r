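#' Coverage model for extrapolating billing counts to the national level
#'
#' Billing extracts cover only part of the population. Two extrapolation
#' modes are supported: plain population scaling (divide observed counts by
#' the covered population fraction) and activity-ratio scaling (divide by the
#' ratio of the covered region's share of general medical activity, under the
#' hypothesis that the indication for radiological examinations is homogeneous
#' across the country). In the 2018 Swiss survey the covered canton held
#' 10.7% of the population but 10.1% of the medical activity, so the
#' activity-ratio estimate exceeds the population-scaled one by 0.107/0.101.
#' The activity-ratio factor is an exogenous input: its derivation requires
#' general-consultation volumes that are not part of this pipeline.
#'
#' @param population_total National population (inhabitants).
#' @param covered_fraction Covered share of the population, in (0, 1].
#' @param activity_ratio_factor Covered share of general medical activity, in
#'   (0, 1]; defaults to `covered_fraction` (making the two modes coincide).
#' @param mode Which factor divides the observed counts:
#'   `"activity_ratio"` or `"population_scaling"`.
#' @return A `coverage_model` object.
#' @examples
#' coverage_model(8.5e6, covered_fraction = 0.107,
#'                activity_ratio_factor = 0.101)
#' @export
coverage_model <- function(population_total,
                           covered_fraction,
                           activity_ratio_factor = covered_fraction,
                           mode = c("activity_ratio", "population_scaling")) {
  mode <- match.arg(mode)
  if (!is.numeric(population_total) || population_total <= 0) {
    abort_config("population_total", "must be a positive number of inhabitants")
  }
  for (f in c("covered_fraction", "activity_ratio_factor")) {
    v <- get(f)
    if (!is.numeric(v) || length(v) != 1 || v <= 0 || v > 1) {
      abort_config(f, "must be a proportion in (0, 1]")
    }
  }
  structure(
    list(population_total = population_total,
         covered_fraction = covered_fraction,
         activity_ratio_factor = activity_ratio_factor,
         mode = mode),
    class = "coverage_model"
  )
}

#' Extrapolate observed billing counts to national counts
#'
#' Divides observed counts by the coverage factor selected by the model's
#' mode. Both estimates are kept side by side so the sensitivity of the
#' result to the extrapolation hypothesis stays visible.
#'
#' @param counts Tibble with a `count` column (plus any identifying columns
#'   such as `modality` and `region`, which pass through).
#' @param coverage A [coverage_model()].
#' @return The input tibble with columns `national_population_scaling`,
#'   `national_activity_ratio` and `national` (the mode's choice).
#' @examples
#' cov <- coverage_model(1e6, 0.107, 0.101)
#' extrapolate_billing(tibble::tibble(modality = "CT", count = 1070), cov)
#' @export
extrapolate_billing <- function(counts, coverage) {
  if (!inherits(coverage, "coverage_model")) {
    abort("`coverage` must be created by coverage_model()")
  }
  if (!"count" %in% names(counts)) abort("`counts` needs a `count` column")
  if (any(counts$count < 0)) abort("counts must be >= 0")
  out <- tibble::as_tibble(counts)
  out$national_population_scaling <- out$count / coverage$covered_fraction
  out$national_activity_ratio <- out$count / coverage$activity_ratio_factor
  out$national <- switch(coverage$mode,
    population_scaling = out$national_population_scaling,
    activity_ratio = out$national_activity_ratio
  )
  out
}

#' Extrapolate survey-channel counts through response rates
#'
#' For modalities collected by questionnaire rather than billing extracts,
#' the national count is the count reported by responding facilities divided
#' by the modality's response rate.
#'
#' @param counts Tibble with columns `modality` and `count` (counts summed
#'   over responding facilities).
#' @param rates Response rates per modality: a named vector or a tibble with
#'   columns `modality`, `rate`; see [default_response_rates()].
#' @return The input tibble with a `national` column.
#' @examples
#' extrapolate_survey(tibble::tibble(modality = "nuclear medicine", count = 941),
#'                    c("nuclear medicine" = 0.941))
#' @export
extrapolate_survey <- function(counts, rates) {
  rates <- as_named_rates(rates, "modality", "rate", "rates")
  if (any(rates <= 0 | rates > 1)) {
    abort("response rates must be proportions in (0, 1]")
  }
  missing <- setdiff(unique(counts$modality), names(rates))
  if (length(missing) > 0) {
    abort(paste0("no response rate for modality: ",
                 paste(missing, collapse = ", ")))
  }
  out <- tibble::as_tibble(counts)
  out$national <- out$count / unname(rates[out$modality])
  out
}

#' Convert national counts to frequencies per 1000 inhabitants
#'
#' @param counts Tibble with a `national` column (and identifying columns).
#' @param population_total National population.
#' @param total Append a `Total` row holding the summed frequency
#'   (default `TRUE`).
#' @return A frequency table: the input plus `frequency` (per 1000
#'   inhabitants per year) and, if requested, a final `Total` row.
#' @examples
#' per_1000(tibble::tibble(modality = "CT", national = 135000), 1e6)
#' @export
per_1000 <- function(counts, population_total, total = TRUE) {
  if (!is.numeric(population_total) || population_total <= 0) {
    abort("`population_total` must be positive")
  }
  if (!"national" %in% names(counts)) {
    abort("`counts` needs a `national` column")
  }
  out <- tibble::as_tibble(counts)
  out$frequency <- out$national / population_total * 1000
  if (total) {
    tot <- tibble::tibble(national = sum(out$national),
                          frequency = sum(out$frequency))
    if ("modality" %in% names(out)) tot$modality <- "Total"
    out <- dplyr::bind_rows(out, tot)
  }
  out
}

#' Combine frequency estimates from several sources
#'
#' National surveys assemble frequencies from heterogeneous channels —
#' billing extracts, medical-society reports, web surveys. When a modality is
#' estimated by more than one channel, the configured precedence names the
#' authoritative source.
#'
#' @param ... Named tibbles, each with columns `modality` and `frequency`;
#'   the argument names become the `source` column.
#' @param precedence Character vector of source names, most authoritative
#'   first. Defaults to the order the sources are given in.
#' @return A tibble `modality`, `frequency`, `source` with one row per
#'   modality.
#' @examples
#' combine_frequencies(
#'   billing = tibble::tibble(modality = "CT", frequency = 135),
#'   web_survey = tibble::tibble(modality = c("CT", "nuclear medicine"),
#'                               frequency = c(120, 13.3))
#' )
#' @export
combine_frequencies <- function(..., precedence = NULL) {
  sources <- rlang::list2(...)
  if (length(sources) == 0 || is.null(names(sources)) ||
      any(names(sources) == "")) {
    abort("give each frequency table as a named argument")
  }
  precedence <- precedence %||% names(sources)
  stacked <- purrr::imap_dfr(sources, function(tbl, src) {
    tibble::tibble(modality = tbl$modality, frequency = tbl$frequency,
                   source = src)
  })
  stacked$priority <- match(stacked$source, precedence)
  if (anyNA(stacked$priority)) {
    abort("`precedence` must cover every source name")
  }
  stacked |>
    dplyr::arrange(.data$priority) |>
    dplyr::distinct(.data$modality, .keep_all = TRUE) |>
    dplyr::select("modality", "frequency", "source") |>
    dplyr::arrange(.data$modality)
}
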