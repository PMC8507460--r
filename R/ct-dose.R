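#' Summarise DLP dose-archive records per CT region
#'
#' Computes the median dose length product (DLP) per anatomical region —
#' pooled over all records and separately per facility stratum — and converts
#' medians to effective dose with region-specific conversion factors
#' (effective dose = k x median DLP, exactly). The median of an even number
#' of records is the mean of the two central order statistics.
#'
#' @param records Tibble of dose records with columns `region`, `dlp_mgycm`
#'   (mGy.cm, finite and >= 0) and optionally `stratum` (e.g. university vs
#'   nonuniversity practice).
#' @param k Conversion factors in mSv per mGy.cm: named vector or tibble with
#'   columns `region`, `k`. If `NULL`, only DLP medians are returned. A region
#'   present in `records` but absent from `k` is an error.
#' @return A tibble with one row per region: `n_records`, `median_dlp`,
#'   `effective_dose` (if `k` given), plus `median_dlp_<stratum>` /
#'   `effective_dose_<stratum>` columns when `records` has strata.
#' @examples
#' recs <- tibble::tibble(region = "head", dlp_mgycm = c(100, 200, 300),
#'                        stratum = "university")
#' summarize_dlp(recs, c(head = 0.0021))
#' @export
summarize_dlp <- function(records, k = NULL) {
  if (!all(c("region", "dlp_mgycm") %in% names(records))) {
    abort("`records` needs columns `region` and `dlp_mgycm`")
  }
  if (nrow(records) == 0) abort("`records` is empty")
  if (any(!is.finite(records$dlp_mgycm)) || any(records$dlp_mgycm < 0)) {
    abort("`dlp_mgycm` must be finite and >= 0")
  }
  if (!is.null(k)) {
    k <- as_named_rates(k, "region", "k", "k")
    missing_k <- setdiff(unique(records$region), names(k))
    if (length(missing_k) > 0) {
      abort(paste0("no conversion factor for region: ",
                   paste(sort(missing_k), collapse = ", ")))
    }
    if (any(k[unique(records$region)] <= 0)) {
      abort("conversion factors must be > 0")
    }
  }

  pooled <- records |>
    dplyr::group_by(.data$region) |>
    dplyr::summarise(n_records = dplyr::n(),
                     median_dlp = median(.data$dlp_mgycm), .groups = "drop")

  out <- pooled
  if ("stratum" %in% names(records)) {
    by_str <- records |>
      dplyr::group_by(.data$region, .data$stratum) |>
      dplyr::summarise(median_dlp = median(.data$dlp_mgycm),
                       .groups = "drop") |>
      tidyr::pivot_wider(names_from = "stratum", values_from = "median_dlp",
                         names_prefix = "median_dlp_")
    out <- dplyr::left_join(out, by_str, by = "region")
  }
  if (!is.null(k)) {
    for (col in grep("^median_dlp", names(out), value = TRUE)) {
      e_col <- sub("^median_dlp", "effective_dose", col)
      out[[e_col]] <- unname(k[out$region]) * out[[col]]
    }
  }
  dplyr::arrange(out, .data$region)
}

pick_col <- function(tbl, candidates, what) {
  hit <- intersect(candidates, names(tbl))
  if (length(hit) == 0) {
    abort(paste0(what, " column not found (looked for: ",
                 paste(candidates, collapse = ", "), ")"))
  }
  hit[[1]]
}

#' Frequency-weighted CT effective-dose vector
#'
#' Combines the per-region effective doses with the per-region examination
#' frequencies into the CT dose vector: `sum_r share(r) * E(r)` with
#' `share(r) = frequency(r) / sum frequencies`. When the dose summaries carry
#' per-stratum effective doses, the vector is also evaluated per stratum and
#' the relative uncertainty is the sample standard deviation of the stratum
#' vectors divided by their mean (see [stratum_uncertainty()]).
#'
#' @param summaries Per-region dose summaries, as from [summarize_dlp()]
#'   (columns `region` and `effective_dose`, with optional
#'   `effective_dose_<stratum>` columns), or any table with `region` and a
#'   `median_effective_dose_msv` column such as [swiss_ct_regions_2018()].
#' @param frequencies Tibble with `region` and `frequency` (or
#'   `frequency_per_1000`); rows named `Total` are ignored. The region sets
#'   of `summaries` and `frequencies` must coincide.
#' @return A `ct_dose_vector` object: per-region table (frequency, share,
#'   effective dose, dose contribution), the vector value in mSv, per-stratum
#'   vector values and their relative uncertainty. Methods: [tidy()],
#'   [glance()], `print()`.
#' @examples
#' ct <- swiss_ct_regions_2018()
#' ct_dose_vector(ct, ct)  # the published per-region table carries both parts
#' @export
ct_dose_vector <- function(summaries, frequencies) {
  e_col <- pick_col(summaries, c("effective_dose", "median_effective_dose_msv"),
                    "effective dose")
  f_col <- pick_col(frequencies, c("frequency", "frequency_per_1000"),
                    "frequency")
  freq <- tibble::tibble(region = frequencies$region,
                         frequency = frequencies[[f_col]])
  freq <- freq[freq$region != "Total", ]
  if (anyDuplicated(freq$region) || anyDuplicated(summaries$region)) {
    abort("regions must be unique in both tables")
  }
  missing_e <- setdiff(freq$region, summaries$region)
  extra_e <- setdiff(summaries$region, freq$region)
  if (length(missing_e) > 0 || length(extra_e) > 0) {
    abort(paste0(
      "region sets differ between frequencies and dose summaries",
      if (length(missing_e)) paste0("; no dose for: ",
                                    paste(missing_e, collapse = ", ")),
      if (length(extra_e)) paste0("; no frequency for: ",
                                  paste(extra_e, collapse = ", "))
    ))
  }
  if (sum(freq$frequency) <= 0) abort("total frequency must be positive")

  regions <- dplyr::left_join(freq, summaries, by = "region")
  regions$share <- regions$frequency / sum(regions$frequency)
  regions$effective_dose <- regions[[e_col]]
  regions$contribution <- regions$share * regions$effective_dose

  stratum_cols <- grep("^effective_dose_", names(summaries), value = TRUE)
  stratum_msv <- purrr::map_dbl(stratum_cols, function(col) {
    if (anyNA(regions[[col]])) NA_real_ else sum(regions$share * regions[[col]])
  })
  names(stratum_msv) <- sub("^effective_dose_", "", stratum_cols)
  stratum_msv <- stratum_msv[!is.na(stratum_msv)]

  structure(
    list(
      regions = dplyr::select(regions, "region", "frequency", "share",
                              "effective_dose", "contribution"),
      vector_msv = sum(regions$contribution),
      stratum_msv = stratum_msv,
      relative_uncertainty = stratum_uncertainty(stratum_msv)
    ),
    class = "ct_dose_vector"
  )
}

#' Relative uncertainty from stratum-level estimates
#'
#' The spread between estimates computed on different facility strata (for
#' instance, restricting the dose data to university hospitals versus
#' non-university facilities) quantifies the sensitivity of the dose vector
#' to practice differences: the relative uncertainty is the sample standard
#' deviation (n - 1 denominator) of the stratum estimates divided by their
#' mean.
#'
#' @param values Numeric vector of stratum-level estimates (mSv).
#' @return A proportion; `NA` when fewer than two stratum values are
#'   available (the spread is then undefined, not zero).
#' @examples
#' stratum_uncertainty(c(6.73, 7.5))  # ~0.0765, i.e. about 8%
#' @export
stratum_uncertainty <- function(values) {
  values <- values[!is.na(values)]
  if (length(values) < 2) return(NA_real_)
  sd(values) / mean(values)
}

#' @export
print.ct_dose_vector <- function(x, ...) {
  cat("<ct_dose_vector>\n")
  cat(sprintf("  dose vector: %.2f mSv over %d regions\n",
              x$vector_msv, nrow(x$regions)))
  if (length(x$stratum_msv) > 0) {
    cat("  by stratum: ",
        paste(sprintf("%s %.2f", names(x$stratum_msv), x$stratum_msv),
              collapse = ", "), "\n")
  }
  if (!is.na(x$relative_uncertainty)) {
    cat(sprintf("  relative uncertainty: %.1f%%\n",
                100 * x$relative_uncertainty))
  }
  invisible(x)
}

#' @rdname ct_dose_vector
#' @param x A `ct_dose_vector`.
#' @param ... Unused.
#' @export
tidy.ct_dose_vector <- function(x, ...) {
  x$regions
}

#' @rdname ct_dose_vector
#' @export
glance.ct_dose_vector <- function(x, ...) {
  out <- tibble::tibble(
    vector_msv = x$vector_msv,
    relative_uncertainty = x$relative_uncertainty,
    n_regions = nrow(x$regions)
  )
  for (s in names(x$stratum_msv)) {
    out[[paste0("vector_", s, "_msv")]] <- x$stratum_msv[[s]]
  }
  out
}
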