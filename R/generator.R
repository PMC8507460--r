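#' Configuration for the synthetic survey-data generator
#'
#' Bundles every parameter the generator needs to emulate the data landscape
#' of a national imaging-exposure survey: invoice-level billing extracts for
#' the modalities covered by a tariff system, a radiology-information-system
#' (RIS) reference with a controlled discrepancy rate, dose-archive (DACS)
#' DLP records per CT region and facility stratum, and per-facility web-survey
#' responses for the modalities outside the billing extract.
#'
#' Defaults reproduce the structure of the 2018 Swiss survey: the published
#' per-modality frequencies as ground truth, a 10.7% billing coverage, the
#' published web-survey response rates, and a 16.4% share of CT sessions that
#' combine chest and abdomen acquisitions (billed as two codes, counted as one
#' combined examination downstream). Population size is an explicit parameter
#' (defaulting to 8.5 million inhabitants) because per-1000 frequencies only
#' acquire meaning relative to a stated denominator.
#'
#' @param seed Integer seed; the whole bundle is reproducible given
#'   `seed` + configuration.
#' @param population_size Number of inhabitants the frequencies refer to.
#' @param coverage_fraction Proportion of the population whose facilities
#'   appear in the billing extract (in (0, 1]).
#' @param facility_strata Tibble with columns `stratum`, `n_facilities`,
#'   `volume_share`; volume shares must sum to 1.
#' @param modality_frequencies Named vector: true examinations per 1000
#'   inhabitants per year, per modality.
#' @param region_mix Tibble `modality`, `region`, `share`; shares sum to 1
#'   within each modality. For CT the combined "chest and abdomen" label must
#'   not appear here: combined sessions are governed by `combined_ct_rate`.
#' @param dlp_models Tibble `region`, `stratum`, `median_dlp`, `log_sd`:
#'   log-normal DLP model per CT region and facility stratum (medians in
#'   mGy.cm are exact distribution parameters).
#' @param response_rates Named vector of web-survey response probabilities per
#'   modality; these modalities are reported through the survey channel.
#' @param billing_modalities Modalities present in the billing extract.
#' @param ris_discrepancy_rate Probability that an examination is perturbed in
#'   the RIS relative to the billing-derived truth.
#' @param ris_deletion_share Among perturbed examinations, the share deleted
#'   from the RIS (the rest are duplicated). Default 0.5 (symmetric).
#' @param combined_ct_rate Probability that a CT session is a combined
#'   chest-plus-abdomen acquisition (two invoice codes, one examination).
#' @param n_dose_records DACS records generated per (region, stratum) cell.
#'
#' @return An object of class `generator_config` (a validated list).
#' @seealso [simulate_survey_data()]
#' @examples
#' cfg <- generator_config(seed = 7, population_size = 1e5)
#' cfg$modality_frequencies[["CT"]]
#' @export
generator_config <- function(seed = 1L,
                             population_size = 8.5e6,
                             coverage_fraction = 0.107,
                             facility_strata = default_facility_strata(),
                             modality_frequencies = default_modality_frequencies(),
                             region_mix = default_region_mix(),
                             dlp_models = default_dlp_models(),
                             response_rates = default_response_rates(),
                             billing_modalities = c(
                               "CT", "conventional radiography",
                               "diagnostic mammography",
                               "conventional radioscopy",
                               "coronary angioplasty",
                               "other diagnostic interventional",
                               "PTCA", "other therapeutic interventional"
                             ),
                             ris_discrepancy_rate = 0.08,
                             ris_deletion_share = 0.5,
                             combined_ct_rate = 0.164,
                             n_dose_records = 300L) {
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed)) {
    abort_config("seed", "must be a single integer")
  }
  if (!is.numeric(population_size) || population_size <= 0) {
    abort_config("population_size", "must be a positive count of inhabitants")
  }
  if (!is.numeric(coverage_fraction) || coverage_fraction <= 0 || coverage_fraction > 1) {
    abort_config("coverage_fraction", "must be a proportion in (0, 1]")
  }
  facility_strata <- tibble::as_tibble(facility_strata)
  if (!all(c("stratum", "n_facilities", "volume_share") %in% names(facility_strata))) {
    abort_config("facility_strata",
                 "needs columns `stratum`, `n_facilities`, `volume_share`")
  }
  if (abs(sum(facility_strata$volume_share) - 1) > 1e-9) {
    abort_config("facility_strata", "volume shares must sum to 1")
  }
  if (any(facility_strata$n_facilities < 1)) {
    abort_config("facility_strata", "each stratum needs at least one facility")
  }
  modality_frequencies <- as_named_rates(modality_frequencies, "modality",
                                         "frequency", "modality_frequencies")
  if (any(modality_frequencies < 0)) {
    abort_config("modality_frequencies", "frequencies must be >= 0")
  }
  region_mix <- tibble::as_tibble(region_mix)
  if (!all(c("modality", "region", "share") %in% names(region_mix))) {
    abort_config("region_mix", "needs columns `modality`, `region`, `share`")
  }
  sums <- tapply(region_mix$share, region_mix$modality, sum)
  if (any(abs(sums - 1) > 1e-9)) {
    abort_config("region_mix", paste0(
      "shares must sum to 1 per modality; off for: ",
      paste(names(sums)[abs(sums - 1) > 1e-9], collapse = ", ")
    ))
  }
  dlp_models <- tibble::as_tibble(dlp_models)
  if (!all(c("region", "stratum", "median_dlp", "log_sd") %in% names(dlp_models))) {
    abort_config("dlp_models",
                 "needs columns `region`, `stratum`, `median_dlp`, `log_sd`")
  }
  if (any(dlp_models$median_dlp <= 0) || any(dlp_models$log_sd < 0)) {
    abort_config("dlp_models", "median_dlp must be > 0 and log_sd >= 0")
  }
  response_rates <- as_named_rates(response_rates, "modality", "rate",
                                   "response_rates")
  if (any(response_rates <= 0 | response_rates > 1)) {
    abort_config("response_rates", "rates must be proportions in (0, 1]")
  }
  missing_freq <- setdiff(c(billing_modalities, names(response_rates)),
                          names(modality_frequencies))
  if (length(missing_freq) > 0) {
    abort_config("modality_frequencies", paste0(
      "no frequency configured for: ", paste(missing_freq, collapse = ", ")
    ))
  }
  check_prob(ris_discrepancy_rate, "ris_discrepancy_rate")
  check_prob(ris_deletion_share, "ris_deletion_share")
  check_prob(combined_ct_rate, "combined_ct_rate")
  if (!is.numeric(n_dose_records) || length(n_dose_records) != 1 ||
      n_dose_records < 0) {
    abort_config("n_dose_records", "must be a single count >= 0")
  }

  structure(
    list(
      seed = as.integer(seed),
      population_size = population_size,
      coverage_fraction = coverage_fraction,
      facility_strata = facility_strata,
      modality_frequencies = modality_frequencies,
      region_mix = region_mix,
      dlp_models = dlp_models,
      response_rates = response_rates,
      billing_modalities = billing_modalities,
      ris_discrepancy_rate = ris_discrepancy_rate,
      ris_deletion_share = ris_deletion_share,
      combined_ct_rate = combined_ct_rate,
      n_dose_records = as.integer(n_dose_records)
    ),
    class = "generator_config"
  )
}

# Facility panel: one row per facility with its share of national volume.
facility_panel <- function(strata) {
  purrr::pmap_dfr(strata, function(stratum, n_facilities, volume_share) {
    tibble::tibble(
      facility_id = sprintf("%s%02d", toupper(substr(stratum, 1, 1)),
                            seq_len(n_facilities)),
      stratum = stratum,
      facility_share = volume_share / n_facilities
    )
  })
}

#' Generate a synthetic survey-data bundle
#'
#' Draws a full set of synthetic survey sources under the statistical model
#' the downstream analysis assumes: per-facility examination counts are
#' independent Poisson realizations of frequency x population / 1000 (scaled
#' by billing coverage), regions are multinomial within modality, a configured
#' share of CT sessions carries both a chest and an abdomen code, DLPs are
#' log-normal per (region, stratum), the RIS mirrors the billing-derived
#' examinations up to a configured discrepancy rate (half deletions, half
#' duplications by default), and web-survey responses are per-facility
#' Bernoulli draws at the configured response rates.
#'
#' Bundles are bit-for-bit reproducible for a fixed configuration: one base
#' seed, with per-table sub-streams derived deterministically, and the
#' caller's RNG state is left untouched.
#'
#' @param config A [generator_config()].
#' @return A `survey_bundle`: a list with tibbles `invoices` (patient_id,
#'   facility_id, date, billing_code), `ris` (patient_id, facility_id, date,
#'   modality, region), `dacs` (exam_id, region, dlp_mgycm, stratum), `survey`
#'   (facility_id, modality, count, responded), `facilities`, and `truth` (the
#'   configuration used).
#' @examples
#' cfg <- generator_config(seed = 42, population_size = 5e4,
#'                         coverage_fraction = 1, n_dose_records = 50)
#' bundle <- simulate_survey_data(cfg)
#' dplyr::count(bundle$ris, modality)
#' @export
simulate_survey_data <- function(config) {
  if (!inherits(config, "generator_config")) {
    abort("`config` must be created by generator_config()")
  }
  facilities <- facility_panel(config$facility_strata)
  pop <- config$population_size
  dates <- seq(as.Date("2018-01-01"), as.Date("2018-12-31"), by = "day")
  code_map <- default_code_map()

  # --- examinations underlying the billing extract ----------------------
  exams <- with_preserved_seed(substream_seed(config$seed, 1L), {
    purrr::map_dfr(config$billing_modalities, function(m) {
      lambda <- config$modality_frequencies[[m]] / 1000 * pop *
        config$coverage_fraction
      n_fac <- rpois(nrow(facilities), lambda * facilities$facility_share)
      n <- sum(n_fac)
      if (n == 0) {
        return(tibble::tibble(
          patient_id = character(), facility_id = character(),
          date = as.Date(character()), modality = character(),
          region = character(), combined = logical()
        ))
      }
      mix <- config$region_mix[config$region_mix$modality == m, ]
      combined <- if (m == "CT") runif(n) < config$combined_ct_rate
                  else rep(FALSE, n)
      region <- character(n)
      region[combined] <- "chest and abdomen"
      if (any(!combined)) {
        region[!combined] <- sample(mix$region, sum(!combined),
                                    replace = TRUE, prob = mix$share)
      }
      pool <- max(1000L, as.integer(3 * n))
      tibble::tibble(
        patient_id = sprintf("P%08d", sample.int(pool, n, replace = TRUE)),
        facility_id = rep(facilities$facility_id, n_fac),
        date = sample(dates, n, replace = TRUE),
        modality = m,
        region = region,
        combined = combined
      )
    })
  })
  # identical draws within one session are one examination by definition
  exams <- dplyr::distinct(exams)

  # --- invoices: combined CT sessions emit one code per component -------
  code_of <- setNames(code_map$billing_code,
                      paste(code_map$modality, code_map$region, sep = "\r"))
  simple <- exams[!exams$combined, ]
  comb <- exams[exams$combined, ]
  invoices <- dplyr::bind_rows(
    tibble::tibble(
      patient_id = simple$patient_id, facility_id = simple$facility_id,
      date = simple$date,
      billing_code = unname(code_of[paste(simple$modality, simple$region,
                                          sep = "\r")])
    ),
    purrr::map_dfr(c("chest", "abdomen"), function(part) {
      tibble::tibble(
        patient_id = comb$patient_id, facility_id = comb$facility_id,
        date = comb$date,
        billing_code = rep(unname(code_of[paste("CT", part, sep = "\r")]),
                           nrow(comb))
      )
    })
  )
  invoices <- dplyr::arrange(invoices, .data$patient_id, .data$facility_id,
                             .data$date, .data$billing_code)

  # --- RIS: the true examinations, perturbed at the discrepancy rate ----
  ris <- dplyr::select(exams, "patient_id", "facility_id", "date",
                       "modality", "region")
  ris <- with_preserved_seed(substream_seed(config$seed, 2L), {
    if (config$ris_discrepancy_rate > 0 && nrow(ris) > 0) {
      hit <- runif(nrow(ris)) < config$ris_discrepancy_rate
      drop <- hit & (runif(nrow(ris)) < config$ris_deletion_share)
      dup <- hit & !drop
      dplyr::bind_rows(ris[!drop, ], ris[dup, ])
    } else {
      ris
    }
  })
  ris <- dplyr::arrange(ris, .data$patient_id, .data$facility_id, .data$date,
                        .data$modality, .data$region)

  # --- DACS DLP records -------------------------------------------------
  dacs <- with_preserved_seed(substream_seed(config$seed, 3L), {
    n <- config$n_dose_records
    if (n == 0 || nrow(config$dlp_models) == 0) {
      tibble::tibble(exam_id = character(), region = character(),
                     dlp_mgycm = numeric(), stratum = character())
    } else {
      recs <- purrr::pmap_dfr(config$dlp_models,
        function(region, stratum, median_dlp, log_sd) {
          tibble::tibble(
            region = region, stratum = stratum,
            dlp_mgycm = rlnorm(n, meanlog = log(median_dlp), sdlog = log_sd)
          )
        })
      recs$exam_id <- sprintf("DX%07d", seq_len(nrow(recs)))
      dplyr::select(recs, "exam_id", "region", "dlp_mgycm", "stratum")
    }
  })

  # --- web-survey responses (full population, all facilities asked) -----
  survey <- with_preserved_seed(substream_seed(config$seed, 4L), {
    purrr::map_dfr(names(config$response_rates), function(m) {
      lambda <- config$modality_frequencies[[m]] / 1000 * pop
      tibble::tibble(
        facility_id = facilities$facility_id,
        modality = m,
        count = rpois(nrow(facilities), lambda * facilities$facility_share),
        responded = runif(nrow(facilities)) < config$response_rates[[m]]
      )
    })
  })

  structure(
    list(invoices = invoices, ris = ris, dacs = dacs, survey = survey,
         facilities = facilities, truth = config),
    class = "survey_bundle"
  )
}

#' @export
print.survey_bundle <- function(x, ...) {
  cat("<survey_bundle>\n")
  cat("  invoices:", nrow(x$invoices), "billed acts\n")
  cat("  ris:     ", nrow(x$ris), "examinations\n")
  cat("  dacs:    ", nrow(x$dacs), "DLP records\n")
  cat("  survey:  ", nrow(x$survey), "facility x modality responses\n")
  invisible(x)
}

bundle_tables <- c("invoices", "ris", "dacs", "survey", "facilities")

#' Write / read a synthetic bundle as plain CSV files
#'
#' `write_bundle()` writes one CSV per table plus a JSON echo of the
#' generating configuration; `read_bundle()` reads them back into an
#' identical `survey_bundle`, so bundles round-trip losslessly through disk.
#'
#' @param bundle A `survey_bundle` from [simulate_survey_data()].
#' @param dir Directory to write to (created if missing).
#' @return `write_bundle()` returns the file paths invisibly; `read_bundle()`
#'   returns a `survey_bundle`.
#' @export
write_bundle <- function(bundle, dir) {
  if (!inherits(bundle, "survey_bundle")) {
    abort("`bundle` must be a survey_bundle")
  }
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- setNames(file.path(dir, paste0(bundle_tables, ".csv")),
                    bundle_tables)
  for (tab in bundle_tables) {
    readr::write_csv(bundle[[tab]], paths[[tab]], progress = FALSE)
  }
  cfg <- unclass(bundle$truth)
  cfg$modality_frequencies <- as.list(cfg$modality_frequencies)
  cfg$response_rates <- as.list(cfg$response_rates)
  cfg_path <- file.path(dir, "config.json")
  jsonlite::write_json(cfg, cfg_path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(c(paths, config = cfg_path))
}

#' @rdname write_bundle
#' @export
read_bundle <- function(dir) {
  col_specs <- list(
    invoices = readr::cols(patient_id = "c", facility_id = "c",
                           date = readr::col_date(), billing_code = "c"),
    ris = readr::cols(patient_id = "c", facility_id = "c",
                      date = readr::col_date(), modality = "c", region = "c"),
    dacs = readr::cols(exam_id = "c", region = "c", dlp_mgycm = "d",
                       stratum = "c"),
    survey = readr::cols(facility_id = "c", modality = "c", count = "i",
                         responded = "l"),
    facilities = readr::cols(facility_id = "c", stratum = "c",
                             facility_share = "d")
  )
  tables <- purrr::imap(col_specs, function(spec, tab) {
    out <- readr::read_csv(file.path(dir, paste0(tab, ".csv")),
                           col_types = spec, progress = FALSE)
    attr(out, "spec") <- NULL
    attr(out, "problems") <- NULL
    class(out) <- c("tbl_df", "tbl", "data.frame")
    out
  })
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  truth <- generator_config(
    seed = cfg$seed,
    population_size = cfg$population_size,
    coverage_fraction = cfg$coverage_fraction,
    facility_strata = tibble::as_tibble(cfg$facility_strata),
    modality_frequencies = unlist(cfg$modality_frequencies),
    region_mix = tibble::as_tibble(cfg$region_mix),
    dlp_models = tibble::as_tibble(cfg$dlp_models),
    response_rates = unlist(cfg$response_rates),
    billing_modalities = cfg$billing_modalities,
    ris_discrepancy_rate = cfg$ris_discrepancy_rate,
    ris_deletion_share = cfg$ris_deletion_share,
    combined_ct_rate = cfg$combined_ct_rate,
    n_dose_records = cfg$n_dose_records
  )
  structure(c(tables, list(truth = truth)), class = "survey_bundle")
}
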