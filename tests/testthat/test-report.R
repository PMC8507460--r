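test_that("the survey result reproduces the published per-inhabitant dose totals", {
  res <- build_result(swiss_modalities_2018(), year = 2018)
  g <- glance(res)
  expect_equal(g$dose_without_nm, 1.378, tolerance = 0.005 / 1.378)
  expect_equal(g$dose_with_nm, 1.485, tolerance = 0.005 / 1.485)
  expect_lte(abs(g$frequency_without_nm - 1215.8), 0.1 + 1e-9)
  expect_equal(g$exams_per_inhabitant, 1.2, tolerance = 0.03 / 1.2)
  # additivity: the total is exactly the sum of the modality doses
  expect_equal(sum(tidy(res)$dose_per_inhabitant), g$dose_with_nm)
})

test_that("contribution shares reproduce the published percentages and sum to 100", {
  res <- build_result(swiss_modalities_2018())
  expect_equal(share_of(res, "CT", "dose"), 64.3, tolerance = 0.2 / 64.3)
  expect_equal(share_of(res, "CT", "frequency"), 11, tolerance = 0.02)
  expect_equal(
    share_of(res, c("dental radiography (without CBCT)", "CBCT"), "frequency"),
    47.89, tolerance = 0.2 / 47.89
  )
  expect_equal(share_of(res, "nuclear medicine", "dose"), 7.2,
               tolerance = 0.2 / 7.2)
  expect_equal(sum(tidy(res)$frequency_share_pct), 100)
  expect_equal(sum(tidy(res)$dose_share_pct), 100)
})

test_that("a single-modality survey carries 100% of both shares", {
  res <- build_result(tibble::tibble(modality = "CT", frequency = 135,
                                     dose_vector = 7.08))
  expect_equal(tidy(res)$frequency_share_pct, 100)
  expect_equal(tidy(res)$dose_share_pct, 100)
})

test_that("mismatched modality sets between frequencies and doses are errors", {
  f <- tibble::tibble(modality = c("CT", "MR"), frequency = c(135, 50))
  d <- tibble::tibble(modality = "CT", dose_vector = 7.08)
  expect_error(build_result(f, d), "no dose vector for: MR")
  expect_error(build_result(f[1, ],
                            dplyr::bind_rows(d, tibble::tibble(
                              modality = "NM", dose_vector = 8))),
               "no frequency for: NM")
})

test_that("per-1000 and per-inhabitant outputs are invariant to population scale", {
  counts <- tibble::tibble(modality = c("CT", "radiography"),
                           national = c(135000, 439000))
  f1 <- per_1000(counts, 1e6, total = FALSE)
  f2 <- per_1000(dplyr::mutate(counts, national = national * 2), 2e6,
                 total = FALSE)
  expect_equal(f1$frequency, f2$frequency)
  d <- tibble::tibble(modality = c("CT", "radiography"),
                      dose_vector = c(7.08, 0.32))
  expect_equal(glance(build_result(f1, d))$dose_with_nm,
               glance(build_result(f2, d))$dose_with_nm)
})

test_that("between-survey comparison reproduces the published five-year trends", {
  res18 <- build_result(swiss_modalities_2018(), year = 2018)
  trend <- compare_surveys(swiss_survey_2013(), res18)
  ct <- trend[trend$modality == "CT", ]
  expect_equal(round(ct$frequency_change_pct), 15)
  expect_equal(round(ct$dose_per_exam_change_pct), -17)
  scopy <- trend[trend$modality == "conventional radioscopy", ]
  expect_equal(round(scopy$frequency_change_pct), -21)
  radiog <- trend[trend$modality == "conventional radiography", ]
  expect_equal(round(radiog$frequency_change_pct), -7)
  # overall: examination numbers stable, dose down ~3% excluding NM
  tot <- trend[trend$modality == "Total", ]
  expect_equal(tot$frequency_change_pct, -0.3, tolerance = 0.2)
  expect_equal(round(tot$dose_change_pct), -3)
  # NM exists only in 2018: reported with NA change, not dropped
  nm <- trend[trend$modality == "nuclear medicine", ]
  expect_equal(nrow(nm), 1)
  expect_true(is.na(nm$frequency_change_pct))
})

test_that("comparing a survey with itself gives all-zero changes", {
  res <- build_result(swiss_modalities_2018())
  trend <- compare_surveys(res, res)
  expect_true(all(trend$frequency_change_pct == 0))
  expect_true(all(trend$dose_change_pct == 0))
  expect_true(all(trend$dose_per_exam_change_pct == 0))
})

test_that("the rendered report writes tables, summary and optional sections", {
  res <- build_result(swiss_modalities_2018(), year = 2018)
  trend <- compare_surveys(swiss_survey_2013(), res)
  verif <- verification_summary(swiss_verification_2018())
  dir <- withr::local_tempdir()
  paths <- render_report(res, comparison = trend, verification = verif,
                         dir = dir, chart = FALSE)
  expect_true(all(file.exists(paths)))
  expect_setequal(names(paths), c("modalities", "summary", "trend",
                                  "verification"))
  mods <- readr::read_csv(paths[["modalities"]], show_col_types = FALSE)
  expect_equal(
    mods$dose_per_inhabitant[mods$modality == "Total (with nuclear medicine)"],
    1.486
  )
  expect_equal(mods$frequency[mods$modality == "CT"], 135)
  smry <- jsonlite::read_json(paths[["summary"]])
  expect_equal(round(smry$dose_per_inhabitant_msv, 3), 1.486)
  # omitting the comparison omits the trend section
  dir2 <- withr::local_tempdir()
  paths2 <- render_report(res, dir = dir2, chart = FALSE)
  expect_false("trend" %in% names(paths2))
  # the chart either renders or is skipped gracefully
  expect_no_error(suppressWarnings(render_report(res, dir = dir2)))
})

test_that("the full pipeline recovers configured frequencies and per-inhabitant
           dose from a synthetic bundle", {
  pop <- 3e5
  coverage <- 0.5
  # equal stratum medians make the configured pooled median exact truth
  dlp <- default_dlp_models()
  dlp <- dlp |>
    dplyr::group_by(region) |>
    dplyr::mutate(median_dlp = mean(median_dlp)) |>
    dplyr::ungroup()
  cfg <- generator_config(seed = 101, population_size = pop,
                          coverage_fraction = coverage,
                          dlp_models = dlp, ris_discrepancy_rate = 0,
                          n_dose_records = 400)
  b <- simulate_survey_data(cfg)
  exams <- build_examinations(b$invoices, default_code_map())

  cov <- coverage_model(pop, covered_fraction = coverage,
                        mode = "population_scaling")
  billing <- exams |>
    dplyr::count(modality, name = "count") |>
    extrapolate_billing(cov) |>
    per_1000(pop, total = FALSE)
  survey <- b$survey[b$survey$responded, ] |>
    dplyr::count(modality, wt = count, name = "count") |>
    extrapolate_survey(cfg$response_rates) |>
    per_1000(pop, total = FALSE)
  society <- tibble::tibble(modality = "screening mammography",
                            frequency = 11.8)
  freq <- combine_frequencies(billing = billing, web_survey = survey,
                              society_report = society)

  ct_freq <- exams |>
    dplyr::filter(modality == "CT") |>
    dplyr::count(region, name = "frequency")
  summaries <- summarize_dlp(b$dacs, default_conversion_factors())
  v <- ct_dose_vector(summaries, ct_freq)
  doses <- assemble_dose_tables(default_modality_doses(), ct = v,
                                nm = nm_effective_dose(default_nm_procedures()))
  res <- build_result(freq, doses)

  # ---- truth and its standard error -----------------------------------
  k <- default_conversion_factors()
  mix <- cfg$region_mix[cfg$region_mix$modality == "CT", ]
  share_true <- setNames(mix$share * (1 - cfg$combined_ct_rate), mix$region)
  share_true["chest and abdomen"] <- cfg$combined_ct_rate
  med <- setNames(dlp$median_dlp[dlp$stratum == "university"],
                  dlp$region[dlp$stratum == "university"])
  v_ct_true <- sum(share_true * unname(k[names(share_true)]) *
                     unname(med[names(share_true)]))
  dose_tbl <- assemble_dose_tables(default_modality_doses(), ct = v_ct_true,
                                   nm = nm_effective_dose(default_nm_procedures()))
  vec_true <- setNames(dose_tbl$dose_vector, dose_tbl$modality)
  f_true <- cfg$modality_frequencies[names(vec_true)]
  dose_true <- sum(f_true * vec_true) / 1000

  shares_fac <- b$facilities$facility_share
  var_freq <- purrr::map_dbl(names(vec_true), function(m) {
    if (m %in% cfg$billing_modalities) {
      f_true[[m]] * 1000 / (pop * coverage)
    } else if (m %in% names(cfg$response_rates)) {
      r <- cfg$response_rates[[m]]
      lam <- f_true[[m]] / 1000 * pop * shares_fac
      (sum(lam) / r + (1 - r) / r * sum(lam^2)) * (1000 / pop)^2
    } else 0  # society report: exogenous
  })
  # CT-vector estimation noise: lognormal median SE per region, pooled n
  n_pool <- 2 * cfg$n_dose_records
  se_med <- med * dlp$log_sd[1] * sqrt(pi / 2) / sqrt(n_pool)
  var_vec <- sum((share_true * unname(k[names(share_true)]) *
                    unname(se_med[names(share_true)]))^2)
  var_dose <- sum((vec_true / 1000)^2 * var_freq) +
    (f_true[["CT"]] / 1000)^2 * var_vec
  se_dose <- sqrt(var_dose)

  g <- glance(res)
  expect_lt(abs(g$dose_with_nm - dose_true), 3 * se_dose)
  # frequency totals also recover (billing + survey noise only)
  se_freq <- sqrt(sum(var_freq))
  expect_lt(abs(g$frequency_with_nm - sum(f_true)), 3 * se_freq)
  # and the estimated CT vector is close to its configured truth
  expect_equal(v$vector_msv, v_ct_true, tolerance = 0.05)
})
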