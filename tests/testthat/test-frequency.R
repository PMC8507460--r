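test_that("billing extrapolation divides by the coverage factor of the chosen mode", {
  cov <- coverage_model(1e6, covered_fraction = 0.107,
                        activity_ratio_factor = 0.101)
  counts <- tibble::tibble(modality = c("CT", "conventional radiography"),
                           count = c(1070, 101))
  out <- extrapolate_billing(counts, cov)
  expect_equal(out$national_population_scaling[1], 10000)
  expect_equal(out$national_activity_ratio[2], 1000)
  # default mode is the activity ratio
  expect_equal(out$national, out$national_activity_ratio)
  # the two modes differ exactly by the ratio of the factors
  expect_equal(out$national_activity_ratio / out$national_population_scaling,
               rep(0.107 / 0.101, 2))
  cov_pop <- coverage_model(1e6, 0.107, 0.101, mode = "population_scaling")
  expect_equal(extrapolate_billing(counts, cov_pop)$national[1], 10000)
})

test_that("coverage factors are validated", {
  expect_error(coverage_model(1e6, 0), "covered_fraction")
  expect_error(coverage_model(1e6, 0.107, 1.3), "activity_ratio_factor")
  expect_error(coverage_model(-1, 0.107), "population_total")
})

test_that("survey extrapolation divides by the modality response rate", {
  out <- extrapolate_survey(
    tibble::tibble(modality = "nuclear medicine", count = 941),
    c("nuclear medicine" = 0.941)
  )
  expect_equal(out$national, 1000)
  # rate 1 is the identity
  ident <- extrapolate_survey(tibble::tibble(modality = "CBCT", count = 37),
                              c(CBCT = 1))
  expect_equal(ident$national, 37)
  # the dental channel uses its own published rate
  dental <- extrapolate_survey(
    tibble::tibble(modality = "dental radiography (without CBCT)", count = 500),
    default_response_rates()
  )
  expect_equal(dental$national, 500 / 0.291)
  expect_error(
    extrapolate_survey(tibble::tibble(modality = "MRI", count = 1),
                       default_response_rates()),
    "MRI"
  )
})

test_that("per-1000 conversion and its Total row are exact", {
  out <- per_1000(tibble::tibble(modality = "CT", national = 135000), 1e6)
  expect_equal(out$frequency[out$modality == "CT"], 135)
  expect_equal(out$frequency[out$modality == "Total"], 135)
  no_total <- per_1000(tibble::tibble(modality = "CT", national = 135000),
                       1e6, total = FALSE)
  expect_false("Total" %in% no_total$modality)
})

test_that("summed published frequencies reproduce the printed totals", {
  tbl <- swiss_modalities_2018()
  no_nm <- tbl[tbl$modality != "nuclear medicine", ]
  # printed parts sum to the printed without-NM total within 0.1
  expect_lte(abs(sum(no_nm$frequency_per_1000) - 1215.8), 0.1 + 1e-9)
  expect_lte(abs(sum(tbl$frequency_per_1000) - 1229.1), 0.1 + 1e-9)
  # dental (incl. CBCT) share of all examinations
  dental <- tbl$frequency_per_1000[
    tbl$modality %in% c("dental radiography (without CBCT)", "CBCT")]
  expect_equal(sum(dental) / sum(tbl$frequency_per_1000) * 100, 47.9,
               tolerance = 0.002)
})

test_that("extrapolation commutes with summation across facilities", {
  cov <- coverage_model(1e6, 0.107, 0.101)
  per_fac <- tibble::tibble(modality = "CT", facility = c("A", "B", "C"),
                            count = c(120, 45, 310))
  summed_then <- extrapolate_billing(
    dplyr::summarise(per_fac, modality = "CT", count = sum(count)), cov
  )$national
  then_summed <- sum(extrapolate_billing(per_fac, cov)$national)
  expect_equal(summed_then, then_summed)
})

test_that("source precedence picks the authoritative channel per modality", {
  out <- combine_frequencies(
    billing = tibble::tibble(modality = c("CT", "conventional radiography"),
                             frequency = c(135, 439)),
    web_survey = tibble::tibble(modality = c("CT", "nuclear medicine"),
                                frequency = c(120, 13.3))
  )
  expect_equal(out$frequency[out$modality == "CT"], 135)
  expect_equal(out$source[out$modality == "CT"], "billing")
  expect_equal(out$frequency[out$modality == "nuclear medicine"], 13.3)
  flipped <- combine_frequencies(
    billing = tibble::tibble(modality = "CT", frequency = 135),
    web_survey = tibble::tibble(modality = "CT", frequency = 120),
    precedence = c("web_survey", "billing")
  )
  expect_equal(flipped$frequency, 120)
})

test_that("the billing pipeline recovers configured frequencies through
           generation, building, extrapolation and per-1000 scaling", {
  pop <- 4e5
  coverage <- 0.25
  cfg <- generator_config(
    seed = 31, population_size = pop, coverage_fraction = coverage,
    ris_discrepancy_rate = 0, n_dose_records = 0,
    dlp_models = default_dlp_models()[0, ]
  )
  b <- simulate_survey_data(cfg)
  exams <- build_examinations(b$invoices, default_code_map())
  cov <- coverage_model(pop, covered_fraction = coverage,
                        mode = "population_scaling")
  freq <- exams |>
    dplyr::count(modality, name = "count") |>
    extrapolate_billing(cov) |>
    per_1000(pop, total = FALSE)
  for (m in cfg$billing_modalities) {
    truth <- cfg$modality_frequencies[[m]]
    est <- freq$frequency[freq$modality == m]
    # per-1000 SE of a Poisson count observed under partial coverage
    se <- sqrt(truth * 1000 / (pop * coverage))
    expect_lt(abs(est - truth), 3 * se + 1e-9)
  }
})

test_that("the survey channel recovers configured frequencies through
           response-rate extrapolation", {
  pop <- 3e5
  strata <- tibble::tibble(stratum = c("university", "regional", "private"),
                           n_facilities = c(30L, 100L, 300L),
                           volume_share = c(0.45, 0.30, 0.25))
  cfg <- generator_config(
    seed = 17, population_size = pop, facility_strata = strata,
    n_dose_records = 0, dlp_models = default_dlp_models()[0, ]
  )
  b <- simulate_survey_data(cfg)
  responded <- b$survey[b$survey$responded, ]
  est <- responded |>
    dplyr::count(modality, wt = count, name = "count") |>
    extrapolate_survey(cfg$response_rates) |>
    per_1000(pop, total = FALSE)
  shares <- b$facilities$facility_share
  for (m in names(cfg$response_rates)) {
    truth <- cfg$modality_frequencies[[m]]
    r <- cfg$response_rates[[m]]
    lambda <- truth / 1000 * pop * shares
    # variance of sum(responding counts)/r: Poisson within facilities plus
    # Bernoulli response at facility level
    v <- sum(lambda) / r + (1 - r) / r * sum(lambda^2)
    se <- sqrt(v) / pop * 1000
    got <- est$frequency[est$modality == m]
    expect_lt(abs(got - truth), 3 * se)
  }
})
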