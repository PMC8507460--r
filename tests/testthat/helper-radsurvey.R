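# Shared fixtures: small generator configurations and an independent
# brute-force oracle for the invoice-grouping logic.

small_config <- function(seed = 1, population = 5e4, coverage = 1,
                         ris_discrepancy_rate = 0, ...) {
  generator_config(
    seed = seed,
    population_size = population,
    coverage_fraction = coverage,
    ris_discrepancy_rate = ris_discrepancy_rate,
    n_dose_records = 50,
    ...
  )
}

# A tiny code map covering a handful of CT regions plus one radiography code.
toy_code_map <- function() {
  tibble::tibble(
    billing_code = c("C1", "C2", "C3", "C4", "C5", "R1"),
    modality = c(rep("CT", 5), "conventional radiography"),
    region = c("chest", "abdomen", "pelvis", "head", "chest and abdomen", "all")
  )
}

toy_invoice <- function(patient, facility, date, code) {
  tibble::tibble(patient_id = patient, facility_id = facility,
                 date = as.Date(date), billing_code = code)
}

# Brute-force grouping oracle: base-R, loops over sessions, no shared code
# with build_examinations(). Handles ordered greedy merge rules.
oracle_build <- function(invoices, code_map, rules = NULL) {
  mod <- code_map$modality[match(invoices$billing_code, code_map$billing_code)]
  reg <- code_map$region[match(invoices$billing_code, code_map$billing_code)]
  stopifnot(!anyNA(mod))
  df <- data.frame(patient_id = invoices$patient_id,
                   facility_id = invoices$facility_id,
                   date = as.character(invoices$date),
                   modality = mod, region = reg,
                   stringsAsFactors = FALSE)
  key <- paste(df$patient_id, df$facility_id, df$date, df$modality, df$region,
               sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  exams <- data.frame(
    patient_id = vapply(parts, `[`, "", 1),
    facility_id = vapply(parts, `[`, "", 2),
    date = vapply(parts, `[`, "", 3),
    modality = vapply(parts, `[`, "", 4),
    region = vapply(parts, `[`, "", 5),
    n_source_codes = as.integer(tab),
    stringsAsFactors = FALSE
  )
  if (!is.null(rules)) {
    sessions <- unique(exams[c("patient_id", "facility_id", "date")])
    out <- list()
    for (s in seq_len(nrow(sessions))) {
      sel <- exams$patient_id == sessions$patient_id[s] &
        exams$facility_id == sessions$facility_id[s] &
        exams$date == sessions$date[s]
      block <- exams[sel, ]
      for (r in seq_len(nrow(rules))) {
        comp <- rules$components[[r]]
        idx <- which(block$modality == rules$modality[r] &
                       block$region %in% comp)
        if (length(idx) == length(comp)) {
          merged <- block[idx[1], ]
          merged$region <- rules$merged[r]
          merged$n_source_codes <- sum(block$n_source_codes[idx])
          block <- rbind(block[-idx, ], merged)
        }
      }
      out[[s]] <- block
    }
    exams <- do.call(rbind, out)
  }
  exams$date <- as.Date(exams$date)
  exams <- exams[order(exams$patient_id, exams$facility_id, exams$date,
                       exams$modality, exams$region), ]
  rownames(exams) <- NULL
  tibble::as_tibble(exams)
}

# Multiset comparison of examination tables (ignores n_source_codes).
as_exam_multiset <- function(tbl) {
  sort(paste(tbl$patient_id, tbl$facility_id, tbl$date, tbl$modality,
             tbl$region, sep = "\r"))
}
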