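Package: radsurvey
Title: Population Exposure Surveys from Medical Imaging
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for nationwide surveys of population exposure from medical
    imaging: turning invoice-level billing records into radiological
    examinations (including merging co-billed computed-tomography regions into
    combined examinations), verifying billing-derived counts against a
    radiology information system, extrapolating partially observed counts to
    national frequencies per 1000 inhabitants, estimating the CT effective-dose
    vector from dose-archive (DLP) records with a facility-stratum uncertainty,
    assembling per-modality effective-dose vectors including nuclear medicine,
    and combining frequencies and dose vectors into per-inhabitant annual
    effective dose, contribution shares and between-survey trends. A synthetic
    data generator emulates the confidential hospital sources so the whole
    pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
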