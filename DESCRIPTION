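Package: ckdtier
Title: Tiered Electronic Health Record Phenotype for Advanced Chronic Kidney Disease
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Identifies patients with advanced (stage 4-5, nondialysis) chronic
    kidney disease in four-table electronic health record extracts. Computes
    MDRD estimated glomerular filtration rate (eGFR) from serum creatinine,
    selects index and >=90-day-prior eGFR values, builds a source cohort with
    dialysis exclusion by ICD-10/CPT code sets, and assigns each patient to a
    high-, intermediate-, or low-risk advanced CKD tier with an acute kidney
    injury carve-out. Includes comparator phenotypes (diagnosis codes only,
    single index eGFR, two eGFR values), prevalence estimates with binomial
    confidence intervals, diagnostic-accuracy metrics, six-month follow-up
    stability summaries, and a seeded synthetic EHR generator so the whole
    pipeline can be exercised without access to protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
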