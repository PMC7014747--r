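# Small hand-built fixtures used across the suite.

# One row per patient; defaults are a "benign" patient (every risk
# indicator 0) so tests can flip single fields.
patient_row <- function(id, outcome = "optimal", age = 50, figo_stage = "III",
                        grade = 1, histology = "serous", ca125 = 100,
                        he4 = 100, ecog = 0, asa = "2") {
  tibble::tibble(
    patient_id = id, age = age, figo_stage = figo_stage, grade = grade,
    histology = histology, ca125 = ca125, he4 = he4, ecog = ecog, asa = asa,
    outcome = outcome
  )
}

# Six patients whose indicator vectors and confusion tables are easy to
# enumerate by hand: suboptimal patients carry high HE4, optimal do not.
toy_cohort <- function() {
  dplyr::bind_rows(
    patient_row("a", "suboptimal", he4 = 900, age = 70),
    patient_row("b", "suboptimal", he4 = 800),
    patient_row("c", "suboptimal", he4 = 100),
    patient_row("d", "optimal", he4 = 100),
    patient_row("e", "optimal", he4 = 850),
    patient_row("f", "optimal", he4 = 100)
  )
}

# A generated cohort reused by several files (kept small for speed).
shared_cohort <- function(seed = 42, n = 200) {
  generate_cohort(default_cohort_config(), seed = seed, n = n)
}
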