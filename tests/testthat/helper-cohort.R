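# Shared builders and independent oracles for the test suite.

# one fully valid patient row; override any field
make_patient <- function(patient_id = "p1", sex = "M", marital = "married",
                         age = 60, bmi = 24, functional = "normal",
                         vintage_years = 0.5, albumin_gL = 40,
                         ferritin_ugL = 200, dm = 0, htn = 1, ihd = 0,
                         cvd = 0, epo = 1, hemoglobin_gL = 110, ktv = 1.6,
                         adm_vascular = 0, adm_nonvascular = 0, died = 0,
                         quarter = 0L) {
  data.frame(patient_id = patient_id, sex = sex, marital = marital,
             age = age, bmi = bmi, functional = functional,
             vintage_years = vintage_years, albumin_gL = albumin_gL,
             ferritin_ugL = ferritin_ugL, dm = dm, htn = htn, ihd = ihd,
             cvd = cvd, epo = epo, hemoglobin_gL = hemoglobin_gL, ktv = ktv,
             adm_vascular = adm_vascular, adm_nonvascular = adm_nonvascular,
             died = died, quarter = quarter, stringsAsFactors = FALSE)
}

# a patient guaranteed to score 0 (all best bands) or >= 6 (high risk)
low_risk_patient <- function(patient_id = "lo", ...) {
  make_patient(patient_id = patient_id, ...)
}
high_risk_patient <- function(patient_id = "hi", ...) {
  # vintage 3 + functional 3 = total >= 6 whatever the rest
  make_patient(patient_id = patient_id, vintage_years = 6,
               functional = "bed_chair_bound", ...)
}

# independent brute-force Pearson chi-square: direct cell-by-cell summation
chi2_oracle <- function(m) {
  n <- sum(m)
  expected <- outer(rowSums(m), colSums(m)) / n
  stat <- 0
  for (i in seq_len(nrow(m))) {
    for (j in seq_len(ncol(m))) {
      stat <- stat + (m[i, j] - expected[i, j])^2 / expected[i, j]
    }
  }
  list(statistic = stat, df = (nrow(m) - 1) * (ncol(m) - 1))
}

# random strictly-positive 2x2 table
random_2x2 <- function(max_count = 200) {
  matrix(sample.int(max_count, 4, replace = TRUE), 2, 2)
}
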