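# Shared fixtures, built in code.

# Flat toy life table over a wide age range.
flat_life_table <- function(expectancy = 15, ages = 40:105) {
  life_table(rbind(
    data.frame(sex = "M", age = ages, expectancy = expectancy),
    data.frame(sex = "F", age = ages, expectancy = expectancy)))
}

# Utility table matching the documented toy values.
test_utilities <- function(reference = 0.85) {
  utility_table(reference, data.frame(
    state = c("noncirrhosis", "compensated_cirrhosis",
              "decompensated_cirrhosis", "post_lt_sr", "incurable_hcc"),
    base = c(0.80, 0.72, 0.66, 0.75, 0.40),
    low = c(0.72, 0.64, 0.55, 0.65, 0.32),
    high = c(0.88, 0.80, 0.75, 0.85, 0.48)))
}

# Identity deflators (CPI flat, PPP 1) over the study years.
identity_deflators <- function(years = 2000:2020) {
  deflator_table(setNames(rep(100, length(years)), years), 1, base_year = 2013)
}

# Minimal single-strategy spec for regression-recovery studies.
recovery_spec <- function(n = 2000, seed = 1, prevalence = 0.45,
                          d_qaly = 0.9, d_cost = 14000, d_ly = 1.7) {
  cohort_spec(
    n_patients = n,
    treatment_prevalences = c(RFA = prevalence),
    true_incremental_effect = c(RFA = d_qaly),
    true_incremental_ly = c(RFA = d_ly),
    true_incremental_cost = c(RFA = d_cost),
    missingness_rates = c(birth_country = 0, comorbidity = 0,
                          cancer_stage = 0),
    seed = seed)
}

# Independent recursive re-implementation of the scan-retention rule,
# used as a brute-force oracle for screening classification.
oracle_screening <- function(scan_dates, diagnosis_date, min_gap = 137) {
  retain <- function(dates) {
    if (!length(dates)) return(as.Date(character(0)))
    first <- min(dates)
    rest <- dates[as.numeric(dates - first) >= min_gap]
    c(first, retain(rest))
  }
  kept <- retain(sort(as.Date(scan_dates)))
  d <- as.numeric(as.Date(diagnosis_date) - kept)
  in1 <- any(d > 0 & d <= 365)
  in2 <- any(d > 365 & d <= 730)
  if (in1 && in2) "routine" else if (in1 || in2) "inconsistent" else "none"
}
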