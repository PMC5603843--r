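test_that("cohort generation is deterministic under a fixed seed", {
  spec <- cohort_spec(n_patients = 100, seed = 7)
  a <- generate_cohort(spec)
  b <- generate_cohort(spec)
  expect_identical(a, b)
  expect_identical(cost_ledger(a), cost_ledger(b))
  expect_false(identical(generate_cohort(cohort_spec(n_patients = 100, seed = 8)),
                         a))
})

test_that("marginal strategy shares and covariate prevalences converge to the spec", {
  spec <- cohort_spec(n_patients = 20000, seed = 11)
  co <- generate_cohort(spec)
  shares <- table(co$treatment) / nrow(co)
  expect_lt(abs(shares[["RFA"]] - 0.105), 0.01)
  for (s in names(spec$treatment_prevalences))
    expect_lt(abs(shares[[s]] - spec$treatment_prevalences[[s]]), 0.01)
  expect_lt(abs(shares[["none"]] - (1 - sum(spec$treatment_prevalences))), 0.015)
  cp <- spec$covariate_prevalences
  expect_lt(max(abs(table(co$age_category) / nrow(co) - cp$age_category)), 0.01)
  expect_lt(max(abs(table(co$screening) / nrow(co) - cp$screening)), 0.01)
  expect_lt(abs(mean(co$diabetes) - cp$diabetes), 0.01)
})

test_that("the default cohort carries every strategy label including no treatment", {
  co <- generate_cohort(cohort_spec(seed = 3))
  expect_equal(nrow(co), 2222)
  expect_setequal(strategy_labels(),
                  unique(as.character(co$treatment)))
  expect_equal(levels(co$treatment)[1], "none")
})

test_that("latent outcomes carry the configured increments in expectation", {
  spec <- recovery_spec(n = 40000, seed = 21)
  co <- generate_cohort(spec)
  t <- co$treatment == "RFA"
  # raw contrasts are confounded; compare within covariate stratum instead
  strat <- co$cancer_stage == "I" & co$age_category == "<60" &
    co$screening == "none"
  d_q <- mean(co$qaly_gained[t & strat]) - mean(co$qaly_gained[!t & strat])
  d_c <- mean(co$cost_usd[t & strat]) - mean(co$cost_usd[!t & strat])
  expect_lt(abs(d_q - 0.9), 0.15)
  expect_lt(abs(d_c - 14000) / 14000, 0.15)
})

test_that("spec validation names the offending field", {
  expect_error(cohort_spec(n_patients = 0), "n_patients")
  expect_error(cohort_spec(treatment_prevalences = c(RFA = 0.7, SR = 0.6)),
               "treatment_prevalences")
  expect_error(cohort_spec(treatment_prevalences = c(ABC = 0.1)),
               "unknown strategy")
  expect_error(cohort_spec(missingness_rates = c(birth_country = 0.5,
                                                 comorbidity = 0.2,
                                                 cancer_stage = 0.6)),
               "monotone")
  expect_error(cohort_spec(missingness_rates = c(birth_country = 0.1,
                                                 comorbidity = 0.2,
                                                 cancer_stage = 1)),
               "missingness_rates")
})

test_that("screening classification follows the two-window retention rule", {
  dx <- as.Date("2008-06-15")
  expect_equal(derive_screening_category(dx - c(23, 8) * 30.44, dx), "routine")
  expect_equal(derive_screening_category(as.Date(character(0)), dx), "none")
  # second scan only 0.5 months after the first is discarded
  expect_equal(derive_screening_category(dx - c(10, 9.5) * 30.44, dx),
               "inconsistent")
  # a discarded scan cannot cover a window on its own
  expect_equal(derive_screening_category(dx - c(370, 360), dx), "inconsistent")
  expect_error(derive_screening_category(dx, dx), "before the diagnosis")
})

test_that("screening classification agrees with the recursive brute-force oracle", {
  set.seed(42)
  dx <- as.Date("2009-01-01")
  for (rep in 1:300) {
    k <- sample(0:4, 1)
    scans <- dx - sample(1:900, k)
    expect_equal(derive_screening_category(scans, dx),
                 oracle_screening(scans, dx),
                 info = paste(format(scans), collapse = ", "))
  }
})

test_that("baseline comorbidity uses the diagnosis-date episode, else the most recent within 2 years", {
  dx <- as.Date("2007-03-01")
  ep <- function(days_before, idx)
    data.frame(admission_date = dx - days_before, charlson_index = idx)
  expect_equal(assign_baseline_comorbidity(ep(0, 2), dx), "2")
  expect_equal(assign_baseline_comorbidity(
    rbind(ep(30 * 30.44, 1), ep(10 * 30.44, 3)), dx), "3+")
  expect_equal(assign_baseline_comorbidity(ep(30 * 30.44, 1), dx), "no_hosp")
  empty <- data.frame(admission_date = as.Date(character(0)),
                      charlson_index = integer(0))
  expect_equal(assign_baseline_comorbidity(empty, dx), "no_hosp")
  expect_equal(assign_baseline_comorbidity(ep(100, 0), dx), "0")
  expect_error(assign_baseline_comorbidity(ep(10, -1), dx), "non-negative")
})

test_that("missingness injection hits the configured rates with a monotone pattern", {
  spec <- cohort_spec(n_patients = 10000,
                      missingness_rates = c(birth_country = 0.1,
                                            comorbidity = 0.2,
                                            cancer_stage = 0.5),
                      seed = 13)
  co <- generate_cohort(spec)
  cm <- inject_missingness(co, spec)
  expect_lt(abs(mean(is.na(cm$birth_country)) - 0.1), 0.01)
  expect_lt(abs(mean(is.na(cm$comorbidity)) - 0.2), 0.01)
  expect_lt(abs(mean(is.na(cm$cancer_stage)) - 0.5), 0.01)
  # monotone: missing an earlier-ordered variable implies missing all later
  expect_true(all(is.na(cm$comorbidity[is.na(cm$birth_country)])))
  expect_true(all(is.na(cm$cancer_stage[is.na(cm$comorbidity)])))
  expect_silent(check_monotone(cm))

  zero <- cohort_spec(n_patients = 500,
                      missingness_rates = c(birth_country = 0,
                                            comorbidity = 0,
                                            cancer_stage = 0),
                      seed = 13)
  co0 <- generate_cohort(zero)
  expect_identical(inject_missingness(co0, zero), co0)
})
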