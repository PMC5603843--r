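# Person-level effect measures and costs.
#
# Effects are measured on two complementary scales:
#   * losses  — potential years of life lost (PYLL: residual life-table
#     expectancy at the age of death) and quality-adjusted life years
#     lost (QALYL: utility-weighted PYLL plus per-year utility decrements
#     for years lived with disease);
#   * gains   — (discounted) life years and QALYs from diagnosis to the
#     (estimated) death year, the E_i consumed by the net benefit
#     regression.
# Costs are deflated to 2013 CAD, converted to USD at purchasing power
# parity, and discounted.

#' Estimate age and year of death
#'
#' Age at diagnosis is the midpoint of the recorded category (<60, 60-69,
#' 70-79, 80+ mapped to 55, 65, 75, 85). For patients who died on or
#' before the administrative end year, age at death adds the years from
#' diagnosis to death. For patients still alive, the expected death year
#' is diagnosis year plus the literature survival by stage at diagnosis
#' (stage I: 5 years, II: 4, III-IV: 3); if that year falls within the
#' observed window (on or before the administrative end year) the year
#' after the administrative end is taken as the most likely death year.
#'
#' @param age_category factor/character in `<60`, `60-69`, `70-79`, `80+`.
#' @param cancer_stage factor/character in `I`, `II`, `III-IV`; must be
#'   non-missing (impute first).
#' @param diagnosis_year,death_year calendar years; `death_year` is `NA`
#'   for patients alive at the administrative end.
#' @param admin_end_year administrative end of follow-up (default 2011).
#' @return data frame with `age_at_death` and the (estimated) `death_year`.
#' @export
estimate_age_at_death <- function(age_category, cancer_stage, diagnosis_year,
                                  death_year, admin_end_year = 2011) {
  if (anyNA(cancer_stage))
    stop("cancer_stage contains missing values; run imputation before estimating ages at death",
         call. = FALSE)
  age_mid <- c("<60" = 55, "60-69" = 65, "70-79" = 75, "80+" = 85)
  a0 <- age_mid[as.character(age_category)]
  if (anyNA(a0)) stop("unknown age category", call. = FALSE)
  surv <- c("I" = 5, "II" = 4, "III-IV" = 3)[as.character(cancer_stage)]
  expected <- diagnosis_year + surv
  est_death <- ifelse(!is.na(death_year), death_year,
                      ifelse(expected <= admin_end_year, admin_end_year + 1,
                             expected))
  data.frame(age_at_death = unname(a0 + (est_death - diagnosis_year)),
             death_year = as.integer(est_death))
}

#' Discount a stream of dated amounts
#'
#' Present value `sum(amount / (1 + rate)^(year - reference_year))`.
#'
#' @param years,amounts equal-length vectors (may be empty).
#' @param discount a [discount_spec()].
#' @return present value (0 for an empty stream).
#' @export
discount_stream <- function(years, amounts, discount = discount_spec()) {
  if (!length(years)) return(0)
  sum(amounts * pv_factor(years - discount$reference_year,
                          discount$annual_rate))
}

#' Potential years of life lost
#'
#' Looks up the residual life expectancy at (sex, age at death) and
#' discounts the lost year-fractions from the death year at the annual
#' rate: an expectancy of `L` years contributes `floor(L)` full years
#' (the first undiscounted) plus a pro-rata fraction in the final year.
#' A zero rate returns the raw table lookup.
#'
#' @param age_at_death age in years (from [estimate_age_at_death()]).
#' @param sex sex code matching the life table.
#' @param table a [life_table()].
#' @param discount a [discount_spec()]; only the rate is used (the
#'   stream is anchored at the death year).
#' @return discounted PYLL in years.
#' @export
compute_pyll <- function(age_at_death, sex, table, discount = discount_spec()) {
  expectancy <- residual_expectancy(table, sex, age_at_death)
  vapply(expectancy, function(L) {
    full <- floor(L)
    frac <- L - full
    t <- seq_len(full) - 1
    sum(pv_factor(t, discount$annual_rate)) +
      frac * pv_factor(full, discount$annual_rate)
  }, numeric(1))
}

# Health state occupied in year k (0-based) after diagnosis. Stage at
# diagnosis is held fixed (no progression information); advanced-stage
# cancer overrides the liver state as incurable disease; transplant or
# resection recipients switch to the post-procedure state from the second
# year onwards.
health_state_for_year <- function(k, cancer_stage, liver_disease_stage,
                                  treatment) {
  if (as.character(cancer_stage) == "III-IV") return("incurable_hcc")
  trt <- as.character(treatment)
  if (k >= 1 && (grepl("LT", trt) || grepl("SR", trt))) return("post_lt_sr")
  ls <- as.character(liver_disease_stage)
  if (grepl("decomp", ls)) "decompensated_cirrhosis"
  else if (grepl("cirrhosis", ls) && ls != "no_cirrhosis") "compensated_cirrhosis"
  else "noncirrhosis"
}

#' Quality-adjusted life years lost
#'
#' Two parts: the PYLL weighted by the reference (alive-and-disease-free)
#' utility, plus, for each year lived from diagnosis to death, the
#' decrement from the reference utility down to the utility of the
#' health state occupied that year. Each decrement is discounted from
#' diagnosis at the annual rate.
#'
#' @param pyll discounted PYLL (from [compute_pyll()]).
#' @param states character vector of health states, one per year lived
#'   from diagnosis to death (may be empty).
#' @param utilities a [utility_table()].
#' @param discount a [discount_spec()] (rate only; decrements anchored at
#'   diagnosis).
#' @param scenario utility scenario (`"base"`, `"lower"`, `"upper"`).
#' @return QALYL in quality-adjusted years.
#' @export
compute_qalyl <- function(pyll, states, utilities, discount = discount_spec(),
                          scenario = "base") {
  u <- utility_values(utilities, scenario)
  unknown <- setdiff(states, names(u))
  if (length(unknown))
    stop(sprintf("unknown health state(s) %s; supported: %s",
                 paste(unknown, collapse = ", "),
                 paste(names(u), collapse = ", ")), call. = FALSE)
  ref <- utilities$reference_utility
  dec <- if (length(states)) {
    sum((ref - u[states]) * pv_factor(seq_along(states) - 1,
                                      discount$annual_rate))
  } else 0
  ref * pyll + dec
}

#' Total deflated, converted, discounted cost
#'
#' Each ledger item (nominal CAD of its year) is inflated to the
#' base-year price level by the CPI ratio, converted to USD at purchasing
#' power parity, and discounted to the reference year.
#'
#' @param ledger data frame with columns `year` and `amount` (one
#'   person's cost stream).
#' @param deflators a [deflator_table()].
#' @param discount a [discount_spec()].
#' @return total cost in discounted base-year USD.
#' @export
total_cost <- function(ledger, deflators, discount = discount_spec()) {
  if (!nrow(ledger)) return(0)
  yr <- as.character(ledger$year)
  missing_yr <- setdiff(yr, names(deflators$cpi))
  if (length(missing_yr))
    stop(sprintf("no deflator entry for year(s): %s",
                 paste(sort(unique(missing_yr)), collapse = ", ")),
         call. = FALSE)
  base_idx <- deflators$cpi[[as.character(deflators$base_year)]]
  usd <- ledger$amount * (base_idx / deflators$cpi[yr]) * deflators$ppp_factor
  discount_stream(ledger$year, usd, discount)
}

#' Per-person effects and costs for a completed cohort
#'
#' Runs the full outcome construction for every record of a completed
#' (no missing values) cohort: estimated death year and age at death,
#' discounted PYLL and QALYL, discounted life years and QALYs from
#' diagnosis (the gained-scale effects E_i), and total cost C_i from the
#' cohort's ledger.
#'
#' @param cohort completed cohort (with attached cost ledger, see
#'   [cost_ledger()]).
#' @param table a [life_table()].
#' @param utilities a [utility_table()].
#' @param deflators a [deflator_table()].
#' @param discount a [discount_spec()].
#' @param scenario utility scenario for the QALY-scale outcomes.
#' @param admin_end_year administrative end of follow-up.
#' @return data frame: `id`, `age_at_death`, `pyll`, `qalyl`,
#'   `life_years`, `qalys`, `total_cost`.
#' @export
person_effects <- function(cohort, table = toy_life_table(),
                           utilities = toy_utility_table(),
                           deflators = toy_deflator_table(),
                           discount = discount_spec(),
                           scenario = "base",
                           admin_end_year = 2011) {
  est <- estimate_age_at_death(cohort$age_category, cohort$cancer_stage,
                               cohort$diagnosis_year, cohort$death_year,
                               admin_end_year)
  pyll <- compute_pyll(est$age_at_death, as.character(cohort$sex), table,
                       discount)
  led <- cost_ledger(cohort)
  rate <- discount$annual_rate
  u <- utility_values(utilities, scenario)
  ref <- utilities$reference_utility
  n <- nrow(cohort)
  qalyl <- life_years <- qalys <- cost <- numeric(n)
  cost_split <- split(led[c("year", "amount")], led$id)
  for (i in seq_len(n)) {
    yrs <- est$death_year[i] - cohort$diagnosis_year[i]
    states <- if (yrs > 0) {
      vapply(seq_len(yrs) - 1, health_state_for_year, character(1),
             cancer_stage = cohort$cancer_stage[i],
             liver_disease_stage = cohort$liver_disease_stage[i],
             treatment = cohort$treatment[i])
    } else character(0)
    disc <- pv_factor(seq_len(max(yrs, 0)) - 1, rate)
    qalyl[i] <- ref * pyll[i] +
      (if (yrs > 0) sum((ref - u[states]) * disc) else 0)
    life_years[i] <- sum(disc)
    qalys[i] <- if (yrs > 0) sum(u[states] * disc) else 0
    l <- cost_split[[as.character(cohort$id[i])]]
    # each person's stream is discounted to their own diagnosis year, the
    # anchor used for the effect streams
    cost[i] <- if (is.null(l)) 0 else
      total_cost(l, deflators,
                 discount_spec(rate, cohort$diagnosis_year[i]))
  }
  data.frame(id = cohort$id, age_at_death = est$age_at_death,
             pyll = pyll, qalyl = qalyl, life_years = life_years,
             qalys = qalys, total_cost = cost)
}
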