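# Synthetic person-level cohort generator. Stands in for the non-public
# registry-linked administrative data: one row per patient with derived
# covariates, a confounded treatment label, survival to an administrative
# end date, a per-calendar-year cost ledger, and (optionally injected)
# monotone missingness. Covariates are generated directly at the derived
# level; the two claims-derivation rules that the analysis relies on
# (ultrasound screening classification and baseline comorbidity lookback)
# are exposed as standalone functions.

#' Treatment strategy labels
#'
#' The eleven mutually exclusive labels: no treatment plus ten active
#' strategies formed from radiofrequency ablation (RFA), surgical
#' resection (SR), liver transplantation (LT) and transarterial
#' chemoembolization (TACE).
#'
#' @return character vector, `"none"` first.
#' @export
strategy_labels <- function() {
  c("none", "RFA", "SR", "LT", "RFA+SR", "RFA+LT", "SR+LT",
    "TACE+RFA", "TACE+SR", "TACE+LT", "RFA+SR+LT")
}

liver_stage_labels <- function() {
  c("viral_hepatitis", "no_cirrhosis", "cirrhosis", "ald_cirrhosis",
    "viral_hep_cirrhosis", "ald_viral_hep_cirrhosis",
    "decomp_cirrhosis", "ald_decomp_cirrhosis", "nafld_decomp_cirrhosis",
    "viral_hep_decomp_cirrhosis", "ald_viral_hep_decomp_cirrhosis")
}

age_labels <- function() c("<60", "60-69", "70-79", "80+")

#' Default generator settings
#'
#' Treatment shares follow the observed overall distribution of the
#' Ontario 2002-2010 HCC cohort; covariate prevalences approximate its
#' marginal composition; the true incremental effects (QALYs, life years)
#' and costs per strategy equal the reference adjusted estimates, so that
#' the generator's ground truth matches the study conditions.
#'
#' @return named list / vector of defaults.
#' @export
default_treatment_prevalences <- function() {
  c("RFA" = 0.105, "SR" = 0.141, "LT" = 0.103, "RFA+SR" = 0.031,
    "RFA+LT" = 0.025, "SR+LT" = 0.017, "TACE+RFA" = 0.012,
    "TACE+SR" = 0.005, "TACE+LT" = 0.012, "RFA+SR+LT" = 0.005)
}

#' @rdname default_treatment_prevalences
#' @export
default_covariate_prevalences <- function() {
  list(
    age_category = c("<60" = 0.35, "60-69" = 0.27, "70-79" = 0.27, "80+" = 0.11),
    sex = c("F" = 0.22, "M" = 0.78),
    income_quintile = c(Q1 = 0.24, Q2 = 0.21, Q3 = 0.21, Q4 = 0.17, Q5 = 0.17),
    residence = c(urban = 0.91, rural = 0.09),
    birth_country = c(Canada = 0.46, Other = 0.54),
    comorbidity = c("0" = 0.37, "1" = 0.27, "2" = 0.12, "3+" = 0.09,
                    "no_hosp" = 0.15),
    diabetes = 0.49,
    hiv = 0.02,
    liver_disease_stage = c(
      viral_hepatitis = 0.023, no_cirrhosis = 0.196, cirrhosis = 0.198,
      ald_cirrhosis = 0.031, viral_hep_cirrhosis = 0.036,
      ald_viral_hep_cirrhosis = 0.007, decomp_cirrhosis = 0.274,
      ald_decomp_cirrhosis = 0.143, nafld_decomp_cirrhosis = 0.007,
      viral_hep_decomp_cirrhosis = 0.048,
      ald_viral_hep_decomp_cirrhosis = 0.037),
    screening = c(none = 0.47, inconsistent = 0.41, routine = 0.12),
    cancer_stage = c(I = 0.30, II = 0.32, "III-IV" = 0.38),
    stage_iv_share = 0.22  # share of stage IV within the III-IV category
  )
}

#' @rdname default_treatment_prevalences
#' @export
default_confounding_coefficients <- function() {
  list(
    age_category = c("70-79" = -0.25, "80+" = -1.2),
    screening = c(inconsistent = 0.45, routine = 0.9),
    cancer_stage = c("III-IV" = -1.3),
    liver_disease_stage = c(decomp_cirrhosis = 0.2,
                            ald_decomp_cirrhosis = 0.2,
                            viral_hep_decomp_cirrhosis = 0.2,
                            ald_viral_hep_decomp_cirrhosis = 0.2),
    diabetes = 0.15
  )
}

#' @rdname default_treatment_prevalences
#' @export
default_incremental_qaly <- function() {
  c("RFA" = 0.88067, "SR" = 1.02540, "LT" = 2.09062, "RFA+SR" = 1.46756,
    "RFA+LT" = 1.88475, "SR+LT" = 2.41171, "TACE+RFA" = 0.93455,
    "TACE+SR" = 0.44091, "TACE+LT" = 1.81332, "RFA+SR+LT" = 2.71620)
}

#' @rdname default_treatment_prevalences
#' @export
default_incremental_ly <- function() {
  c("RFA" = 1.72958, "SR" = 1.97368, "LT" = 3.34719, "RFA+SR" = 2.63641,
    "RFA+LT" = 3.01967, "SR+LT" = 3.76051, "TACE+RFA" = 1.82717,
    "TACE+SR" = 1.09491, "TACE+LT" = 3.04816, "RFA+SR+LT" = 4.10809)
}

#' @rdname default_treatment_prevalences
#' @export
default_incremental_cost <- function() {
  c("RFA" = 13697, "SR" = 81514, "LT" = 160430, "RFA+SR" = 71559,
    "RFA+LT" = 112411, "SR+LT" = 173575, "TACE+RFA" = 2304,
    "TACE+SR" = 96088, "TACE+LT" = 132266, "RFA+SR+LT" = 164608)
}

# Baseline (no-treatment) outcome models, linear in the analysis dummies.
baseline_outcome_coefficients <- function() {
  list(
    ly = list(intercept = 2.6,
              age_category = c("70-79" = -0.5, "80+" = -1.2),
              cancer_stage = c(II = -0.5, "III-IV" = -1.5),
              screening = c(inconsistent = 0.25, routine = 0.55),
              sd = 1.3),
    qaly = list(intercept = 2.0,
                age_category = c("70-79" = -0.4, "80+" = -1.0),
                cancer_stage = c(II = -0.4, "III-IV" = -1.2),
                screening = c(inconsistent = 0.2, routine = 0.45),
                sd = 1.1),
    cost = list(intercept = 38000,
                age_category = c("80+" = -4000),
                cancer_stage = c("III-IV" = -8000),
                screening = c(inconsistent = 1000, routine = 2000),
                liver_disease_stage = c(decomp_cirrhosis = 8000,
                                        ald_decomp_cirrhosis = 8000,
                                        viral_hep_decomp_cirrhosis = 8000,
                                        ald_viral_hep_decomp_cirrhosis = 8000),
                sd = 15000),
    cost_qaly_cor = 0.3
  )
}

#' Cohort generator specification
#'
#' Bundles every knob of the synthetic cohort: size, strategy shares,
#' covariate prevalences, the confounding log-odds that tie treatment
#' assignment to covariates, the true incremental effects/costs that hold
#' in expectation, missingness rates, the administrative end year, and the
#' seed. Defaults reproduce the study conditions of the motivating Ontario
#' cohort (n = 2,222; administrative end of follow-up 2011).
#'
#' @param n_patients cohort size (>= 1).
#' @param treatment_prevalences named vector of active-strategy shares
#'   summing to <= 1; the remainder is no treatment.
#' @param covariate_prevalences list of per-covariate level prevalences.
#' @param confounding_coefficients list mapping covariate (level) to the
#'   log-odds effect on receiving any active treatment.
#' @param true_incremental_effect named vector: true incremental QALYs per
#'   strategy versus no treatment.
#' @param true_incremental_ly named vector: true incremental life years.
#' @param true_incremental_cost named vector: true incremental cost (USD).
#' @param missingness_rates named proportions in \[0,1) for
#'   `birth_country`, `comorbidity`, `cancer_stage`; must be non-decreasing
#'   in that (monotone) order.
#' @param admin_end_year administrative censoring year.
#' @param seed integer seed; identical specs generate identical cohorts.
#' @return object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_patients = 2222,
                        treatment_prevalences = default_treatment_prevalences(),
                        covariate_prevalences = default_covariate_prevalences(),
                        confounding_coefficients = default_confounding_coefficients(),
                        true_incremental_effect = default_incremental_qaly(),
                        true_incremental_ly = default_incremental_ly(),
                        true_incremental_cost = default_incremental_cost(),
                        missingness_rates = c(birth_country = 0.33,
                                              comorbidity = 0.35,
                                              cancer_stage = 0.56),
                        admin_end_year = 2011,
                        seed = 1L) {
  if (!is.numeric(n_patients) || length(n_patients) != 1 || n_patients < 1)
    stop_field("n_patients", "must be a single count >= 1")
  check_prob(treatment_prevalences, "treatment_prevalences")
  if (sum(treatment_prevalences) > 1 + 1e-12)
    stop_field("treatment_prevalences", "active-strategy shares must sum to <= 1")
  bad <- setdiff(names(treatment_prevalences), strategy_labels())
  if (length(bad))
    stop_field("treatment_prevalences",
               paste("unknown strategy:", paste(bad, collapse = ", ")))
  for (v in c("birth_country", "comorbidity", "cancer_stage"))
    if (!v %in% names(missingness_rates))
      stop_field("missingness_rates", paste("missing rate for", v))
  mr <- missingness_rates[c("birth_country", "comorbidity", "cancer_stage")]
  check_prob(mr, "missingness_rates", allow_one = FALSE)
  if (is.unsorted(mr))
    stop_field("missingness_rates",
               "must be non-decreasing along birth_country -> comorbidity -> cancer_stage (monotone pattern)")
  for (s in names(true_incremental_effect))
    if (!s %in% strategy_labels()) stop_field("true_incremental_effect",
                                              paste("unknown strategy:", s))
  structure(list(
    n_patients = as.integer(n_patients),
    treatment_prevalences = treatment_prevalences,
    covariate_prevalences = covariate_prevalences,
    confounding_coefficients = confounding_coefficients,
    true_incremental_effect = true_incremental_effect,
    true_incremental_ly = true_incremental_ly,
    true_incremental_cost = true_incremental_cost,
    missingness_rates = mr,
    admin_end_year = admin_end_year,
    seed = as.integer(seed)
  ), class = "cohort_spec")
}

# Linear predictor from a list of (covariate -> named level coefficients),
# applied to a cohort data frame. Numeric covariates use a scalar slope.
covariate_score <- function(cohort, coefficients) {
  score <- numeric(nrow(cohort))
  for (cv in names(coefficients)) {
    co <- coefficients[[cv]]
    x <- cohort[[cv]]
    if (is.null(x)) next
    if (is.numeric(x)) {
      score <- score + co[1] * x
    } else {
      for (lev in names(co)) score <- score + co[[lev]] * (as.character(x) == lev)
    }
  }
  score
}

# Calibrate per-strategy intercepts of the multinomial assignment model so
# that the *marginal* strategy shares match the configured prevalences
# despite the covariate-driven log-odds shift `f`.
calibrate_intercepts <- function(f, targets, n_iter = 40) {
  alpha <- log(targets / max(1 - sum(targets), 1e-8))
  for (it in seq_len(n_iter)) {
    eta <- outer(f, rep(1, length(alpha))) +
      matrix(alpha, nrow = length(f), ncol = length(alpha), byrow = TRUE)
    ee <- exp(eta)
    denom <- 1 + rowSums(ee)
    pbar <- colMeans(ee / denom)
    alpha <- alpha + log(targets / pbar)
  }
  alpha
}

draw_categorical <- function(n, probs) {
  stopifnot(abs(sum(probs) - 1) < 1e-6)
  factor(sample(names(probs), n, replace = TRUE, prob = probs),
         levels = names(probs))
}

#' Generate a synthetic person-level cohort
#'
#' Draws `n_patients` records: covariates at their configured prevalences
#' (independently across covariates), a treatment label from a single
#' multinomial logistic model whose log-odds of any active strategy versus
#' no treatment shift with the confounding coefficients (intercepts are
#' calibrated so marginal shares match the configured prevalences), latent
#' person-level outcomes (life years, QALYs from diagnosis, and total
#' 2013-USD cost) that carry the configured true increments exactly in
#' expectation, a death year derived from the latent survival (records
#' surviving past `admin_end_year` are censored alive), and a per-calendar-
#' year cost ledger consistent with the latent total under the packaged
#' deflators.
#'
#' The returned cohort is fully observed; apply [inject_missingness()] to
#' emulate the registry's missing-data pattern.
#'
#' @param spec a [cohort_spec()].
#' @return data frame of class `nbrcea_cohort`, one row per patient, with
#'   the cost ledger attached as attribute `"cost_ledger"` (see
#'   [cost_ledger()]).
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$seed)
  n <- spec$n_patients
  cp <- spec$covariate_prevalences

  cohort <- data.frame(
    id = seq_len(n),
    age_category = draw_categorical(n, cp$age_category),
    sex = draw_categorical(n, cp$sex),
    income_quintile = draw_categorical(n, cp$income_quintile),
    residence = draw_categorical(n, cp$residence),
    birth_country = draw_categorical(n, cp$birth_country),
    comorbidity = draw_categorical(n, cp$comorbidity),
    diabetes = rbinom(n, 1, cp$diabetes),
    hiv = rbinom(n, 1, cp$hiv),
    liver_disease_stage = draw_categorical(n, cp$liver_disease_stage),
    screening = draw_categorical(n, cp$screening),
    cancer_stage = draw_categorical(n, cp$cancer_stage),
    diagnosis_year = sample(2002:2010, n, replace = TRUE),
    stringsAsFactors = TRUE
  )
  cohort$stage_iv <- cohort$cancer_stage == "III-IV" &
    runif(n) < (cp$stage_iv_share %||% 0.22)
  cohort$dx_year_band <- cut(cohort$diagnosis_year,
                             breaks = c(2001, 2004, 2007, 2010),
                             labels = c("2002-2004", "2005-2007", "2008-2010"))

  # Confounded multinomial treatment assignment.
  f <- covariate_score(cohort, spec$confounding_coefficients)
  targets <- spec$treatment_prevalences
  active <- names(targets)
  if (length(active)) {
    alpha <- calibrate_intercepts(f, targets)
    eta <- outer(f, rep(1, length(alpha))) +
      matrix(alpha, nrow = n, ncol = length(alpha), byrow = TRUE)
    ee <- cbind(1, exp(eta))  # first column: no treatment
    probs <- ee / rowSums(ee)
    cum <- t(apply(probs, 1, cumsum))
    u <- runif(n)
    idx <- rowSums(u > cum) + 1L
    cohort$treatment <- factor(c("none", active)[idx], levels = strategy_labels())
  } else {
    cohort$treatment <- factor(rep("none", n), levels = strategy_labels())
  }

  # Latent outcomes: baseline linear in the analysis dummies + strategy
  # increment + Gaussian noise (cost noise correlated with QALY noise).
  bc <- baseline_outcome_coefficients()
  inc_of <- function(map) {
    out <- numeric(n)
    trt <- as.character(cohort$treatment)
    hit <- trt %in% names(map)
    out[hit] <- map[trt[hit]]
    out
  }
  z_q <- rnorm(n)
  z_c <- bc$cost_qaly_cor * z_q + sqrt(1 - bc$cost_qaly_cor^2) * rnorm(n)
  cohort$ly_gained <- covariate_score(cohort, bc$ly[!names(bc$ly) %in% c("intercept", "sd")]) +
    bc$ly$intercept + inc_of(spec$true_incremental_ly) + rnorm(n, sd = bc$ly$sd)
  cohort$qaly_gained <- covariate_score(cohort, bc$qaly[!names(bc$qaly) %in% c("intercept", "sd")]) +
    bc$qaly$intercept + inc_of(spec$true_incremental_effect) + bc$qaly$sd * z_q
  cohort$cost_usd <- pmax(
    covariate_score(cohort, bc$cost[!names(bc$cost) %in% c("intercept", "sd")]) +
      bc$cost$intercept + inc_of(spec$true_incremental_cost) + bc$cost$sd * z_c,
    0)

  # Death year from latent survival; censored alive past the admin end.
  surv_years <- pmax(round(cohort$ly_gained), 0)
  death <- cohort$diagnosis_year + surv_years
  cohort$death_year <- ifelse(death > spec$admin_end_year, NA_integer_,
                              as.integer(death))

  attr(cohort, "cost_ledger") <- build_cost_ledger(cohort, spec)
  attr(cohort, "spec") <- spec
  class(cohort) <- c("nbrcea_cohort", "data.frame")
  cohort
}

# Spread each person's latent USD total over calendar years from diagnosis
# to death/censoring, front-loaded (treatment costs concentrate in the
# first year), expressed in nominal CAD of each year so that deflating to
# 2013 CAD and converting at PPP recovers the latent total (undiscounted).
build_cost_ledger <- function(cohort, spec,
                              deflators = toy_deflator_table(),
                              first_year_share = 0.6) {
  end <- pmin(ifelse(is.na(cohort$death_year), spec$admin_end_year,
                     cohort$death_year), spec$admin_end_year)
  n_years <- pmax(end - cohort$diagnosis_year + 1L, 1L)
  id <- rep(cohort$id, n_years)
  year <- unlist(lapply(seq_len(nrow(cohort)), function(i)
    seq(cohort$diagnosis_year[i], length.out = n_years[i])), use.names = FALSE)
  k <- unlist(lapply(n_years, seq_len), use.names = FALSE) - 1L
  nrep <- rep(n_years, n_years)
  share <- ifelse(nrep == 1L, 1,
                  ifelse(k == 0L, first_year_share,
                         (1 - first_year_share) / (nrep - 1L)))
  usd <- rep(cohort$cost_usd, n_years) * share
  cpi <- deflators$cpi
  base_idx <- cpi[[as.character(deflators$base_year)]]
  nominal_cad <- usd / deflators$ppp_factor / (base_idx / cpi[as.character(year)])
  data.frame(id = id, year = year, amount = unname(nominal_cad),
             category = "total")
}

#' Access the cost ledger of a generated cohort
#'
#' @param cohort a cohort from [generate_cohort()].
#' @return long data frame: `id`, `year`, `amount` (nominal CAD of that
#'   year), `category`.
#' @export
cost_ledger <- function(cohort) {
  led <- attr(cohort, "cost_ledger")
  if (is.null(led)) stop("cohort carries no cost ledger", call. = FALSE)
  led
}

#' Classify ultrasound screening history
#'
#' Scans closer than 137 days (4.5 months) to the previously retained scan
#' are discarded; the patient is `"routine"` if at least one retained scan
#' falls in each of the two 12-month windows before diagnosis
#' (`[dx-365, dx)` and `[dx-730, dx-365)`), `"inconsistent"` if exactly one
#' window is covered, else `"none"`.
#'
#' @param scan_dates `Date` vector of ultrasound dates (any order), all
#'   strictly before `diagnosis_date`.
#' @param diagnosis_date `Date` of cancer diagnosis.
#' @param min_gap_days minimum spacing for a scan to count as distinct.
#' @return one of `"routine"`, `"inconsistent"`, `"none"`.
#' @export
derive_screening_category <- function(scan_dates, diagnosis_date,
                                      min_gap_days = 137) {
  scan_dates <- as.Date(scan_dates)
  diagnosis_date <- as.Date(diagnosis_date)
  if (any(scan_dates >= diagnosis_date))
    stop("scan dates must be strictly before the diagnosis date", call. = FALSE)
  retained <- as.Date(character(0))
  for (d in sort(scan_dates)) {
    d <- as.Date(d, origin = "1970-01-01")
    if (!length(retained) ||
        as.numeric(d - retained[length(retained)]) >= min_gap_days)
      retained <- c(retained, d)
  }
  days_before <- as.numeric(diagnosis_date - retained)
  w1 <- any(days_before > 0 & days_before <= 365)
  w2 <- any(days_before > 365 & days_before <= 730)
  if (w1 && w2) "routine" else if (w1 || w2) "inconsistent" else "none"
}

#' Assign baseline comorbidity from hospitalization episodes
#'
#' Uses the Charlson-Deyo index of the episode on the diagnosis date if
#' one exists, otherwise of the most recent episode within the 2-year
#' lookback window; with no qualifying episode the category is
#' `"no_hosp"`.
#'
#' @param episodes data frame with columns `admission_date` (`Date`) and
#'   `charlson_index` (integer >= 0); may have zero rows.
#' @param diagnosis_date `Date` of cancer diagnosis.
#' @param lookback_days lookback window length (default 2 years).
#' @return one of `"0"`, `"1"`, `"2"`, `"3+"`, `"no_hosp"`.
#' @export
assign_baseline_comorbidity <- function(episodes, diagnosis_date,
                                        lookback_days = 730) {
  diagnosis_date <- as.Date(diagnosis_date)
  if (is.null(episodes) || nrow(episodes) == 0) return("no_hosp")
  if (any(episodes$charlson_index < 0))
    stop("charlson_index must be non-negative", call. = FALSE)
  adm <- as.Date(episodes$admission_date)
  at_dx <- which(adm == diagnosis_date)
  pick <- if (length(at_dx)) {
    at_dx[1]
  } else {
    days_before <- as.numeric(diagnosis_date - adm)
    ok <- which(days_before > 0 & days_before <= lookback_days)
    if (!length(ok)) return("no_hosp")
    ok[which.min(days_before[ok])]
  }
  idx <- episodes$charlson_index[pick]
  if (idx >= 3) "3+" else as.character(idx)
}

#' Inject a monotone missingness pattern
#'
#' Sets `birth_country`, `comorbidity` and `cancer_stage` to missing at
#' the configured marginal rates, coupled through a single uniform draw
#' per person so the pattern is monotone by construction in the declared
#' order (a record missing `birth_country` is also missing `comorbidity`
#' and `cancer_stage`, and so on down the order). Completely at random
#' with respect to all covariates.
#'
#' @param cohort fully observed cohort data frame.
#' @param spec the [cohort_spec()] carrying `missingness_rates` (rates
#'   must be < 1 and non-decreasing along the monotone order).
#' @param seed seed for the missingness draw (defaults to the spec seed
#'   offset by one so it does not replay the generation stream).
#' @return the cohort with `NA`s injected; ordering and all other columns
#'   untouched.
#' @export
inject_missingness <- function(cohort, spec, seed = spec$seed + 1L) {
  rates <- spec$missingness_rates
  check_prob(rates, "missingness_rates", allow_one = FALSE)
  set.seed(seed)
  u <- runif(nrow(cohort))
  out <- cohort
  out$birth_country[u < rates[["birth_country"]]] <- NA
  out$comorbidity[u < rates[["comorbidity"]]] <- NA
  out$cancer_stage[u < rates[["cancer_stage"]]] <- NA
  out
}

#' Strategy counts and shares
#'
#' Tabulates treatment labels with report-style one-decimal percentage
#' shares.
#'
#' @param cohort a cohort data frame with a `treatment` column.
#' @return data frame: `strategy`, `n`, `share_pct` (numeric, 1 decimal).
#' @export
strategy_shares <- function(cohort) {
  tab <- table(cohort$treatment)
  data.frame(strategy = names(tab),
             n = as.integer(tab),
             share_pct = as.numeric(fmt_share(as.integer(tab), nrow(cohort))),
             row.names = NULL)
}
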