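# External reference tables: life table, health-state utilities, cost
# deflators, discounting. All are plain-text config (CSV / YAML) with
# packaged toy defaults; real analyses supply jurisdiction-specific files.

#' Residual life expectancy table
#'
#' A life table maps (sex, integer age) to residual life expectancy in
#' years. It drives the potential-years-of-life-lost (PYLL) computation:
#' the PYLL of a person dying at a given age is the standard expectancy a
#' person of that sex and age would still have had.
#'
#' @param entries data frame with columns `sex` (`"F"`/`"M"`), `age`
#'   (integer years) and `expectancy` (> 0 years).
#' @return object of class `life_table`.
#' @seealso [toy_life_table()], [read_life_table()], [residual_expectancy()]
#' @export
life_table <- function(entries) {
  entries <- as.data.frame(entries)
  need <- c("sex", "age", "expectancy")
  if (!all(need %in% names(entries)))
    stop_field("entries", paste("needs columns", paste(need, collapse = ", ")))
  if (any(entries$expectancy <= 0))
    stop_field("expectancy", "residual expectancies must be positive")
  entries$sex <- as.character(entries$sex)
  entries$age <- as.integer(entries$age)
  for (s in unique(entries$sex)) {
    ages <- sort(entries$age[entries$sex == s])
    if (length(ages) > 1 && any(diff(ages) != 1L))
      stop_field("age", sprintf("ages for sex %s must be contiguous", s))
  }
  structure(list(entries = entries), class = "life_table")
}

#' @rdname life_table
#' @param path CSV file with columns sex, age, expectancy.
#' @export
read_life_table <- function(path) life_table(read.csv(path))

#' Packaged toy life table
#'
#' A smooth synthetic life table (ages 40-105, both sexes) with
#' exponentially declining residual expectancy, shipped so that examples
#' and tests run without jurisdiction data. It is *not* an official life
#' table; supply one via [read_life_table()] for real analyses.
#'
#' @return a `life_table`.
#' @export
toy_life_table <- function() {
  read_life_table(system.file("extdata", "toy_life_table.csv",
                              package = "nbrcea", mustWork = TRUE))
}

#' Look up residual life expectancy
#'
#' @param table a [life_table()].
#' @param sex,age vectors (recycled) of sex codes and integer ages.
#' @return residual expectancy in years.
#' @export
residual_expectancy <- function(table, sex, age) {
  stopifnot(inherits(table, "life_table"))
  age <- as.integer(round(age))
  key <- paste(as.character(sex), age)
  ref <- setNames(table$entries$expectancy,
                  paste(table$entries$sex, table$entries$age))
  out <- ref[key]
  if (anyNA(out)) {
    bad <- key[is.na(out)][1]
    rng <- range(table$entries$age)
    stop(sprintf(
      "no life-table entry for (sex age) = %s; table covers ages %d-%d",
      bad, rng[1], rng[2]), call. = FALSE)
  }
  unname(out)
}

#' Health-state utility table
#'
#' Utilities weight years of life by health-related quality of life.
#' `reference_utility` is the utility of being alive and disease-free
#' (the weight applied to lost life years); `stage_utilities` gives, per
#' disease health state, a base value and low/high bounds for sensitivity
#' scenarios. The incurable-HCC base value 0.40 (range 0.32-0.48) is the
#' literature-pooled anchor; the remaining packaged values are labelled
#' placeholders.
#'
#' @param reference_utility utility in \[0,1\] of the alive-and-disease-free
#'   state.
#' @param stage_utilities data frame with columns `state`, `base`, `low`,
#'   `high`, all in \[0,1\] with `low <= base <= high`.
#' @return object of class `utility_table`.
#' @export
utility_table <- function(reference_utility, stage_utilities) {
  check_prob(reference_utility, "reference_utility")
  su <- as.data.frame(stage_utilities)
  need <- c("state", "base", "low", "high")
  if (!all(need %in% names(su)))
    stop_field("stage_utilities", paste("needs columns", paste(need, collapse = ", ")))
  for (col in c("base", "low", "high")) check_prob(su[[col]], col)
  if (any(su$low > su$base | su$base > su$high))
    stop_field("stage_utilities", "must satisfy low <= base <= high")
  structure(list(reference_utility = reference_utility, stage_utilities = su),
            class = "utility_table")
}

#' @rdname utility_table
#' @param path YAML file with keys `reference` and `states` (per-state
#'   base/low/high).
#' @export
read_utility_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  su <- do.call(rbind, lapply(names(cfg$states), function(s) {
    e <- cfg$states[[s]]
    data.frame(state = s, base = e$base, low = e$low, high = e$high)
  }))
  utility_table(cfg$reference, su)
}

#' @rdname utility_table
#' @export
toy_utility_table <- function() {
  read_utility_table(system.file("extdata", "toy_utilities.yaml",
                                 package = "nbrcea", mustWork = TRUE))
}

#' Pick the utility scenario column
#'
#' @param utilities a [utility_table()].
#' @param scenario one of `"base"`, `"lower"`, `"upper"`.
#' @return named vector state -> utility.
#' @export
utility_values <- function(utilities, scenario = c("base", "lower", "upper")) {
  scenario <- match.arg(scenario)
  col <- switch(scenario, base = "base", lower = "low", upper = "high")
  setNames(utilities$stage_utilities[[col]], utilities$stage_utilities$state)
}

#' Discounting specification
#'
#' Costs and effects are discounted at `annual_rate` (base case 3% per
#' year) to `reference_year`.
#'
#' @param annual_rate non-negative proportion per year.
#' @param reference_year calendar year values are discounted to.
#' @return object of class `discount_spec`.
#' @export
discount_spec <- function(annual_rate = 0.03, reference_year = 2013) {
  if (!is.finite(annual_rate) || annual_rate < 0)
    stop_field("annual_rate", "must be a non-negative proportion")
  structure(list(annual_rate = annual_rate, reference_year = reference_year),
            class = "discount_spec")
}

#' Cost deflator table
#'
#' Maps calendar year to a consumer price index (health-care basket) used
#' to inflate nominal amounts to the 2013 price level, plus the 2013
#' purchasing-power-parity factor converting CAD to USD.
#'
#' @param cpi named numeric vector year -> index (> 0).
#' @param ppp_factor multiplicative CAD -> USD conversion for 2013.
#' @param base_year year whose price level amounts are inflated to.
#' @return object of class `deflator_table`.
#' @export
deflator_table <- function(cpi, ppp_factor, base_year = 2013) {
  if (any(cpi <= 0)) stop_field("cpi", "indices must be positive")
  if (ppp_factor <= 0) stop_field("ppp_factor", "must be positive")
  if (!as.character(base_year) %in% names(cpi))
    stop_field("base_year", "must have a CPI entry")
  structure(list(cpi = cpi, ppp_factor = ppp_factor, base_year = base_year),
            class = "deflator_table")
}

#' @rdname deflator_table
#' @param path YAML file with keys `cpi` (year: index), `ppp` and
#'   optionally `base_year`.
#' @export
read_deflator_table <- function(path) {
  cfg <- yaml::read_yaml(path)
  deflator_table(unlist(cfg$cpi), cfg$ppp, cfg$base_year %||% 2013)
}

#' @rdname deflator_table
#' @export
toy_deflator_table <- function() {
  read_deflator_table(system.file("extdata", "toy_deflators.yaml",
                                  package = "nbrcea", mustWork = TRUE))
}

#' Reference estimates for the Ontario 2002-2010 HCC cohort
#'
#' Published adjusted per-strategy estimates for the Ontario 2002-2010
#' hepatocellular-carcinoma cohort (2013 USD): mean PYLL/QALYL and cost,
#' covariate- and propensity-adjusted incremental effects (life years and
#' QALYs) and costs versus no treatment, and the printed ICERs. Shipped as
#' worked-example inputs: the underlying person-level administrative data
#' are not public, but the incremental arithmetic (ICERs, frontier
#' classification) is reproducible from these values.
#'
#' @return data frame with one row per strategy (`"none"` first).
#' @export
hcc_reference <- function() {
  read.csv(system.file("extdata", "ontario_hcc_reference.csv",
                       package = "nbrcea", mustWork = TRUE),
           check.names = FALSE)
}

#' Reference incremental net benefit grid (QALY scale)
#'
#' Published incremental net benefit estimates and standard errors for
#' three monotherapies versus no treatment across willingness-to-pay
#' thresholds $0-$100,000/QALY, with the printed one-sided p-values and
#' cost-effectiveness probabilities. Used as spot-check inputs for the
#' acceptability-curve probability rule.
#'
#' @return data frame with columns `lambda`, `strategy`, `inb`, `se`,
#'   `p_one_sided`, `probability`.
#' @export
hcc_reference_inb <- function() {
  read.csv(system.file("extdata", "ontario_hcc_inb_qaly.csv",
                       package = "nbrcea", mustWork = TRUE))
}
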