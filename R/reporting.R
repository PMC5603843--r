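# Pipeline orchestration and report tables: simulate -> inject
# missingness -> impute -> outcomes -> net benefit regression (per
# strategy versus no treatment, per imputation) -> Rubin pooling ->
# ICERs, acceptability curves, efficiency frontier; written as CSVs with
# deterministic column order and rounding.

#' Analysis configuration
#'
#' @param lambda_grid willingness-to-pay grid (USD per effect unit,
#'   non-negative, strictly increasing). The default covers the
#'   acceptability-curve range $0-$100,000 in $1,000 steps; widen to
#'   $500,000 for exploration of the crossing bounds.
#' @param discount_rate annual discount rate for effects and costs
#'   (base case 0.03).
#' @param utility_scenario `"base"`, `"lower"` or `"upper"` health-state
#'   utilities (sensitivity scenarios).
#' @param exclude_stage_iv drop records carrying the hidden stage-IV
#'   sub-label before analysis (sensitivity run).
#' @param m number of imputations.
#' @param seed master seed; every stage derives its stream from it.
#' @param frontier_lambda willingness-to-pay at which the efficiency
#'   frontier is classified.
#' @param robust_se use heteroscedasticity-robust (HC) standard errors in
#'   place of classical OLS ones (not the default).
#' @return object of class `analysis_config`.
#' @export
analysis_config <- function(lambda_grid = seq(0, 100000, by = 1000),
                            discount_rate = 0.03,
                            utility_scenario = c("base", "lower", "upper"),
                            exclude_stage_iv = FALSE,
                            m = 5L,
                            seed = 1L,
                            frontier_lambda = 50000,
                            robust_se = FALSE) {
  if (any(lambda_grid < 0)) stop_field("lambda_grid", "bounds must be non-negative")
  if (any(diff(lambda_grid) <= 0)) stop_field("lambda_grid", "must be strictly increasing")
  structure(list(lambda_grid = lambda_grid,
                 discount_rate = discount_rate,
                 utility_scenario = match.arg(utility_scenario),
                 exclude_stage_iv = isTRUE(exclude_stage_iv),
                 m = as.integer(m), seed = as.integer(seed),
                 frontier_lambda = frontier_lambda,
                 robust_se = isTRUE(robust_se)),
            class = "analysis_config")
}

#' Efficiency frontier classification
#'
#' Flags, at willingness-to-pay `lambda`, the strategies with positive
#' point-estimate incremental net benefit (`lambda * delta_e - delta_c >
#' 0`, i.e. lying below the ceiling-ratio line through the origin), and
#' marks strategies strictly dominated by another (strictly higher
#' incremental cost and strictly lower incremental effect).
#'
#' @param points data frame with columns `strategy`, `delta_e`, `delta_c`
#'   (one row per strategy).
#' @param lambda willingness-to-pay (USD per effect unit).
#' @return the input with `inb`, `acceptable` and `dominated` columns.
#' @export
efficiency_frontier <- function(points, lambda) {
  stopifnot(all(c("strategy", "delta_e", "delta_c") %in% names(points)))
  points$inb <- lambda * points$delta_e - points$delta_c
  points$acceptable <- points$inb > 0
  points$dominated <- vapply(seq_len(nrow(points)), function(i)
    any(points$delta_e > points$delta_e[i] & points$delta_c < points$delta_c[i]),
    logical(1))
  points
}

# INB and SE over the grid from one imputation's incremental estimates
# (exact OLS identity, so this equals refitting at every lambda).
nbr_over_grid <- function(inc, lambda_grid) {
  data.frame(lambda = lambda_grid,
             inb = inb_at(inc, lambda_grid),
             se = inb_se_at(inc, lambda_grid))
}

#' Run the full cost-effectiveness pipeline
#'
#' Generates (or takes) a cohort, injects monotone missingness (when the
#' cohort is fully observed), imputes `m` completed datasets, computes
#' per-person effects and costs, and, for every active strategy versus no
#' treatment, fits the propensity model and the adjusted incremental
#' effect/cost regressions per imputation on both the life-year and QALY
#' scales. Per-imputation estimates are pooled by Rubin's rules at every
#' willingness-to-pay value; ICERs, sign-crossing confidence bounds,
#' acceptability curves and the efficiency frontier are derived from the
#' pooled quantities.
#'
#' @param config an [analysis_config()].
#' @param cohort an observed cohort (with attached cost ledger); when
#'   `NULL`, one is generated from `spec`.
#' @param spec a [cohort_spec()] used when `cohort` is `NULL` (its seed
#'   is replaced by the config seed).
#' @param life_tab,utilities,deflators reference tables (packaged toys by
#'   default).
#' @param design a [design_spec()].
#' @return list of class `nbrcea_report`: `table2` (per-strategy mean
#'   losses and costs with 95% CIs), `table3` (pooled adjusted increments
#'   and ICERs with crossing bounds, both scales), `table4` (pooled INB,
#'   SE, one-sided p and probability across the grid), `ceac`, `frontier`,
#'   `n_excluded`, and the `config`.
#' @export
run_pipeline <- function(config = analysis_config(), cohort = NULL,
                         spec = cohort_spec(seed = config$seed),
                         life_tab = toy_life_table(),
                         utilities = toy_utility_table(),
                         deflators = toy_deflator_table(),
                         design = design_spec()) {
  stopifnot(inherits(config, "analysis_config"))
  if (is.null(cohort)) {
    cohort <- generate_cohort(spec)
    cohort <- inject_missingness(cohort, spec, seed = config$seed + 1L)
  }
  n_excluded <- 0L
  if (config$exclude_stage_iv) {
    drop <- !is.na(cohort$stage_iv) & cohort$stage_iv
    n_excluded <- sum(drop)
    led <- cost_ledger(cohort)
    cohort <- cohort[!drop, , drop = FALSE]
    attr(cohort, "cost_ledger") <- led[led$id %in% cohort$id, , drop = FALSE]
  }
  disc <- discount_spec(config$discount_rate)
  imps <- impute_monotone(cohort,
                          imputation_config(m = config$m,
                                            seed = config$seed + 2L))

  strategies <- setdiff(levels(droplevels(cohort$treatment)), "none")
  strategies <- strategies[strategies %in% unique(as.character(cohort$treatment))]
  ledger <- cost_ledger(cohort)

  per_imp <- lapply(imps, function(ci) {
    attr(ci, "cost_ledger") <- ledger
    eff <- person_effects(ci, life_tab, utilities, deflators, disc,
                          scenario = config$utility_scenario)
    list(cohort = ci, eff = eff)
  })

  table2 <- make_table2(per_imp, config$m)

  scales <- c(qaly = "qalys", ly = "life_years")
  rows3 <- list(); rows4 <- list()
  for (s in strategies) {
    incs <- list(qaly = list(), ly = list())
    for (k in seq_along(per_imp)) {
      ci <- per_imp[[k]]$cohort
      eff <- per_imp[[k]]$eff
      sub <- as.character(ci$treatment) %in% c(s, "none")
      cs <- droplevels(ci[sub, , drop = FALSE])
      es <- eff[sub, , drop = FALSE]
      scores <- fit_propensity(cs, design)
      for (sc in names(scales)) {
        incs[[sc]][[k]] <- incremental_effect_cost(
          cs, design, scores,
          effect = es[[scales[[sc]]]], cost = es$total_cost,
          robust = config$robust_se)
      }
    }
    for (sc in names(scales)) {
      pooled <- pool_incrementals(incs[[sc]])
      icer <- compute_icer(pooled)
      ci_b <- icer_confidence_bounds(
        pooled, lambda_range = c(0, max(5e5, max(config$lambda_grid))))
      rows3[[paste(s, sc)]] <- data.frame(
        strategy = s, scale = sc,
        delta_e = pooled$delta_e, delta_c = pooled$delta_c,
        var_e = pooled$var_e, var_c = pooled$var_c, cov_ec = pooled$cov_ec,
        icer = icer$ratio, ci_lower = ci_b[["ci_lower"]],
        ci_upper = ci_b[["ci_upper"]], n = incs[[sc]][[1]]$n)
      grid_fits <- lapply(incs[[sc]], nbr_over_grid,
                          lambda_grid = config$lambda_grid)
      pooled_grid <- do.call(rbind, lapply(seq_along(config$lambda_grid),
        function(j) {
          pts <- vapply(grid_fits, function(g) g$inb[j], numeric(1))
          vars <- vapply(grid_fits, function(g) g$se[j]^2, numeric(1))
          pr <- pool_rubin(pts, vars)
          data.frame(lambda = config$lambda_grid[j], inb = pr$point,
                     se = pr$se)
        }))
      pooled_grid$strategy <- s
      pooled_grid$scale <- sc
      rows4[[paste(s, sc)]] <- pooled_grid
    }
  }
  table3 <- do.call(rbind, rows3)
  rownames(table3) <- NULL
  inb_grid <- do.call(rbind, rows4)
  rownames(inb_grid) <- NULL

  table4 <- do.call(rbind, lapply(split(inb_grid,
                                        inb_grid[c("strategy", "scale")],
                                        drop = TRUE), function(g) {
    cc <- build_ceac(g[c("lambda", "inb", "se")], strategy = g$strategy[1])
    cc$scale <- g$scale[1]
    as.data.frame(cc)
  }))
  rownames(table4) <- NULL

  ceac <- table4[table4$scale == "qaly",
                 c("strategy", "lambda", "inb", "se", "p_one_sided",
                   "probability")]
  frontier <- efficiency_frontier(
    table3[table3$scale == "qaly", c("strategy", "delta_e", "delta_c")],
    config$frontier_lambda)

  structure(list(table2 = table2, table3 = table3, table4 = table4,
                 ceac = ceac, frontier = frontier,
                 n_excluded = n_excluded, config = config),
            class = "nbrcea_report")
}

# Rubin pooling of a list of incremental_estimates (bivariate).
pool_incrementals <- function(incs) {
  covs <- lapply(incs, function(i)
    matrix(c(i$var_e, i$cov_ec, i$cov_ec, i$var_c), 2))
  pooled <- pool_rubin_bivariate(
    vapply(incs, `[[`, numeric(1), "delta_e"),
    vapply(incs, `[[`, numeric(1), "delta_c"), covs)
  pooled$n <- incs[[1]]$n
  class(pooled) <- "incremental_estimates"
  pooled
}

# Per-strategy mean losses and costs with 95% CIs, pooled over the
# stacked person-by-imputation rows; counts are reported at both the
# person level and the stacked person-by-imputation level.
make_table2 <- function(per_imp, m) {
  stacked <- do.call(rbind, lapply(per_imp, function(pi)
    cbind(pi$eff, treatment = pi$cohort$treatment)))
  out <- lapply(split(stacked, stacked$treatment), function(g) {
    n_person <- nrow(g) / m
    ci <- function(x) {
      mu <- mean(x); se <- sd(x) / sqrt(n_person)
      c(mu, mu - 1.96 * se, mu + 1.96 * se)
    }
    p <- ci(g$pyll); q <- ci(g$qalyl); co <- ci(g$total_cost)
    data.frame(strategy = as.character(g$treatment[1]),
               n_person = n_person, n_person_imputation = nrow(g),
               pyll = p[1], pyll_lo = p[2], pyll_hi = p[3],
               qalyl = q[1], qalyl_lo = q[2], qalyl_hi = q[3],
               cost = co[1], cost_lo = co[2], cost_hi = co[3])
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}

#' Write report tables as CSV files
#'
#' Deterministic column order and print rounding: ICERs and dollar
#' amounts to whole dollars, probabilities to 4 decimals, effects to 5
#' decimals, shares to one decimal percentage point.
#'
#' @param results an `nbrcea_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_tables <- function(results, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  t2 <- results$table2
  for (col in c("pyll", "pyll_lo", "pyll_hi", "qalyl", "qalyl_lo", "qalyl_hi"))
    t2[[col]] <- fmt_effect(t2[[col]])
  for (col in c("cost", "cost_lo", "cost_hi")) t2[[col]] <- fmt_icer(t2[[col]])
  t3 <- results$table3
  for (col in c("delta_e")) t3[[col]] <- fmt_effect(t3[[col]])
  for (col in c("delta_c", "icer", "ci_lower", "ci_upper"))
    t3[[col]] <- fmt_icer(t3[[col]])
  t3$var_e <- NULL; t3$var_c <- NULL; t3$cov_ec <- NULL
  t4 <- results$table4
  t4$inb <- fmt_icer(t4$inb); t4$se <- fmt_icer(t4$se)
  t4$p_one_sided <- fmt_prob(t4$p_one_sided)
  t4$probability <- fmt_prob(t4$probability)
  fr <- results$frontier
  fr$delta_e <- fmt_effect(fr$delta_e)
  for (col in c("delta_c", "inb")) fr[[col]] <- fmt_icer(fr[[col]])
  paths <- file.path(dir, c("table2_effects_costs.csv",
                            "table3_increments_icers.csv",
                            "table4_inb_probability.csv",
                            "ceac.csv", "frontier.csv"))
  write.csv(t2, paths[1], row.names = FALSE)
  write.csv(t3, paths[2], row.names = FALSE)
  write.csv(t4, paths[3], row.names = FALSE)
  ceac <- results$ceac
  ceac$probability <- fmt_prob(ceac$probability)
  ceac$p_one_sided <- fmt_prob(ceac$p_one_sided)
  write.csv(ceac, paths[4], row.names = FALSE)
  write.csv(fr, paths[5], row.names = FALSE)
  invisible(paths)
}

#' @export
print.nbrcea_report <- function(x, ...) {
  cat(sprintf("nbrcea report: %d strategies, lambda grid %s-%s (x%d), m = %d\n",
              nrow(x$frontier),
              format(min(x$config$lambda_grid), big.mark = ","),
              format(max(x$config$lambda_grid), big.mark = ","),
              length(x$lambda_grid %||% x$config$lambda_grid),
              x$config$m))
  t3 <- x$table3[x$table3$scale == "qaly", ]
  t3 <- t3[order(t3$icer), ]
  cat("ICERs ($/QALY), ascending:\n")
  for (i in seq_len(nrow(t3)))
    cat(sprintf("  %-10s dE = %8.5f  dC = %8.0f  ICER = %s\n",
                t3$strategy[i], t3$delta_e[i], t3$delta_c[i],
                fmt_icer(t3$icer[i])))
  invisible(x)
}
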