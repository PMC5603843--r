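# Net benefit regression: propensity scores, person-level net benefit,
# covariate- and propensity-adjusted OLS of NB(lambda) on a treatment
# dummy, adjusted incremental effect/cost estimation, ICERs, and ICER
# confidence bounds read off the incremental-net-benefit sign crossings.

#' Regression design specification
#'
#' Names the dummy-coded covariates entering the propensity and net
#' benefit regressions (one reference level per covariate is dropped by
#' the usual treatment contrasts) and whether the estimated propensity
#' score enters the outcome regressions as a linear covariate.
#'
#' @param covariates covariate column names.
#' @param include_propensity add the propensity score as a regressor.
#' @return object of class `design_spec`.
#' @export
design_spec <- function(covariates = c("age_category", "sex",
                                       "income_quintile", "residence",
                                       "birth_country", "comorbidity",
                                       "diabetes", "hiv",
                                       "liver_disease_stage", "screening",
                                       "cancer_stage", "dx_year_band"),
                        include_propensity = TRUE) {
  structure(list(covariates = covariates,
                 include_propensity = include_propensity),
            class = "design_spec")
}

# Model matrix of intercept + treatment dummy + covariate dummies
# (+ propensity score), with empty factor levels dropped. Errors on rank
# deficiency, naming the aliased columns.
build_design <- function(cohort, design, scores = NULL,
                         check_rank = TRUE) {
  cohort <- droplevels(cohort)
  cohort$treated <- as.integer(cohort$treatment != "none")
  covs <- intersect(design$covariates, names(cohort))
  rhs <- c("treated", covs)
  if (design$include_propensity && !is.null(scores)) {
    cohort$.propensity <- scores
    rhs <- c(rhs, ".propensity")
  }
  x <- model.matrix(as.formula(paste("~", paste(rhs, collapse = " + "))),
                    data = cohort)
  if (check_rank) {
    qx <- qr(x)
    if (qx$rank < ncol(x)) {
      aliased <- colnames(x)[qx$pivot[(qx$rank + 1):ncol(x)]]
      stop(sprintf("rank-deficient design; aliased term(s): %s",
                   paste(aliased, collapse = ", ")), call. = FALSE)
    }
  }
  x
}

#' Propensity scores for treatment assignment
#'
#' Logistic regression of the binary treatment indicator (strategy versus
#' no treatment) on the design covariates; the fitted conditional
#' probabilities of treatment are returned per person. Under complete or
#' quasi-complete separation the fit is stabilised with a small ridge
#' penalty and a warning is issued.
#'
#' @param cohort cohort restricted to one strategy plus no-treatment,
#'   with a `treatment` column.
#' @param design a [design_spec()].
#' @return numeric vector of scores in (0, 1).
#' @export
fit_propensity <- function(cohort, design = design_spec()) {
  cohort <- droplevels(cohort)
  treated <- as.integer(cohort$treatment != "none")
  covs <- intersect(design$covariates, names(cohort))
  if (!length(covs)) return(rep(mean(treated), nrow(cohort)))
  f <- as.formula(paste("treated ~", paste(covs, collapse = " + ")))
  dat <- cbind(treated = treated, cohort)
  separated <- FALSE
  fit <- withCallingHandlers(
    glm(f, data = dat, family = binomial()),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)) ||
          grepl("did not converge", conditionMessage(w))) {
        separated <<- TRUE
        invokeRestart("muffleWarning")
      }
    })
  if (separated || any(!is.finite(coef(fit)))) {
    warning("separation in the propensity model; refitting with a small ridge penalty",
            call. = FALSE)
    x <- model.matrix(as.formula(paste("~", paste(covs, collapse = " + "))),
                      data = dat)
    rf <- ridge_logit(x, treated, ridge = 1e-3)
    return(plogis(drop(x %*% rf$coef)))
  }
  unname(fitted(fit))
}

#' Person-level net benefit
#'
#' `NB(lambda)_i = lambda * E_i - C_i`: the monetised effect at
#' willingness-to-pay `lambda` minus the cost.
#'
#' @param effect effect units (life years or QALYs).
#' @param cost cost in USD.
#' @param lambda willingness-to-pay (USD per effect unit, >= 0).
#' @return net benefit in USD.
#' @export
person_net_benefit <- function(effect, cost, lambda) {
  if (any(lambda < 0)) stop_field("lambda", "willingness-to-pay must be >= 0")
  lambda * effect - cost
}

# OLS via the design QR; returns treatment coefficient, its SE, residual
# info. Shared by fit_nbr and incremental_effect_cost.
ols_treatment <- function(x, y) {
  qx <- qr(x)
  coefs <- qr.coef(qx, y)
  res <- drop(y - x %*% coefs)
  df <- nrow(x) - qx$rank
  r_inv <- backsolve(qr.R(qx), diag(ncol(x)))
  xtx_inv <- r_inv %*% t(r_inv)
  # undo any column pivoting
  piv <- qx$pivot
  xtx_inv <- xtx_inv[order(piv), order(piv), drop = FALSE]
  tt <- match("treated", colnames(x))
  # leverage row for the treatment coefficient: beta_tt = sum(h_i y_i)
  h <- drop(x %*% xtx_inv[, tt])
  list(coef = coefs, res = res, df = df, xtx_tt = xtx_inv[tt, tt], tt = tt,
       h = h)
}

#' Net benefit regression at one willingness-to-pay value
#'
#' OLS of the person-level net benefit on the treatment dummy, covariate
#' dummies and (optionally) the propensity score. The treatment
#' coefficient estimates the covariate-adjusted incremental net benefit
#' (INB) at `lambda`; the strategy is cost-effective at `lambda` when the
#' INB is positive.
#'
#' @param cohort cohort restricted to one strategy plus no-treatment.
#' @param lambda willingness-to-pay (USD per effect unit).
#' @param design a [design_spec()].
#' @param scores propensity scores (from [fit_propensity()]), or `NULL`.
#' @param effect,cost per-person effect and cost vectors (defaults to
#'   cohort columns `effect` and `cost`).
#' @param robust use heteroscedasticity-robust (HC0) instead of classical
#'   standard errors.
#' @return object of class `nbr_fit`: `lambda`, `inb`, `se`,
#'   `p_two_sided`, `n`.
#' @export
fit_nbr <- function(cohort, lambda, design = design_spec(), scores = NULL,
                    effect = cohort$effect, cost = cohort$cost,
                    robust = FALSE) {
  nb <- person_net_benefit(effect, cost, lambda)
  x <- build_design(cohort, design, scores)
  fit <- ols_treatment(x, nb)
  if (var(nb) == 0) {
    est <- 0; se <- 0
  } else {
    est <- unname(fit$coef[fit$tt])
    se <- if (robust) sqrt(sum(fit$h^2 * fit$res^2))
          else sqrt(sum(fit$res^2) / fit$df * fit$xtx_tt)
  }
  p <- if (se > 0) 2 * pnorm(-abs(est / se)) else as.numeric(est == 0)
  structure(list(lambda = lambda, inb = est, se = se, p_two_sided = p,
                 n = nrow(x)), class = "nbr_fit")
}

#' Adjusted incremental effect and cost
#'
#' Two OLS fits with an identical design (effect and cost as responses);
#' the treatment coefficients are the covariate- and propensity-adjusted
#' incremental effect and cost, returned with their sampling variances
#' and covariance (estimated from the cross-covariance of the two
#' residual vectors). By linearity of least squares,
#' `lambda * delta_e - delta_c` equals the [fit_nbr()] coefficient at any
#' `lambda` on the same design, and `lambda^2 var_e + var_c -
#' 2 lambda cov_ec` equals its squared standard error.
#'
#' @inheritParams fit_nbr
#' @return object of class `incremental_estimates`: `delta_e`, `delta_c`,
#'   `var_e`, `var_c`, `cov_ec`, `n`.
#' @export
incremental_effect_cost <- function(cohort, design = design_spec(),
                                    scores = NULL,
                                    effect = cohort$effect,
                                    cost = cohort$cost,
                                    robust = FALSE) {
  x <- build_design(cohort, design, scores)
  fe <- ols_treatment(x, effect)
  fc <- ols_treatment(x, cost)
  if (robust) {
    ve <- sum(fe$h^2 * fe$res^2)
    vc <- sum(fe$h^2 * fc$res^2)
    vec <- sum(fe$h^2 * fe$res * fc$res)
  } else {
    ve <- sum(fe$res^2) / fe$df * fe$xtx_tt
    vc <- sum(fc$res^2) / fc$df * fc$xtx_tt
    vec <- sum(fe$res * fc$res) / fe$df * fe$xtx_tt
  }
  structure(list(delta_e = unname(fe$coef[fe$tt]),
                 delta_c = unname(fc$coef[fc$tt]),
                 var_e = ve, var_c = vc, cov_ec = vec,
                 n = nrow(x)),
            class = "incremental_estimates")
}

#' Incremental cost-effectiveness ratio
#'
#' @param inc an [incremental_effect_cost()] result (or any list with
#'   `delta_e`, `delta_c`).
#' @return object of class `icer_estimate` with `ratio` (USD per effect
#'   unit; `NA` with an `undefined` flag when `delta_e` is 0) and
#'   `ci_lower`/`ci_upper` slots filled by [icer_confidence_bounds()].
#' @export
compute_icer <- function(inc) {
  undefined <- inc$delta_e == 0
  structure(list(ratio = if (undefined) NA_real_ else inc$delta_c / inc$delta_e,
                 undefined = undefined,
                 ci_lower = NA_real_, ci_upper = NA_real_),
            class = "icer_estimate")
}

# INB and its SE as functions of lambda, from incremental estimates.
inb_at <- function(inc, lambda) lambda * inc$delta_e - inc$delta_c
inb_se_at <- function(inc, lambda)
  sqrt(pmax(lambda^2 * inc$var_e + inc$var_c - 2 * lambda * inc$cov_ec, 0))

#' ICER confidence bounds from INB sign crossings
#'
#' The incremental net benefit `INB(lambda) = lambda * delta_e - delta_c`
#' has standard error `sqrt(lambda^2 var_e + var_c - 2 lambda cov_ec)`.
#' The upper confidence bound of the ICER is the smallest lambda in the
#' search range at which the lower end of the INB confidence band reaches
#' zero (above it the strategy is confidently cost-effective); the lower
#' bound is the largest lambda at which the upper end of the band is
#' still at or below zero. Either bound is undefined (NA) when the band
#' does not cross within the range.
#'
#' @param inc an [incremental_effect_cost()] result.
#' @param level confidence level in (0, 1).
#' @param lambda_range search range for the crossings (USD per unit).
#' @return named vector `c(ci_lower =, ci_upper =)`, possibly `NA`.
#' @export
icer_confidence_bounds <- function(inc, level = 0.95,
                                   lambda_range = c(0, 5e5)) {
  if (!is.numeric(level) || level <= 0 || level >= 1)
    stop_field("level", "confidence level must be in (0, 1)")
  z <- qnorm(1 - (1 - level) / 2)
  lo_band <- function(l) inb_at(inc, l) - z * inb_se_at(inc, l)
  hi_band <- function(l) inb_at(inc, l) + z * inb_se_at(inc, l)
  grid <- seq(lambda_range[1], lambda_range[2], length.out = 20001)

  first_nonneg <- function(f) {
    v <- f(grid)
    i <- which(v >= 0)[1]
    if (is.na(i)) return(NA_real_)
    if (i == 1) return(grid[1])
    uniroot(f, lower = grid[i - 1], upper = grid[i], tol = 1e-6)$root
  }
  last_nonpos <- function(f) {
    v <- f(grid)
    idx <- which(v <= 0)
    if (!length(idx)) return(NA_real_)
    i <- idx[length(idx)]
    if (i == length(grid)) return(grid[i])
    uniroot(f, lower = grid[i], upper = grid[i + 1], tol = 1e-6)$root
  }
  c(ci_lower = last_nonpos(hi_band), ci_upper = first_nonneg(lo_band))
}

#' Variance inflation factors
#'
#' VIF of each regressor is `1 / (1 - R^2)` from regressing it on the
#' remaining columns; values above the threshold indicate severe
#' multicollinearity. Constant (zero-variance) columns are flagged with
#' an infinite VIF.
#'
#' @param x numeric design matrix (an `(Intercept)` column is ignored).
#' @param threshold flagging threshold (default 10).
#' @return object of class `vif_report`: data frame `vif` with per-term
#'   factors, `threshold`, and `flagged` term names.
#' @export
check_vif <- function(x, threshold = 10) {
  x <- as.matrix(x)
  keep <- setdiff(colnames(x), "(Intercept)")
  if (length(keep) < 2)
    stop("need at least 2 non-intercept columns", call. = FALSE)
  vifs <- vapply(keep, function(term) {
    y <- x[, term]
    if (var(y) == 0) return(Inf)
    others <- cbind(1, x[, setdiff(keep, term), drop = FALSE])
    res <- qr.resid(qr(others), y)
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    if (r2 >= 1 - 1e-12) Inf else 1 / (1 - r2)
  }, numeric(1))
  structure(list(vif = data.frame(term = keep, vif = unname(vifs)),
                 threshold = threshold,
                 flagged = keep[vifs > threshold]),
            class = "vif_report")
}

#' @export
print.nbr_fit <- function(x, ...) {
  cat(sprintf("NBR fit at lambda = %s: INB = %.1f (SE %.1f), p = %.4g, n = %d\n",
              format(x$lambda, big.mark = ","), x$inb, x$se, x$p_two_sided, x$n))
  invisible(x)
}

#' @export
print.incremental_estimates <- function(x, ...) {
  cat(sprintf("Adjusted increments (n = %d): dE = %.5f (SE %.5f), dC = %.0f (SE %.0f), cov = %.3g\n",
              x$n, x$delta_e, sqrt(x$var_e), x$delta_c, sqrt(x$var_c),
              x$cov_ec))
  invisible(x)
}
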