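# Monotone multiple imputation by sequential logistic regression, and
# Rubin's-rules pooling of estimates computed on the completed datasets.
#
# The imputed variables and their monotone order are fixed:
# birth_country -> comorbidity -> cancer_stage. Each multilevel variable
# is imputed as an ordered sequence of binary logistic models (level 1 vs
# rest, then level 2 vs rest among the remainder, ...), matching the
# sequential monotone-logistic procedure. Per imputation, model
# parameters are drawn from their approximate sampling distribution
# (proper imputation), so the m completed datasets differ.

MONOTONE_ORDER <- c("birth_country", "comorbidity", "cancer_stage")

#' Imputation configuration
#'
#' @param m number of imputations (>= 2; default 5).
#' @param seed integer seed for the imputation draws.
#' @param predictor_set covariate names entering every imputation model;
#'   defaults to the always-observed analysis covariates plus the
#'   treated indicator.
#' @param ridge ridge penalty stabilising the sequential logistic fits
#'   against separation in small strata.
#' @return object of class `imputation_config`.
#' @export
imputation_config <- function(m = 5L, seed = 1L,
                              predictor_set = c("age_category", "sex",
                                                "income_quintile", "residence",
                                                "diabetes", "hiv",
                                                "liver_disease_stage",
                                                "screening", "dx_year_band",
                                                "treated"),
                              ridge = 1e-4) {
  if (!is.numeric(m) || m < 2) stop_field("m", "need at least 2 imputations")
  structure(list(m = as.integer(m), seed = as.integer(seed),
                 predictor_set = predictor_set, ridge = ridge),
            class = "imputation_config")
}

#' Check that a missingness pattern is monotone
#'
#' @param cohort cohort data frame.
#' @param order variable order defining monotonicity.
#' @return `TRUE` invisibly; errors if the pattern is not monotone.
#' @export
check_monotone <- function(cohort, order = MONOTONE_ORDER) {
  miss <- sapply(order, function(v) is.na(cohort[[v]]))
  for (j in seq_len(length(order) - 1)) {
    viol <- miss[, j] & !miss[, j + 1]
    if (any(viol))
      stop(sprintf(
        "missingness is not monotone: %d record(s) missing `%s` but observing `%s`; reorder the variables or monotonize the pattern first",
        sum(viol), order[j], order[j + 1]), call. = FALSE)
  }
  invisible(TRUE)
}

# Design matrix for the imputation models: intercept + dummies for the
# configured predictors (plus any earlier-ordered, already-complete
# imputed variables passed via `extra`).
imputation_design <- function(cohort, predictors, extra = character(0)) {
  if ("treated" %in% predictors && !"treated" %in% names(cohort) &&
      "treatment" %in% names(cohort))
    cohort$treated <- as.integer(cohort$treatment != "none")
  vars <- unique(c(intersect(predictors, names(cohort)), extra))
  f <- as.formula(paste("~", paste(vars, collapse = " + ")))
  model.matrix(f, data = droplevels(cohort))
}

# Draw imputed values for one categorical variable under one parameter
# draw: sequence of binary logits over the observed levels.
impute_one_variable <- function(cohort, target, predictors, ridge,
                                extra = character(0)) {
  obs <- !is.na(cohort[[target]])
  lv <- levels(droplevels(factor(cohort[[target]][obs])))
  x_all <- imputation_design(cohort, predictors, extra)
  fits <- list()
  for (j in seq_len(length(lv) - 1)) {
    pool <- obs & !(as.character(cohort[[target]]) %in% lv[seq_len(j - 1)])
    y <- as.integer(as.character(cohort[[target]][pool]) == lv[j])
    fits[[j]] <- ridge_logit(x_all[pool, , drop = FALSE], y, ridge = ridge)
  }
  function() {
    # one proper-imputation draw: sample parameters, then values
    betas <- lapply(fits, function(f)
      MASS::mvrnorm(1, f$coef, (f$vcov + t(f$vcov)) / 2))
    out <- as.character(cohort[[target]])
    todo <- which(!obs)
    remaining <- todo
    for (j in seq_len(length(lv) - 1)) {
      if (!length(remaining)) break
      p <- plogis(drop(x_all[remaining, , drop = FALSE] %*% betas[[j]]))
      take <- runif(length(remaining)) < p
      out[remaining[take]] <- lv[j]
      remaining <- remaining[!take]
    }
    out[remaining] <- lv[length(lv)]
    factor(out, levels = levels(cohort[[target]]))
  }
}

#' Monotone multiple imputation
#'
#' Produces `m` completed cohorts. Variables are imputed in the declared
#' monotone order; each model is fitted on the records observing the
#' target (where, by monotonicity, all earlier-ordered variables are also
#' observed) with the configured predictors plus the earlier-ordered
#' imputed variables. Categorical targets with more than two levels are
#' imputed through an ordered sequence of binary logistic models. One
#' parameter draw per imputation makes the completed datasets differ;
#' with no missing values the result is `m` identical copies.
#'
#' @param cohort cohort data frame whose missingness pattern is monotone
#'   in `birth_country -> comorbidity -> cancer_stage`.
#' @param config an [imputation_config()].
#' @return list of `m` completed cohort data frames.
#' @export
impute_monotone <- function(cohort, config = imputation_config()) {
  stopifnot(inherits(config, "imputation_config"))
  check_monotone(cohort)
  targets <- MONOTONE_ORDER[sapply(MONOTONE_ORDER,
                                   function(v) anyNA(cohort[[v]]))]
  set.seed(config$seed)
  out <- vector("list", config$m)
  if (!length(targets)) {
    for (k in seq_len(config$m)) out[[k]] <- cohort
    return(out)
  }
  for (k in seq_len(config$m)) {
    completed <- cohort
    done <- character(0)
    for (tv in targets) {
      # earlier-ordered variables are complete by now and enter as
      # predictors (sequential monotone procedure)
      extra <- setdiff(MONOTONE_ORDER[seq_len(match(tv, MONOTONE_ORDER) - 1)],
                       config$predictor_set)
      extra <- extra[!sapply(extra, function(v) anyNA(completed[[v]]))]
      drawer <- impute_one_variable(completed, tv, config$predictor_set,
                                    config$ridge, extra = extra)
      completed[[tv]] <- drawer()
      done <- c(done, tv)
    }
    out[[k]] <- completed
  }
  out
}

#' Pool estimates across imputations by Rubin's rules
#'
#' The pooled point estimate is the mean of the per-imputation points;
#' the total variance combines the mean within-imputation variance with
#' the between-imputation variance inflated by `(1 + 1/m)`.
#'
#' @param points per-imputation point estimates (length m >= 2).
#' @param variances per-imputation squared standard errors.
#' @return object of class `pooled_estimate`: `point`, `within_var`,
#'   `between_var`, `total_var`, `se`, `m`.
#' @export
pool_rubin <- function(points, variances) {
  if (length(points) < 2 || length(points) != length(variances))
    stop("need at least 2 (point, variance) pairs of equal length",
         call. = FALSE)
  m <- length(points)
  within <- mean(variances)
  between <- var(points)
  total <- within + (1 + 1 / m) * between
  structure(list(point = mean(points), within_var = within,
                 between_var = between, total_var = total,
                 se = sqrt(total), m = m),
            class = "pooled_estimate")
}

# Rubin pooling of the bivariate (delta_e, delta_c) estimate with its
# 2x2 within-imputation covariance matrices. Used to carry the
# effect/cost covariance into pooled ICER confidence bounds.
pool_rubin_bivariate <- function(points_e, points_c, covs) {
  m <- length(points_e)
  stopifnot(m >= 2, length(points_c) == m, length(covs) == m)
  pts <- cbind(points_e, points_c)
  within <- Reduce(`+`, covs) / m
  between <- var(pts)
  total <- within + (1 + 1 / m) * between
  list(delta_e = mean(points_e), delta_c = mean(points_c),
       var_e = total[1, 1], var_c = total[2, 2], cov_ec = total[1, 2], m = m)
}

#' @export
print.pooled_estimate <- function(x, ...) {
  cat(sprintf(
    "Pooled estimate (m = %d): %.5g (SE %.5g; within %.5g, between %.5g)\n",
    x$m, x$point, x$se, x$within_var, x$between_var))
  invisible(x)
}
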