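test_that("propensity scores reduce to group rates in saturated designs", {
  co <- data.frame(
    treatment = factor(rep(c("RFA", "none"), c(30, 70)),
                       levels = c("none", "RFA")))
  expect_equal(fit_propensity(co, design_spec(covariates = character(0))),
               rep(0.3, 100))
  # one balanced binary covariate, group treatment rates 0.2 / 0.4
  co2 <- data.frame(
    sex = factor(rep(c("F", "M"), each = 100)),
    treatment = factor(rep(c("RFA", "none", "RFA", "none"),
                           c(20, 80, 40, 60)), levels = c("none", "RFA")))
  sc <- fit_propensity(co2, design_spec(covariates = "sex"))
  expect_equal(sort(unique(round(sc, 10))), c(0.2, 0.4))
})

test_that("the propensity model recovers the known assignment log-odds", {
  spec <- recovery_spec(n = 10000, seed = 29)
  co <- generate_cohort(spec)
  covs <- c("age_category", "screening", "cancer_stage",
            "liver_disease_stage", "diabetes")
  co$treated <- as.integer(co$treatment != "none")
  fit <- glm(as.formula(paste("treated ~", paste(covs, collapse = "+"))),
             data = co, family = binomial())
  truth <- c("age_category80+" = -1.2, "screeningroutine" = 0.9,
             "cancer_stageIII-IV" = -1.3)
  se <- sqrt(diag(vcov(fit)))
  for (term in names(truth))
    expect_lt(abs(coef(fit)[[term]] - truth[[term]]), 2 * se[[term]])
  # package scores equal the fitted probabilities of the same model
  sc <- fit_propensity(co, design_spec(covariates = covs))
  expect_equal(sc, unname(fitted(fit)), tolerance = 1e-8)
})

test_that("person-level net benefit is lambda * effect - cost", {
  expect_equal(person_net_benefit(1.2, 40000, 50000), 20000)
  expect_equal(person_net_benefit(3.7, 1234, 0), -1234)
  expect_equal(person_net_benefit(0.88067, 13697, 50000), 30336.5)
  expect_error(person_net_benefit(1, 1, -5), "lambda")
})

test_that("fit_nbr at lambda 0 is the negative cost regression and degenerates safely", {
  spec <- recovery_spec(n = 600, seed = 41)
  co <- generate_cohort(spec)
  des <- design_spec()
  sc <- fit_propensity(co, des)
  f0 <- fit_nbr(co, 0, des, sc, effect = co$qaly_gained, cost = co$cost_usd)
  inc <- incremental_effect_cost(co, des, sc,
                                 effect = co$qaly_gained, cost = co$cost_usd)
  expect_equal(f0$inb, -inc$delta_c, tolerance = 1e-10)
  # zero-variance net benefit
  cz <- co
  fz <- fit_nbr(cz, 0, des, sc, effect = rep(1, 600), cost = rep(1, 600))
  expect_equal(fz$inb, 0)
  expect_equal(fz$se, 0)
})

test_that("fit_nbr equals lambda * delta_e - delta_c to machine precision", {
  spec <- recovery_spec(n = 1000, seed = 47)
  co <- generate_cohort(spec)
  des <- design_spec()
  sc <- fit_propensity(co, des)
  inc <- incremental_effect_cost(co, des, sc,
                                 effect = co$qaly_gained, cost = co$cost_usd)
  for (lam in c(0, 1000, 12345, 50000, 98765)) {
    f <- fit_nbr(co, lam, des, sc, effect = co$qaly_gained,
                 cost = co$cost_usd)
    expect_equal(f$inb, lam * inc$delta_e - inc$delta_c,
                 tolerance = 1e-9)
    expect_equal(f$se^2,
                 lam^2 * inc$var_e + inc$var_c - 2 * lam * inc$cov_ec,
                 tolerance = 1e-9)
  }
})

test_that("adjustment removes the confounding bias that the raw contrast carries", {
  set.seed(53)
  reps <- 30
  bias_adj_c <- bias_raw_c <- bias_adj_e <- bias_raw_e <- numeric(reps)
  des <- design_spec()
  for (r in seq_len(reps)) {
    co <- generate_cohort(recovery_spec(n = 2000, seed = 1000 + r))
    t <- co$treatment == "RFA"
    bias_raw_e[r] <- mean(co$qaly_gained[t]) - mean(co$qaly_gained[!t]) - 0.9
    bias_raw_c[r] <- mean(co$cost_usd[t]) - mean(co$cost_usd[!t]) - 14000
    inc <- incremental_effect_cost(co, des, fit_propensity(co, des),
                                   effect = co$qaly_gained,
                                   cost = co$cost_usd)
    bias_adj_e[r] <- inc$delta_e - 0.9
    bias_adj_c[r] <- inc$delta_c - 14000
  }
  expect_lt(abs(mean(bias_adj_e)), abs(mean(bias_raw_e)))
  expect_lt(abs(mean(bias_adj_c)), abs(mean(bias_raw_c)))
  # the raw contrast is materially confounded in these conditions
  expect_gt(abs(mean(bias_raw_e)), 0.05)
})

test_that("ICERs divide adjusted cost by adjusted effect with a division guard", {
  ic <- compute_icer(list(delta_e = 0.93455, delta_c = 2304))
  expect_equal(round(ic$ratio), 2465)
  ic2 <- compute_icer(list(delta_e = 0.88067, delta_c = 13697))
  expect_equal(round(ic2$ratio), 15553)
  und <- compute_icer(list(delta_e = 0, delta_c = 100))
  expect_true(und$undefined)
  expect_true(is.na(und$ratio))
})

test_that("ICER confidence bounds solve the band-crossing quadratic", {
  inc <- structure(list(delta_e = 1, delta_c = 50000, var_e = 0.01,
                        var_c = 1e8, cov_ec = 0), class = "incremental_estimates")
  got <- icer_confidence_bounds(inc, lambda_range = c(0, 5e5))
  # independent oracle: coarse scan + bisection on the band functions
  z <- qnorm(0.975)
  f_lo <- function(l) (l - 50000) - z * sqrt(0.01 * l^2 + 1e8)
  f_hi <- function(l) (l - 50000) + z * sqrt(0.01 * l^2 + 1e8)
  bisect <- function(f, lo, hi) {
    for (i in 1:200) {
      mid <- (lo + hi) / 2
      if (f(lo) * f(mid) <= 0) hi <- mid else lo <- mid
    }
    (lo + hi) / 2
  }
  scan <- seq(0, 5e5, by = 100)
  up_oracle <- bisect(f_lo, scan[max(which(f_lo(scan) < 0))],
                      scan[min(which(f_lo(scan) >= 0))])
  lo_oracle <- bisect(f_hi, scan[max(which(f_hi(scan) <= 0))],
                      scan[min(which(f_hi(scan) > 0))])
  expect_equal(unname(got["ci_upper"]), up_oracle, tolerance = 1e-4)
  expect_equal(unname(got["ci_lower"]), lo_oracle, tolerance = 1e-4)
  expect_lte(got[["ci_lower"]], 50000)
  expect_gte(got[["ci_upper"]], 50000)

  # degenerate variances collapse both bounds onto the ICER
  inc0 <- structure(list(delta_e = 2, delta_c = 90000, var_e = 0,
                         var_c = 0, cov_ec = 0), class = "incremental_estimates")
  b0 <- icer_confidence_bounds(inc0, lambda_range = c(0, 2e5))
  expect_equal(unname(b0["ci_lower"]), 45000, tolerance = 1)
  expect_equal(unname(b0["ci_upper"]), 45000, tolerance = 1)

  # band never confidently positive -> undefined upper bound
  incw <- structure(list(delta_e = 0.05, delta_c = 90000, var_e = 4,
                         var_c = 1e10, cov_ec = 0),
                    class = "incremental_estimates")
  bw <- icer_confidence_bounds(incw, lambda_range = c(0, 1e5))
  expect_true(is.na(bw[["ci_upper"]]))
  expect_error(icer_confidence_bounds(inc, level = 2), "level")
})

test_that("coverage of the adjusted incremental-effect CI is nominal", {
  # 200 replicates, n = 2,000, true dQALY = 0.9 under confounded assignment
  des <- design_spec()
  reps <- 200
  covered <- logical(reps)
  for (r in seq_len(reps)) {
    co <- generate_cohort(recovery_spec(n = 2000, seed = 20000 + r))
    inc <- incremental_effect_cost(co, des, fit_propensity(co, des),
                                   effect = co$qaly_gained,
                                   cost = co$cost_usd)
    half <- 1.96 * sqrt(inc$var_e)
    covered[r] <- abs(inc$delta_e - 0.9) <= half
  }
  expect_gte(mean(covered), 0.90)
  expect_lte(mean(covered), 0.99)
})

test_that("variance inflation factors follow the 1/(1-R^2) definition", {
  # centred, mutually orthogonal contrast columns
  x <- cbind(a = rep(c(-1, 1), 50),
             b = rep(c(-1, -1, 1, 1), 25),
             c = rep(c(-1, 1, 1, -1), 25))
  v <- check_vif(x)
  expect_equal(v$vif$vif, rep(1, 3), tolerance = 1e-8)
  expect_length(v$flagged, 0)
  # engineered R^2 = 0.9 -> VIF 10
  z1 <- rnorm(1000)
  noise <- rnorm(1000)
  z2 <- z1 * sqrt(0.9) + noise * sqrt(0.1)
  z1 <- scale(z1)[, 1]; z2 <- scale(z2)[, 1]
  # orthogonalise the noise construction exactly
  r <- 0.94868
  xx <- cbind(p = z1, q = r * z1 + sqrt(1 - r^2) * scale(resid(lm(noise ~ z1)))[, 1])
  vv <- check_vif(xx)
  expect_equal(vv$vif$vif, rep(10, 2), tolerance = 0.01)
  # duplicated column -> infinite VIF, flagged
  dup <- cbind(u = z1, v = z1)
  vd <- check_vif(dup)
  expect_true(all(is.infinite(vd$vif$vif)))
  expect_setequal(vd$flagged, c("u", "v"))
})
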