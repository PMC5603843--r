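test_that("age at death follows the categorical-age and stage-survival rules", {
  # died during follow-up
  dead <- estimate_age_at_death("60-69", "II", 2005, 2008)
  expect_equal(dead$age_at_death, 68)
  # alive, expected death beyond the admin end
  alive <- estimate_age_at_death("<60", "I", 2009, NA)
  expect_equal(alive$death_year, 2014L)
  expect_equal(alive$age_at_death, 60)
  # alive but expected death inside the window -> year after admin end
  late <- estimate_age_at_death("70-79", "III-IV", 2005, NA)
  expect_equal(late$death_year, 2012L)
  expect_equal(late$age_at_death, 82)
  expect_error(estimate_age_at_death("<60", NA, 2005, NA), "imputation")
})

test_that("PYLL is the life-table lookup, discounted pro rata", {
  tab <- flat_life_table(15)
  expect_equal(compute_pyll(68, "M", tab, discount_spec(0)), 15)
  tab2 <- flat_life_table(2)
  expect_equal(compute_pyll(68, "M", tab2, discount_spec(0.03)),
               1 + 1 / 1.03, tolerance = 1e-9)
  tab3 <- flat_life_table(10.5)
  expect_equal(compute_pyll(50, "F", tab3, discount_spec(0)), 10.5)
  # fractional final year discounted pro rata
  expect_equal(compute_pyll(50, "F", flat_life_table(1.5), discount_spec(0.03)),
               1 + 0.5 / 1.03, tolerance = 1e-9)
  expect_error(compute_pyll(200, "M", tab, discount_spec(0)), "covers ages")
})

test_that("QALYL adds utility-weighted PYLL and per-year decrements", {
  ut <- test_utilities(0.85)
  got <- compute_qalyl(10, c("decompensated_cirrhosis", "incurable_hcc"),
                       ut, discount_spec(0))
  expect_equal(got, 0.85 * 10 + (0.85 - 0.66) + (0.85 - 0.40))
  # all stage utilities at the reference -> pure weighted PYLL
  ref_only <- utility_table(0.8, data.frame(state = "s", base = 0.8,
                                            low = 0.8, high = 0.8))
  expect_equal(compute_qalyl(7, rep("s", 3), ref_only, discount_spec(0)),
               0.8 * 7)
  one <- utility_table(1, data.frame(state = "incurable_hcc", base = 0.40,
                                     low = 0.32, high = 0.48))
  expect_equal(compute_qalyl(0, "incurable_hcc", one, discount_spec(0)), 0.60)
  expect_error(compute_qalyl(1, "nope", ut, discount_spec(0)),
               "supported")
})

test_that("QALYL is monotone in the utilities", {
  mk <- function(u_state, ref) {
    ut <- utility_table(ref, data.frame(state = "s", base = u_state,
                                        low = u_state, high = u_state))
    compute_qalyl(5, rep("s", 4), ut, discount_spec(0.03))
  }
  # non-increasing in the stage utility, non-decreasing in the reference
  expect_gt(mk(0.4, 0.85), mk(0.6, 0.85))
  expect_gt(mk(0.5, 0.9), mk(0.5, 0.8))
})

test_that("cost totals deflate, convert and discount correctly", {
  defl <- deflator_table(c("2010" = 100, "2013" = 106), ppp_factor = 0.94)
  led <- data.frame(year = 2010, amount = 100)
  expect_equal(total_cost(led, defl, discount_spec(0, 2013)),
               100 * 1.06 * 0.94)
  iddefl <- identity_deflators()
  expect_equal(total_cost(data.frame(year = 2013, amount = 250), iddefl,
                          discount_spec(0.03, 2013)), 250)
  expect_equal(total_cost(data.frame(year = 2014, amount = 100), iddefl,
                          discount_spec(0.03, 2013)), 100 / 1.03,
               tolerance = 1e-9)
  expect_error(total_cost(data.frame(year = 1990, amount = 1), defl,
                          discount_spec(0)), "1990")
})

test_that("discount_stream is the standard present-value sum", {
  ds <- discount_spec(0.03, 2013)
  expect_equal(discount_stream(2013:2015, rep(100, 3), ds),
               100 * (1 + 1 / 1.03 + 1 / 1.03^2), tolerance = 1e-9)
  expect_equal(discount_stream(2013:2015, rep(100, 3), discount_spec(0, 2013)),
               300)
  expect_equal(discount_stream(integer(0), numeric(0), ds), 0)
})

test_that("later death means lower PYLL with a declining life table", {
  tab <- toy_life_table()
  early <- compute_pyll(65, "M", tab, discount_spec(0.03))
  late <- compute_pyll(75, "M", tab, discount_spec(0.03))
  expect_gt(early, late)
})

test_that("person_effects is internally consistent on a generated cohort", {
  spec <- recovery_spec(n = 400, seed = 19)
  co <- generate_cohort(spec)
  eff <- person_effects(co, toy_life_table(), test_utilities(),
                        toy_deflator_table(), discount_spec(0.03))
  expect_equal(nrow(eff), 400)
  expect_true(all(eff$pyll >= 0))
  expect_true(all(eff$qalyl >= 0))
  # QALYs cannot exceed life years when utilities are below 1
  expect_true(all(eff$qalys <= eff$life_years + 1e-12))
  expect_true(all(eff$total_cost >= 0))
  # zero discounting reproduces raw sums of the latent USD ledger
  eff0 <- person_effects(co, toy_life_table(), test_utilities(),
                         toy_deflator_table(), discount_spec(0))
  # at rate 0 the deflated ledger must reproduce the latent totals
  expect_equal(unname(eff0$total_cost), unname(co$cost_usd), tolerance = 1e-8)
})
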