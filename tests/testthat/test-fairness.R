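make_decile_table <- function(ej, density, parcel, level = "tract") {
  structure(data.frame(level = level,
                       unit_id = sprintf("T%03d", seq_along(ej)),
                       decile_ej = ej, decile_density = density,
                       decile_parcel = parcel, stringsAsFactors = FALSE),
            class = c("decile_table", "data.frame"))
}

make_demographics <- function(ids, level = "tract",
                              black = runif(length(ids)),
                              dep = runif(length(ids))) {
  data.frame(unit_id = ids, level = level, fraction_nh_black = black,
             deprivation_index = dep, stringsAsFactors = FALSE)
}

test_that("exposure errors are decile differences joined by unit id", {
  set.seed(61)
  parcel <- sample(2:9, 30, replace = TRUE)
  dt <- make_decile_table(parcel, parcel + 1, parcel)
  dem <- make_demographics(dt$unit_id)
  err <- exposure_errors(dt, dem)
  expect_true(all(err$error_ej == 0))
  expect_true(all(err$error_density == 1))
  expect_true(all(err$error_ej >= -9 & err$error_ej <= 9))
  # the join ignores demographic row order
  err2 <- exposure_errors(dt, dem[rev(seq_len(nrow(dem))), ])
  expect_equal(err, err2)
  # missing records are named
  expect_error(exposure_errors(dt, dem[-3, ]), dt$unit_id[3])
})

test_that("the regression slope equals the closed form with calibrated CI", {
  set.seed(62)
  # all-zero errors: slope 0, CI contains 0
  reg <- fairness_regression(rep(0, 20), rnorm(20))
  expect_equal(reg$slope, 0)
  expect_true(reg$ci_low <= 0 && reg$ci_high >= 0)
  # perfect fit on the raw scale: slope 2, zero-width CI
  x <- 1:10
  reg <- fairness_regression(2 * x, x, standardize = FALSE)
  expect_equal(reg$slope, 2)
  expect_lt(reg$ci_high - reg$ci_low, 1e-8)
  # closed-form equality on arbitrary inputs
  for (i in 1:20) {
    n <- sample(5:60, 1)
    y <- rnorm(n)
    xx <- rnorm(n)
    expect_equal(fairness_regression(y, xx, standardize = FALSE)$slope,
                 bf_slope(y, xx), tolerance = 1e-10)
  }
  expect_error(fairness_regression(rnorm(2), rnorm(2)), "n >= 3")
  expect_error(fairness_regression(rnorm(5), rep(1, 5)), "variance")
})

test_that("OLS recovers a standardized slope of -0.15 at n = 222", {
  set.seed(63)
  n_rep <- 500
  slopes <- numeric(n_rep)
  covered <- logical(n_rep)
  for (r in seq_len(n_rep)) {
    x <- rnorm(222)
    y <- -0.15 * x + rnorm(222)
    reg <- fairness_regression(y, x)
    slopes[r] <- reg$slope
    covered[r] <- reg$ci_low <= -0.15 && -0.15 <= reg$ci_high
  }
  expect_lt(abs(mean(slopes) - (-0.15)), 0.02)
  expect_gte(mean(covered), 0.93)
  expect_lte(mean(covered), 0.97)
})

test_that("fairness tau equals the agreement-module tau exactly", {
  set.seed(64)
  e <- sample(-5:5, 100, replace = TRUE)
  v <- rnorm(100)
  expect_identical(fairness_tau(e, v), kendall_tau(e, v))
  # strict monotone relations hit the bounds
  expect_equal(fairness_tau(1:20, sort(rnorm(20))), 1)
  expect_equal(fairness_tau(20:1, sort(rnorm(20))), -1)
  # independence keeps tau near zero
  expect_lt(abs(fairness_tau(sample(-9:9, 1000, TRUE), rnorm(1000))), 0.06)
})

test_that("assess_fairness emits the full measure-by-covariate grid", {
  set.seed(65)
  parcel <- sample(1:10, 50, replace = TRUE)
  dt <- make_decile_table(sample(1:10, 50, TRUE), sample(1:10, 50, TRUE),
                          parcel)
  err <- exposure_errors(dt, make_demographics(dt$unit_id))
  res <- assess_fairness(err)
  expect_equal(nrow(res), 4)
  expect_setequal(res$measure, c("ej_screen", "aadt_density"))
  expect_setequal(res$covariate, c("deprivation_index", "fraction_nh_black"))
  expect_true(all(res$ci_low <= res$slope & res$slope <= res$ci_high))
  # all-zero errors: nothing significant
  dt0 <- make_decile_table(parcel, parcel, parcel)
  err0 <- exposure_errors(dt0, make_demographics(dt0$unit_id))
  res0 <- suppressWarnings(assess_fairness(err0))
  expect_false(any(res0$significant))
})

test_that("a planted covariate-linked distortion is detected with the right sign", {
  county <- generate_county(small_config(seed = 66, n_block_groups = 120,
                                         county_width = 20000,
                                         county_height = 18000,
                                         n_road_segments = 400,
                                         n_parcels = 3000,
                                         demographic_road_correlation = 0.6))
  u <- county$units[county$units$level == "block_group", ]
  et <- compute_exposure_table(county$roads, county$parcels, u)
  # inflate the EJ measure where deprivation is high
  et_d <- distort_measure(et, county$demographics, "ej_screen",
                          "deprivation_index", strength = 2)
  err <- exposure_errors(decile_table(et_d), county$demographics)
  res <- assess_fairness(err)
  row <- res[res$measure == "ej_screen" &
               res$covariate == "deprivation_index", ]
  expect_true(row$significant)
  expect_gt(row$slope, 0)   # over-ranking where the covariate is high
  expect_gt(row$tau, 0)
})

test_that("null calibration and injection recovery are nominal", {
  null <- fairness_null_calibration(n = 222, n_rep = 200, seed = 67)
  expect_gt(null$ci_exclusion_rate, 0.01)
  expect_lt(null$ci_exclusion_rate, 0.10)
  expect_lt(null$mean_abs_kappa, 0.03)
  rec <- fairness_injection_recovery(n = 222, n_rep = 100, slope = -0.15,
                                     seed = 68)
  expect_lt(abs(rec$mean_slope - (-0.15)), 0.04)
  expect_gte(rec$sign_correct_rate, 0.9)
})

test_that("injected slopes of either sign are recovered nearly unbiased", {
  for (s in c(-0.3, -0.15, 0.15, 0.3)) {
    rec <- fairness_injection_recovery(n = 222, n_rep = 200, slope = s,
                                       seed = 69)
    expect_lt(abs(rec$mean_slope - s), 0.03)
    expect_equal(sign(rec$mean_slope), sign(s))
  }
})
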