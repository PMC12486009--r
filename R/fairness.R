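#' Decile-scale exposure errors joined with demographics
#'
#' The error of a candidate measure for a unit is its decile minus the
#' parcel-reference decile (an integer in `[-9, 9]`; positive means the
#' candidate over-ranks the unit's exposure).  Errors are joined by
#' `unit_id` with the unit's demographic covariates.
#'
#' @param deciles A [decile_table()].
#' @param demographics Data frame with columns `unit_id`, `level`,
#'   `fraction_nh_black`, `deprivation_index` covering every unit in
#'   `deciles`.
#' @return A data frame of class `error_table` with columns `level`,
#'   `unit_id`, `error_ej`, `error_density`, `fraction_nh_black`,
#'   `deprivation_index`.
#' @export
exposure_errors <- function(deciles, demographics) {
  dem <- demographics[demographics$level == deciles$level[1], , drop = FALSE]
  idx <- match(deciles$unit_id, dem$unit_id)
  if (anyNA(idx)) {
    stop("missing demographic record for unit(s): ",
         paste(deciles$unit_id[is.na(idx)], collapse = ", "), call. = FALSE)
  }
  structure(data.frame(
    level = deciles$level, unit_id = deciles$unit_id,
    error_ej = deciles$decile_ej - deciles$decile_parcel,
    error_density = deciles$decile_density - deciles$decile_parcel,
    fraction_nh_black = dem$fraction_nh_black[idx],
    deprivation_index = dem$deprivation_index[idx],
    stringsAsFactors = FALSE),
    class = c("error_table", "data.frame"))
}

#' Linear regression of exposure errors on a demographic covariate
#'
#' Ordinary least squares of the decile-scale errors on the covariate
#' with an intercept and the classical homoskedastic 95% t confidence
#' interval.  By default the covariate is z-scored first, so slopes are
#' in decile-error units per covariate standard deviation and comparable
#' across covariates; set `standardize = FALSE` for the raw scale.
#'
#' @param errors Numeric error vector (decile differences).
#' @param covariate Numeric covariate, same length, nonzero variance.
#' @param standardize Z-score the covariate before fitting (default TRUE).
#' @param conf_level Confidence level (default 0.95).
#' @return A list with `slope`, `ci_low`, `ci_high`.
#' @export
fairness_regression <- function(errors, covariate, standardize = TRUE,
                                conf_level = 0.95) {
  check_pair(errors, covariate, "fairness_regression")
  n <- length(errors)
  if (n < 3) stop("fairness_regression: need n >= 3", call. = FALSE)
  if (stats::var(covariate) == 0) {
    stop("fairness_regression: covariate has zero variance", call. = FALSE)
  }
  x <- if (standardize) as.numeric(scale(covariate)) else covariate
  fit <- stats::lm(errors ~ x)
  slope <- unname(stats::coef(fit)[2])
  se <- sqrt(diag(stats::vcov(fit)))[2]
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 2)
  list(slope = slope, ci_low = unname(slope - tq * se),
       ci_high = unname(slope + tq * se))
}

#' Kendall's tau-b between exposure errors and a covariate
#'
#' Same contract as [kendall_tau()]; provided so the fairness output
#' carries the rank-correlation view of each scatter alongside the
#' regression slope.
#'
#' @inheritParams fairness_regression
#' @return Tau-b, or `NaN` with a warning when a vector is fully tied.
#' @export
fairness_tau <- function(errors, covariate) {
  kendall_tau(errors, covariate)
}

#' Fairness assessment across measures and covariates
#'
#' For each candidate measure (EJ-Screen proximity, AADT density) and
#' each covariate (material deprivation index, fraction non-Hispanic
#' Black), regresses the decile-scale errors on the covariate and reports
#' slope, 95% CI, tau-b and whether the CI excludes zero.  A significant
#' slope means the measure's misranking relative to the parcel reference
#' is systematically associated with that covariate -- the operational
#' definition of unfairness used here.
#'
#' @param errortable An [exposure_errors()] result.
#' @param standardize Passed to [fairness_regression()].
#' @return A data frame with 4 rows (2 measures x 2 covariates):
#'   `level`, `measure`, `covariate`, `slope`, `ci_low`, `ci_high`,
#'   `tau`, `n_units`, `significant`.
#' @export
assess_fairness <- function(errortable, standardize = TRUE) {
  grid <- expand.grid(measure = c("ej_screen", "aadt_density"),
                      covariate = c("deprivation_index",
                                    "fraction_nh_black"),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    err <- errortable[[if (grid$measure[i] == "ej_screen") "error_ej"
                       else "error_density"]]
    cov <- errortable[[grid$covariate[i]]]
    reg <- fairness_regression(err, cov, standardize = standardize)
    data.frame(level = errortable$level[1], measure = grid$measure[i],
               covariate = grid$covariate[i], slope = reg$slope,
               ci_low = reg$ci_low, ci_high = reg$ci_high,
               tau = fairness_tau(err, cov),
               n_units = length(err),
               significant = reg$ci_low > 0 | reg$ci_high < 0,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Inject a covariate-linked distortion into an exposure table
#'
#' Multiplies one measure's values by `exp(strength * z)` where `z` is
#' the z-scored covariate of each unit, so the measure systematically
#' over-ranks (positive `strength`) or under-ranks (negative) units with
#' high covariate values.  This is synthetic machinery for validating
#' that the fairness audit recovers a planted bias; it has no real-data
#' counterpart.
#'
#' @param exposure An `exposure_table`.
#' @param demographics Demographics data frame covering the table's level.
#' @param measure Column to distort (`"ej_screen"` or `"aadt_density"`).
#' @param covariate `"deprivation_index"` or `"fraction_nh_black"`.
#' @param strength Distortion strength (log-scale per covariate SD).
#' @return The exposure table with the distorted column.
#' @export
distort_measure <- function(exposure, demographics, measure = "ej_screen",
                            covariate = "deprivation_index",
                            strength = 1) {
  dem <- demographics[demographics$level == exposure$level[1], , drop = FALSE]
  idx <- match(exposure$unit_id, dem$unit_id)
  z <- as.numeric(scale(dem[[covariate]][idx]))
  exposure[[measure]] <- exposure[[measure]] * exp(strength * z)
  exposure
}

#' Null calibration of the fairness audit
#'
#' Monte-Carlo check that the audit's error rates are nominal when
#' nothing is wrong: in each replicate the decile errors are differences
#' of two independent decile rankings (the null error distribution the
#' pipeline produces when a measure carries no signal) and the covariate
#' is independent noise.  Reports how often the 95% CI excludes zero
#' (nominal 5%) and the mean `|kappa|` between independently shuffled
#' decile vectors (nominal 0).
#'
#' @param n Units per replicate (default 222, a tract-scale count).
#' @param n_rep Number of replicates.
#' @param seed RNG seed.
#' @return List with `ci_exclusion_rate` and `mean_abs_kappa`.
#' @export
fairness_null_calibration <- function(n = 222, n_rep = 500, seed = 1) {
  set.seed(seed)
  excl <- logical(n_rep)
  ak <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    err <- to_deciles(stats::runif(n)) - to_deciles(stats::runif(n))
    covariate <- stats::rnorm(n)
    reg <- fairness_regression(err, covariate)
    excl[r] <- reg$ci_low > 0 | reg$ci_high < 0
    ak[r] <- abs(cohens_kappa(sample(to_deciles(stats::runif(n))),
                              sample(to_deciles(stats::runif(n)))))
  }
  list(ci_exclusion_rate = mean(excl), mean_abs_kappa = mean(ak))
}

#' Recovery of a planted fairness slope
#'
#' Monte-Carlo check that a planted association between decile errors and
#' a covariate is recovered: errors are `round(slope * z + e)` with
#' `z ~ N(0,1)` the standardized covariate and `e ~ N(0, noise_sd)`,
#' clamped to the feasible decile-error range `[-9, 9]`.
#'
#' @param n Units per replicate.
#' @param n_rep Number of replicates.
#' @param slope Planted slope on the standardized-covariate scale.
#' @param noise_sd Residual standard deviation.
#' @param seed RNG seed.
#' @return List with `mean_slope`, `sign_correct_rate` and the vector of
#'   per-replicate `slopes`.
#' @export
fairness_injection_recovery <- function(n = 222, n_rep = 200,
                                        slope = -0.15, noise_sd = 1,
                                        seed = 1) {
  set.seed(seed)
  slopes <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    z <- stats::rnorm(n)
    err <- pmin(pmax(round(slope * z + stats::rnorm(n, 0, noise_sd)), -9), 9)
    slopes[r] <- fairness_regression(err, z)$slope
  }
  list(mean_slope = mean(slopes),
       sign_correct_rate = mean(sign(slopes) == sign(slope)),
       slopes = slopes)
}
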