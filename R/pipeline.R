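#' @keywords internal
audit_levels <- function(roads, parcels, units, demographics,
                         params = measure_params(),
                         levels = c("block_group", "tract", "zcta"),
                         verbose = FALSE) {
  exposure <- deciles <- errors <- list()
  agreement <- fairness <- list()
  for (lv in levels) {
    u <- units[units$level == lv, , drop = FALSE]
    if (nrow(u) == 0) {
      stop("pipeline stage 'measure' failed: no units at level '", lv, "'",
           call. = FALSE)
    }
    et <- compute_exposure_table(roads, parcels, u, params)
    dt <- decile_table(et)
    err <- exposure_errors(dt, demographics)
    exposure[[lv]] <- et
    deciles[[lv]] <- dt
    errors[[lv]] <- err
    agreement[[lv]] <- assess_agreement(dt)
    fairness[[lv]] <- assess_fairness(err)
    if (verbose) {
      message(sprintf(
        "level %s: %d units, %d with zero parcel exposure, %d with no parcels",
        lv, nrow(et), sum(et$parcel_proximity == 0),
        sum(et$n_parcels_used == 0)))
    }
  }
  agreement <- do.call(rbind, agreement)
  fairness <- do.call(rbind, fairness)
  rownames(agreement) <- rownames(fairness) <- NULL
  if (nrow(agreement) != 2 * length(levels) ||
      nrow(fairness) != 4 * length(levels)) {
    stop("incomplete reporting grid: expected ", 2 * length(levels),
         " agreement and ", 4 * length(levels), " fairness rows",
         call. = FALSE)
  }
  structure(list(agreement = agreement, fairness = fairness,
                 exposure = exposure, deciles = deciles, errors = errors,
                 params = params, levels = levels,
                 provenance = list(
                   tool = "trapfair",
                   version = as.character(utils::packageVersion("trapfair")),
                   timestamp = format(Sys.time(), tz = "UTC",
                                      "%Y-%m-%dT%H:%M:%SZ"))),
            class = "trap_audit")
}

#' Run the full audit pipeline on a synthetic county
#'
#' Generates the county, computes the three exposure measures at each
#' geographic level, transforms them to within-level deciles, and
#' assesses agreement (vs the parcel reference) and fairness (errors vs
#' demographics).  With `output_dir` set, writes per-level exposure and
#' decile CSVs, `agreement.csv`, `fairness.csv`, per-level scatter CSVs,
#' a plain-text summary and a YAML echo of the resolved configuration;
#' rerunning with the same configuration reproduces the CSVs
#' byte-for-byte.
#'
#' @param config A [county_config()], a plain list of its fields, or the
#'   path to a YAML config file.
#' @param output_dir Optional output directory.
#' @param params A [measure_params()].
#' @param levels Geographic levels to audit.
#' @param seed Optional integer overriding the config's seed.
#' @param verbose Log per-stage unit counts.
#' @return A `trap_audit` object; components `agreement` (2 rows per
#'   level) and `fairness` (4 rows per level) hold the reporting grid.
#' @export
run_pipeline <- function(config = county_config(), output_dir = NULL,
                         params = measure_params(),
                         levels = c("block_group", "tract", "zcta"),
                         seed = NULL, verbose = FALSE) {
  if (is.character(config)) config <- read_config(config)
  if (!inherits(config, "county_config")) {
    config <- do.call(county_config, as.list(config))
  }
  if (!is.null(seed)) {
    config$seed <- as.integer(seed)
    validate_county_config(config)
  }
  county <- generate_county(config)
  audit <- audit_levels(county$roads, county$parcels, county$units,
                        county$demographics, params, levels,
                        verbose = verbose)
  audit$config <- config
  if (!is.null(output_dir)) write_audit(audit, output_dir)
  audit
}

#' Run the audit pipeline on user-supplied county files
#'
#' Same stages as [run_pipeline()] but reading roads, parcels, units and
#' demographics from files (the formats [write_county()] produces)
#' instead of generating them.  All geometries must share one projected
#' planar frame in meters; coordinates that fit inside longitude/latitude
#' ranges are rejected.  Demographics missing at some levels are filled
#' by [fill_demographics()].
#'
#' @param roads_path,parcels_path,units_path GeoJSON files (see
#'   [read_roads_geojson()], [read_parcels_geojson()],
#'   [read_units_geojson()]).
#' @param demographics_path Demographics CSV.
#' @inheritParams run_pipeline
#' @return A `trap_audit` object.
#' @export
run_real <- function(roads_path, parcels_path, units_path,
                     demographics_path, params = measure_params(),
                     output_dir = NULL,
                     levels = c("block_group", "tract", "zcta"),
                     verbose = FALSE) {
  roads <- read_roads_geojson(roads_path)
  parcels <- read_parcels_geojson(parcels_path)
  units <- read_units_geojson(units_path)
  demographics <- read_demographics_csv(demographics_path)
  if (nrow(roads) > 0) {
    rc <- do.call(rbind, roads$geometry)
    check_projected(rc[, 1], rc[, 2], "roads")
  }
  check_projected(parcels$x, parcels$y, "parcels")
  uc <- do.call(rbind, units$geometry)
  check_projected(uc[, 1], uc[, 2], "units")
  demographics <- fill_demographics(units, demographics)
  audit <- audit_levels(roads, parcels, units, demographics, params,
                        levels, verbose = verbose)
  if (!is.null(output_dir)) write_audit(audit, output_dir)
  audit
}

#' Write a `trap_audit`'s tables to a directory
#'
#' @param audit A `trap_audit`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_audit <- function(audit, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (lv in audit$levels) {
    utils::write.csv(audit$exposure[[lv]],
                     file.path(dir, paste0("exposure_", lv, ".csv")),
                     row.names = FALSE)
    utils::write.csv(audit$deciles[[lv]],
                     file.path(dir, paste0("deciles_", lv, ".csv")),
                     row.names = FALSE)
    utils::write.csv(audit$errors[[lv]],
                     file.path(dir, paste0("errors_", lv, ".csv")),
                     row.names = FALSE)
  }
  utils::write.csv(audit$agreement, file.path(dir, "agreement.csv"),
                   row.names = FALSE)
  utils::write.csv(audit$fairness, file.path(dir, "fairness.csv"),
                   row.names = FALSE)
  if (!is.null(audit$config)) {
    write_config(audit$config, file.path(dir, "config_echo.yaml"))
  }
  con <- file(file.path(dir, "summary.txt"), "w")
  on.exit(close(con))
  sink(con)
  on.exit(sink(), add = TRUE, after = FALSE)
  print(audit)
  invisible(dir)
}

#' @export
print.trap_audit <- function(x, digits = 3, ...) {
  cat("Traffic exposure aggregation audit (trapfair ",
      x$provenance$version, ")\n", sep = "")
  cat("Levels:", paste(x$levels, collapse = ", "), "\n\n")
  cat("Agreement with the parcel truck-traffic proximity (deciles):\n")
  a <- x$agreement
  a$good_agreement_fraction <- round(a$good_agreement_fraction, digits)
  a$kappa <- round(a$kappa, digits)
  a$tau <- round(a$tau, digits)
  print(a, row.names = FALSE)
  cat("\nFairness: decile-error regressions on demographics",
      "(slope per covariate SD):\n")
  f <- x$fairness
  for (cc in c("slope", "ci_low", "ci_high", "tau")) {
    f[[cc]] <- round(f[[cc]], digits)
  }
  print(f, row.names = FALSE)
  sig <- x$fairness[x$fairness$significant, , drop = FALSE]
  cat("\n", nrow(sig), " of ", nrow(x$fairness),
      " error regressions have a 95% CI excluding zero\n", sep = "")
  invisible(x)
}

#' @export
summary.trap_audit <- function(object, ...) {
  zero <- t(vapply(object$levels, function(lv) {
    et <- object$exposure[[lv]]
    c(n_units = nrow(et),
      zero_parcel_exposure = sum(et$parcel_proximity == 0),
      no_parcels = sum(et$n_parcels_used == 0),
      zero_ej = sum(et$ej_screen == 0))
  }, numeric(4)))
  out <- list(agreement = object$agreement, fairness = object$fairness,
              unit_diagnostics = as.data.frame(zero),
              provenance = object$provenance)
  class(out) <- "summary.trap_audit"
  out
}

#' @export
print.summary.trap_audit <- function(x, ...) {
  cat("Unit diagnostics (zero-exposure paths):\n")
  print(x$unit_diagnostics)
  cat("\nAgreement grid:\n")
  print(x$agreement, row.names = FALSE)
  cat("\nFairness grid:\n")
  print(x$fairness, row.names = FALSE)
  invisible(x)
}

#' Scatterplots of exposure errors against demographics
#'
#' One panel per (measure, covariate) pair at a chosen level, annotated
#' with Kendall's tau-b, mirroring the standard way these audits are
#' inspected visually.
#'
#' @param x A `trap_audit`.
#' @param level Which geographic level to plot (default `"tract"`).
#' @param ... Passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.trap_audit <- function(x, level = "tract", ...) {
  err <- x$errors[[level]]
  if (is.null(err)) stop("level '", level, "' not in audit", call. = FALSE)
  old <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2.5, 1))
  on.exit(graphics::par(old))
  panels <- expand.grid(m = c("error_ej", "error_density"),
                        v = c("deprivation_index", "fraction_nh_black"),
                        stringsAsFactors = FALSE)
  for (i in seq_len(nrow(panels))) {
    e <- err[[panels$m[i]]]
    v <- err[[panels$v[i]]]
    tau <- suppressWarnings(kendall_tau(e, v))
    graphics::plot(v, e, xlab = panels$v[i],
                   ylab = paste(panels$m[i], "(deciles)"),
                   main = sprintf("%s  τ = %.2f", panels$m[i], tau),
                   pch = 16, col = grDevices::adjustcolor("steelblue", 0.5),
                   ...)
    graphics::abline(h = 0, lty = 3)
    if (stats::var(v) > 0) {
      graphics::abline(stats::lm(e ~ v), col = "firebrick")
    }
  }
  invisible(x)
}
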