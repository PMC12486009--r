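#' Configuration for the synthetic county generator
#'
#' Bundles and validates every knob of [generate_county()].  The defaults
#' describe a mixed urban/suburban county of roughly 1,000 km^2 with 697
#' block groups and about 2,100 arterial road segments carrying
#' heavy-tailed traffic volumes -- the scale of county for which the three
#' exposure aggregation measures are designed to be compared.
#'
#' @param county_width,county_height County extent in meters (projected
#'   planar frame; the county is the rectangle `[0, width] x [0, height]`).
#' @param n_block_groups Number of block groups.  Tract and ZCTA counts are
#'   derived: each tract holds about `tracts_per_side_factor^2` block
#'   groups and each ZCTA about that many tracts.
#' @param tracts_per_side_factor Grid subdivision factor per nesting step
#'   (2 means a parent is split roughly 2 x 2).
#' @param n_road_segments Number of road segments (a long multi-vertex
#'   highway counts as one segment).
#' @param aadt_log_mean,aadt_log_sd Mean and SD of `log(AADT)`; AADT
#'   (annual average daily traffic, vehicles/day) is drawn log-normally.
#' @param truck_fraction_mean Mean fraction of AADT that is truck traffic,
#'   in `[0, 1]`; per-segment fractions are Beta-distributed around it.
#' @param n_parcels Number of parcels.
#' @param parcel_cluster_count Number of Gaussian residential clusters.
#' @param parcel_cluster_sd Cluster standard deviation in meters.
#' @param household_size_mean Mean household size in persons (sizes are
#'   `1 + Poisson(mean - 1)`, so every residential parcel houses someone).
#' @param demographic_road_correlation Target Spearman rank correlation, in
#'   `[-1, 1]`, between a unit's road-length density and its demographic
#'   covariates.  This is the injection knob for fairness experiments: at 0
#'   demographics are independent of traffic.
#' @param seed Integer RNG seed; identical configs give identical counties.
#'
#' @return An object of class `county_config` (a validated named list).
#' @seealso [generate_county()]
#' @export
county_config <- function(county_width = 33000,
                          county_height = 32000,
                          n_block_groups = 697,
                          tracts_per_side_factor = 2,
                          n_road_segments = 2098,
                          aadt_log_mean = 10.92,
                          aadt_log_sd = 0.9,
                          truck_fraction_mean = 0.08,
                          n_parcels = 20000,
                          parcel_cluster_count = 40,
                          parcel_cluster_sd = 1200,
                          household_size_mean = 2.5,
                          demographic_road_correlation = 0.45,
                          seed = 1L) {
  cfg <- list(county_width = county_width, county_height = county_height,
              n_block_groups = n_block_groups,
              tracts_per_side_factor = tracts_per_side_factor,
              n_road_segments = n_road_segments,
              aadt_log_mean = aadt_log_mean, aadt_log_sd = aadt_log_sd,
              truck_fraction_mean = truck_fraction_mean,
              n_parcels = n_parcels,
              parcel_cluster_count = parcel_cluster_count,
              parcel_cluster_sd = parcel_cluster_sd,
              household_size_mean = household_size_mean,
              demographic_road_correlation = demographic_road_correlation,
              seed = seed)
  validate_county_config(cfg)
  class(cfg) <- "county_config"
  cfg
}

validate_county_config <- function(cfg) {
  bad <- function(field, why) {
    stop("invalid county configuration: field '", field, "' ", why,
         call. = FALSE)
  }
  num1 <- function(field) {
    v <- cfg[[field]]
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v)) {
      bad(field, "must be a single finite number")
    }
    v
  }
  for (f in c("county_width", "county_height", "parcel_cluster_sd")) {
    if (num1(f) <= 0) bad(f, "must be > 0")
  }
  for (f in c("n_block_groups", "tracts_per_side_factor",
              "parcel_cluster_count")) {
    v <- num1(f)
    if (v < 1 || v != round(v)) bad(f, "must be an integer >= 1")
  }
  for (f in c("n_road_segments", "n_parcels")) {
    v <- num1(f)
    if (v < 0 || v != round(v)) bad(f, "must be a non-negative integer")
  }
  num1("aadt_log_mean")
  if (num1("aadt_log_sd") < 0) bad("aadt_log_sd", "must be >= 0")
  v <- num1("truck_fraction_mean")
  if (v < 0 || v > 1) bad("truck_fraction_mean", "must be in [0, 1]")
  if (num1("household_size_mean") < 1) {
    bad("household_size_mean", "must be >= 1")
  }
  v <- num1("demographic_road_correlation")
  if (v < -1 || v > 1) {
    bad("demographic_road_correlation", "must be in [-1, 1]")
  }
  v <- num1("seed")
  if (v != round(v)) bad("seed", "must be an integer")
  invisible(cfg)
}

# Split rectangle c(x0, y0, x1, y1) into exactly k sub-rectangles on a
# row-major grid with near-square cells; rows may hold unequal column
# counts so any k tiles exactly.
split_rect <- function(rect, k) {
  w <- rect[3] - rect[1]
  h <- rect[4] - rect[2]
  nr <- max(1L, min(k, as.integer(round(sqrt(k * h / w)))))
  per_row <- tabulate(rep(seq_len(nr), length.out = k), nbins = nr)
  out <- vector("list", k)
  idx <- 1L
  for (r in seq_len(nr)) {
    y0 <- rect[2] + (r - 1) * h / nr
    y1 <- rect[2] + r * h / nr
    nc <- per_row[r]
    for (cc in seq_len(nc)) {
      x0 <- rect[1] + (cc - 1) * w / nc
      x1 <- rect[1] + cc * w / nc
      out[[idx]] <- c(x0, y0, x1, y1)
      idx <- idx + 1L
    }
  }
  out
}

rect_poly <- function(r) {
  cbind(c(r[1], r[3], r[3], r[1]), c(r[2], r[2], r[4], r[4]))
}

# Build the nested block-group / tract / ZCTA partition.
build_units <- function(cfg) {
  f2 <- cfg$tracts_per_side_factor^2
  n_bg <- cfg$n_block_groups
  n_tr <- as.integer(ceiling(n_bg / f2))
  n_z <- as.integer(ceiling(n_tr / f2))
  county <- c(0, 0, cfg$county_width, cfg$county_height)

  z_rects <- split_rect(county, n_z)
  tr_per_z <- tabulate(rep(seq_len(n_z), length.out = n_tr), nbins = n_z)
  bg_per_tr <- tabulate(rep(seq_len(n_tr), length.out = n_bg), nbins = n_tr)

  units <- list()
  ti <- 0L
  bi <- 0L
  for (zi in seq_len(n_z)) {
    zid <- sprintf("Z%03d", zi)
    units[[length(units) + 1L]] <- list(unit_id = zid, level = "zcta",
                                        parent_id = NA_character_,
                                        rect = z_rects[[zi]])
    t_rects <- split_rect(z_rects[[zi]], tr_per_z[zi])
    for (tr in seq_along(t_rects)) {
      ti <- ti + 1L
      tid <- sprintf("T%04d", ti)
      units[[length(units) + 1L]] <- list(unit_id = tid, level = "tract",
                                          parent_id = zid,
                                          rect = t_rects[[tr]])
      b_rects <- split_rect(t_rects[[tr]], bg_per_tr[ti])
      for (bg in seq_along(b_rects)) {
        bi <- bi + 1L
        units[[length(units) + 1L]] <- list(
          unit_id = sprintf("B%05d", bi), level = "block_group",
          parent_id = tid, rect = b_rects[[bg]])
      }
    }
  }
  data.frame(
    unit_id = vapply(units, `[[`, "", "unit_id"),
    level = vapply(units, `[[`, "", "level"),
    parent_id = vapply(units, `[[`, "", "parent_id"),
    geometry = I(lapply(units, function(u) rect_poly(u$rect))),
    stringsAsFactors = FALSE
  )
}

build_roads <- function(cfg) {
  n <- cfg$n_road_segments
  w <- cfg$county_width
  h <- cfg$county_height
  empty <- data.frame(segment_id = character(0), aadt = numeric(0),
                      truck_aadt = numeric(0), road_class = character(0),
                      geometry = I(list()), stringsAsFactors = FALSE)
  if (n == 0) return(empty)

  n_hwy <- min(3L, n)
  geoms <- vector("list", n)
  # Long highways crossing the county, with gentle wiggle.
  for (i in seq_len(n_hwy)) {
    horiz <- i %% 2 == 0
    nv <- 20L
    along <- seq(0, if (horiz) w else h, length.out = nv)
    base <- stats::runif(1, 0.2, 0.8) * (if (horiz) h else w)
    amp <- 0.04 * (if (horiz) h else w)
    wig <- base + amp * sin(along / max(along) * 2 * pi +
                              stats::runif(1, 0, 2 * pi))
    geoms[[i]] <- if (horiz) cbind(along, wig) else cbind(wig, along)
  }
  # Short random chords scattered over the county.
  for (i in seq_len(n - n_hwy) + n_hwy) {
    repeat {
      cx <- stats::runif(1, 0, w)
      cy <- stats::runif(1, 0, h)
      th <- stats::runif(1, 0, pi)
      len <- stats::rlnorm(1, log(90), 0.7)
      ux <- cos(th)
      uy <- sin(th)
      a <- c(cx - ux * len / 2, cy - uy * len / 2)
      b <- c(cx + ux * len / 2, cy + uy * len / 2)
      seg <- rbind(pmin(pmax(a, 0), c(w, h)), pmin(pmax(b, 0), c(w, h)))
      if (sqrt(sum((seg[1, ] - seg[2, ])^2)) > 0) break
    }
    geoms[[i]] <- seg
  }
  aadt <- stats::rlnorm(n, cfg$aadt_log_mean, cfg$aadt_log_sd)
  m <- cfg$truck_fraction_mean
  conc <- 20
  frac <- if (m <= 0) rep(0, n) else if (m >= 1) rep(1, n) else {
    pmin(pmax(stats::rbeta(n, m * conc, (1 - m) * conc), 0), 1)
  }
  cls <- c(rep("principal_arterial", n_hwy),
           sample(c("principal_arterial", "minor_arterial", "other"),
                  n - n_hwy, replace = TRUE, prob = c(0.25, 0.55, 0.20)))
  data.frame(segment_id = sprintf("S%05d", seq_len(n)),
             aadt = aadt, truck_aadt = aadt * frac, road_class = cls,
             geometry = I(geoms), stringsAsFactors = FALSE)
}

build_parcels <- function(cfg) {
  n <- cfg$n_parcels
  w <- cfg$county_width
  h <- cfg$county_height
  if (n == 0) {
    return(data.frame(parcel_id = character(0), x = numeric(0),
                      y = numeric(0), is_residential = logical(0),
                      household_size = integer(0), stringsAsFactors = FALSE))
  }
  k <- cfg$parcel_cluster_count
  cx <- stats::runif(k, 0.05 * w, 0.95 * w)
  cy <- stats::runif(k, 0.05 * h, 0.95 * h)
  assign <- sample.int(k, n, replace = TRUE)
  x <- stats::rnorm(n, cx[assign], cfg$parcel_cluster_sd)
  y <- stats::rnorm(n, cy[assign], cfg$parcel_cluster_sd)
  # Truncate the mixture to the county by resampling strays.
  out <- which(x < 0 | x > w | y < 0 | y > h)
  while (length(out) > 0) {
    x[out] <- stats::rnorm(length(out), cx[assign[out]], cfg$parcel_cluster_sd)
    y[out] <- stats::rnorm(length(out), cy[assign[out]], cfg$parcel_cluster_sd)
    out <- out[x[out] < 0 | x[out] > w | y[out] < 0 | y[out] > h]
  }
  data.frame(parcel_id = sprintf("P%06d", seq_len(n)), x = x, y = y,
             is_residential = stats::runif(n) < 0.92,
             household_size = 1L +
               stats::rpois(n, max(cfg$household_size_mean - 1, 0)),
             stringsAsFactors = FALSE)
}

# Road-length density (meters of road per m^2) for each unit.
unit_road_density <- function(roads, units) {
  bbs <- roads_bboxes(roads)
  vapply(seq_len(nrow(units)), function(i) {
    poly <- units$geometry[[i]]
    bb <- poly_bbox(poly)
    cand <- which(bbs[, 1] <= bb[3] & bb[1] <= bbs[, 3] &
                    bbs[, 2] <= bb[4] & bb[2] <= bbs[, 4])
    tot <- 0
    for (j in cand) {
      tot <- tot + polyline_clip_length(roads$geometry[[j]], poly)
    }
    tot / polygon_area(poly)
  }, numeric(1))
}

# Gaussian-copula demographics with target Spearman correlation r against
# unit road density.  Latent Pearson rho = 2 sin(pi r / 6) inverts the
# normal-copula Spearman relation; ties in density are broken at random.
build_demographics <- function(roads, units, r) {
  n <- nrow(units)
  dens <- unit_road_density(roads, units)
  rk <- rank(dens, ties.method = "random")
  x <- stats::qnorm(rk / (n + 1))
  rho <- 2 * sin(pi * r / 6)
  mix <- function() {
    w <- rho * x + sqrt(max(1 - rho^2, 0)) * stats::rnorm(n)
    stats::pnorm(w)
  }
  data.frame(unit_id = units$unit_id, level = units$level,
             fraction_nh_black = stats::qbeta(mix(), 1.6, 4.8),
             deprivation_index = stats::qbeta(mix(), 4, 6),
             stringsAsFactors = FALSE)
}

#' Generate a seeded synthetic county
#'
#' Builds a self-consistent synthetic study area: three exactly nested
#' areal partitions (block groups within tracts within ZCTAs, by recursive
#' rectangular subdivision), arterial road segments with log-normal AADT
#' and Beta-distributed truck fractions, residential parcels drawn from a
#' truncated Gaussian cluster mixture, and per-unit demographics
#' (fraction non-Hispanic Black, material deprivation index) tied to unit
#' road density through a Gaussian copula at a controllable rank
#' correlation.  Identical configurations (including `seed`) reproduce the
#' county exactly; the caller's RNG state is left untouched.
#'
#' @param config A [county_config()].
#' @return An object of class `trap_county`: a list with data frames
#'   `roads` (`segment_id`, `aadt`, `truck_aadt`, `road_class`, and a
#'   `geometry` list column of coordinate matrices), `parcels`
#'   (`parcel_id`, `x`, `y`, `is_residential`, `household_size`), `units`
#'   (`unit_id`, `level`, `parent_id`, `geometry`), `demographics`
#'   (`unit_id`, `level`, `fraction_nh_black`, `deprivation_index`), plus
#'   the `config` used.
#' @examples
#' county <- generate_county(county_config(
#'   n_block_groups = 16, n_road_segments = 40, n_parcels = 300,
#'   county_width = 8000, county_height = 8000, seed = 42))
#' table(county$units$level)
#' @export
generate_county <- function(config) {
  if (!inherits(config, "county_config")) {
    config <- do.call(county_config, as.list(config))
  }
  validate_county_config(config)
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old_seed, envir = globalenv())
    }
  })
  set.seed(config$seed)
  units <- build_units(config)
  roads <- build_roads(config)
  parcels <- build_parcels(config)
  demographics <- build_demographics(roads, units,
                                     config$demographic_road_correlation)
  structure(list(roads = roads, parcels = parcels, units = units,
                 demographics = demographics, config = config),
            class = "trap_county")
}

#' @export
print.trap_county <- function(x, ...) {
  lv <- table(x$units$level)
  cat("Synthetic county", sprintf("(%.0f x %.0f m, seed %d)\n",
      x$config$county_width, x$config$county_height,
      as.integer(x$config$seed)))
  cat(sprintf("  units: %d block groups, %d tracts, %d ZCTAs\n",
              lv[["block_group"]], lv[["tract"]], lv[["zcta"]]))
  cat(sprintf("  roads: %d segments, total length %.0f m, total AADT %.0f\n",
              nrow(x$roads),
              sum(vapply(x$roads$geometry, polyline_length, numeric(1))),
              sum(x$roads$aadt)))
  cat(sprintf("  parcels: %d (%d residential)\n", nrow(x$parcels),
              sum(x$parcels$is_residential)))
  invisible(x)
}
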