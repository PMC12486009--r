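#' Parameters of the exposure measures
#'
#' @param ej_radius Search radius in meters around the unit centroid for
#'   the EJ-Screen-style proximity (default 500 m).
#' @param parcel_radius Search radius in meters around each residential
#'   parcel for the parcel truck-traffic proximity (default 400 m).
#' @param min_distance_floor Lower bound in meters applied to the
#'   centroid-to-road distance before inverse weighting, so a road passing
#'   through the centroid cannot contribute an unbounded weight.
#' @param arterial_classes Road classes counted as arterial by the two
#'   proximity measures (the AADT density uses every segment).
#' @param parcel_weighting `"household_size"` (default) weights each
#'   parcel's score by its household size in the across-parcel weighted
#'   median; `"unweighted"` treats parcels equally.
#' @param parcel_segment_reducer How a parcel's qualifying segments are
#'   reduced to one score: `"sum"` (default) or `"median"` of their truck
#'   AADT.
#' @param zero_exposure_value Value assigned when nothing qualifies (no
#'   arterial road in radius, or a unit without residential parcels).
#'   Kept numeric, not missing, so decile ranking stays complete.
#' @return An object of class `measure_params`.
#' @export
measure_params <- function(ej_radius = 500,
                           parcel_radius = 400,
                           min_distance_floor = 1,
                           arterial_classes = c("principal_arterial",
                                                "minor_arterial"),
                           parcel_weighting = c("household_size",
                                                "unweighted"),
                           parcel_segment_reducer = c("sum", "median"),
                           zero_exposure_value = 0) {
  stopifnot(is.numeric(ej_radius), length(ej_radius) == 1, ej_radius > 0,
            is.numeric(parcel_radius), length(parcel_radius) == 1,
            parcel_radius > 0,
            is.numeric(min_distance_floor), min_distance_floor > 0,
            is.character(arterial_classes))
  structure(list(ej_radius = ej_radius, parcel_radius = parcel_radius,
                 min_distance_floor = min_distance_floor,
                 arterial_classes = arterial_classes,
                 parcel_weighting = match.arg(parcel_weighting),
                 parcel_segment_reducer = match.arg(parcel_segment_reducer),
                 zero_exposure_value = zero_exposure_value),
            class = "measure_params")
}

arterial_roads <- function(roads, params) {
  roads[roads$road_class %in% params$arterial_classes, , drop = FALSE]
}

# Minimum distance from one point to each road polyline (via its edges).
point_to_roads_dist <- function(px, py, edges) {
  if (nrow(edges) == 0) return(numeric(0))
  d <- pt_seg_dist(px, py, edges[, "ax"], edges[, "ay"],
                   edges[, "bx"], edges[, "by"])
  o <- order(edges[, "seg"], d)
  first <- !duplicated(edges[o, "seg"])
  dmin <- d[o][first]
  names(dmin) <- edges[o, "seg"][first]
  dmin[order(as.integer(names(dmin)))]
}

#' EJ-Screen-style traffic proximity at the unit centroid
#'
#' Inverse-distance-weighted sum of AADT over arterial segments near the
#' areal unit's polygon centroid: `sum(AADT_i / max(d_i, floor))` over the
#' arterial segments whose nearest point lies within `ej_radius` of the
#' centroid, where `d_i` is the Euclidean centroid-to-segment distance.
#' A segment either qualifies whole or not at all; no length clipping is
#' involved (proximity is a point-distance concept).
#'
#' @param roads Road data frame (see [generate_county()]).
#' @param unit A single-row slice of a units data frame, or any list with
#'   a polygon coordinate matrix under `geometry`.
#' @param params A [measure_params()].
#' @return Exposure in vehicles/day per meter; `zero_exposure_value` when
#'   no arterial segment is in radius.
#' @export
ej_screen_proximity <- function(roads, unit, params = measure_params(),
                                edges = NULL) {
  poly <- unit_geometry(unit)
  check_polygon(poly)
  art <- arterial_roads(roads, params)
  if (nrow(art) == 0) return(params$zero_exposure_value)
  if (is.null(edges)) edges <- roads_edge_table(art)
  ctr <- polygon_centroid(poly)
  d <- point_to_roads_dist(ctr[1], ctr[2], edges)
  keep <- d <= params$ej_radius
  if (!any(keep)) return(params$zero_exposure_value)
  sum(art$aadt[keep] / pmax(d[keep], params$min_distance_floor))
}

#' Area-normalized AADT road density
#'
#' Sum over every road segment of its AADT times the length of its
#' geometric intersection with the unit polygon, divided by the unit's
#' area: vehicles/day per meter of unit width, a length-weighted traffic
#' density.  Segments that do not intersect the unit contribute nothing.
#'
#' @inheritParams ej_screen_proximity
#' @return Density in vehicles·day^-1·m^-1 (AADT-weighted road length per
#'   unit area).
#' @export
aadt_density <- function(roads, unit, bboxes = NULL) {
  poly <- unit_geometry(unit)
  check_polygon(poly)
  area <- polygon_area(poly)
  if (nrow(roads) == 0) return(0)
  if (is.null(bboxes)) bboxes <- roads_bboxes(roads)
  bb <- poly_bbox(poly)
  cand <- which(bboxes[, 1] <= bb[3] & bb[1] <= bboxes[, 3] &
                  bboxes[, 2] <= bb[4] & bb[2] <= bboxes[, 4])
  tot <- 0
  for (j in cand) {
    tot <- tot + roads$aadt[j] * polyline_clip_length(roads$geometry[[j]],
                                                      poly)
  }
  tot / area
}

# n x 4 matrix (xmin, ymin, xmax, ymax) of road polyline bounding boxes.
roads_bboxes <- function(roads) {
  n <- nrow(roads)
  out <- matrix(numeric(0), 0, 4)
  if (n > 0) {
    out <- t(vapply(roads$geometry, poly_bbox, numeric(4)))
  }
  out
}

# Truck-traffic score for each query point: reduce truck_aadt over the
# arterial segments within parcel_radius (0 when none qualifies).
parcel_point_scores <- function(roads, px, py, params, edges = NULL) {
  n <- length(px)
  art <- arterial_roads(roads, params)
  if (nrow(art) == 0 || n == 0) return(numeric(n))
  if (is.null(edges)) edges <- roads_edge_table(art)
  vapply(seq_len(n), function(i) {
    d <- point_to_roads_dist(px[i], py[i], edges)
    keep <- d <= params$parcel_radius
    if (!any(keep)) return(0)
    v <- art$truck_aadt[keep]
    if (params$parcel_segment_reducer == "sum") sum(v) else stats::median(v)
  }, numeric(1))
}

#' Weighted median
#'
#' The smallest value `s` such that the cumulative weight of observations
#' with value `<= s` reaches half the total weight.  With unit weights and
#' odd `n` this is the ordinary sample median.
#'
#' @param x Numeric values.
#' @param w Non-negative weights, same length as `x`.
#' @return A single numeric value.
#' @export
weighted_median <- function(x, w = rep(1, length(x))) {
  stopifnot(length(x) == length(w), all(w >= 0))
  keep <- w > 0
  x <- x[keep]
  w <- w[keep]
  if (length(x) == 0) stop("weighted_median: no positive-weight values",
                           call. = FALSE)
  o <- order(x)
  cw <- cumsum(w[o])
  x[o][which(cw >= sum(w) / 2)[1]]
}

#' Parcel-based truck-traffic proximity of an areal unit
#'
#' The reference measure: every residential parcel inside the unit gets a
#' score by reducing (sum by default) the truck AADT of arterial segments
#' within `parcel_radius` of the parcel point, and the unit's value is the
#' household-size-weighted median of those parcel scores.  Units without
#' residential parcels receive `zero_exposure_value`.
#'
#' @inheritParams ej_screen_proximity
#' @param parcels Parcel data frame with columns `x`, `y`,
#'   `is_residential`, `household_size`.
#' @param scores Optional precomputed per-parcel scores (one per row of
#'   `parcels`), used by [compute_exposure_table()] to avoid recomputing
#'   the parcel-to-road distances for every level.
#' @return Truck AADT in vehicles/day at the unit's weighted-median
#'   parcel, with attribute `n_parcels_used`.
#' @export
parcel_traffic_proximity <- function(roads, parcels, unit,
                                     params = measure_params(),
                                     scores = NULL) {
  poly <- unit_geometry(unit)
  check_polygon(poly)
  res <- which(parcels$is_residential)
  if (length(res) > 0) {
    px <- parcels$x[res]
    py <- parcels$y[res]
    bb <- poly_bbox(poly)
    cand <- res[px >= bb[1] & px <= bb[3] & py >= bb[2] & py <= bb[4]]
    inside <- cand[point_in_polygon(parcels$x[cand], parcels$y[cand], poly)]
  } else {
    inside <- integer(0)
  }
  if (length(inside) == 0) {
    return(structure(params$zero_exposure_value, n_parcels_used = 0L))
  }
  sc <- if (is.null(scores)) {
    parcel_point_scores(roads, parcels$x[inside], parcels$y[inside], params)
  } else {
    scores[inside]
  }
  w <- if (params$parcel_weighting == "household_size") {
    parcels$household_size[inside]
  } else {
    rep(1, length(inside))
  }
  structure(weighted_median(sc, w), n_parcels_used = length(inside))
}

unit_geometry <- function(unit) {
  if (is.data.frame(unit)) {
    stopifnot(nrow(unit) == 1)
    unit$geometry[[1]]
  } else if (is.list(unit) && !is.null(unit$geometry)) {
    g <- unit$geometry
    if (is.list(g)) g[[1]] else g
  } else if (is.matrix(unit)) {
    unit
  } else {
    stop("cannot extract a polygon from 'unit'", call. = FALSE)
  }
}

#' Exposure table: all three measures for every unit at one level
#'
#' Applies [ej_screen_proximity()], [aadt_density()] and
#' [parcel_traffic_proximity()] to each areal unit of a single geographic
#' level.  Per-parcel truck scores are computed once and shared across
#' units.  Rows are sorted by `unit_id`, so the result is invariant to the
#' input unit order.
#'
#' @inheritParams parcel_traffic_proximity
#' @param units Units data frame; all rows must share one `level`.
#' @return A data frame of class `exposure_table` with columns `level`,
#'   `unit_id`, `ej_screen`, `aadt_density`, `parcel_proximity`,
#'   `n_parcels_used`.
#' @export
compute_exposure_table <- function(roads, parcels, units,
                                   params = measure_params()) {
  lv <- unique(units$level)
  if (length(lv) != 1) {
    stop("units must all share one level; got: ",
         paste(lv, collapse = ", "), call. = FALSE)
  }
  units <- units[order(units$unit_id), , drop = FALSE]
  art_edges <- roads_edge_table(arterial_roads(roads, params))
  bboxes <- roads_bboxes(roads)
  scores <- rep(NA_real_, nrow(parcels))
  res <- which(parcels$is_residential)
  scores[res] <- parcel_point_scores(roads, parcels$x[res], parcels$y[res],
                                     params, edges = art_edges)
  n <- nrow(units)
  ej <- dens <- pp <- numeric(n)
  npar <- integer(n)
  for (i in seq_len(n)) {
    u <- units[i, , drop = FALSE]
    ej[i] <- ej_screen_proximity(roads, u, params, edges = art_edges)
    dens[i] <- aadt_density(roads, u, bboxes = bboxes)
    p <- parcel_traffic_proximity(roads, parcels, u, params, scores = scores)
    pp[i] <- as.numeric(p)
    npar[i] <- attr(p, "n_parcels_used")
  }
  structure(data.frame(level = lv, unit_id = units$unit_id, ej_screen = ej,
                       aadt_density = dens, parcel_proximity = pp,
                       n_parcels_used = npar, stringsAsFactors = FALSE,
                       row.names = NULL),
            class = c("exposure_table", "data.frame"))
}
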