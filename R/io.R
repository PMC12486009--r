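# File formats: GeoJSON for geometry (written/parsed with jsonlite at full
# double precision so a write/read cycle is lossless), CSV for tables,
# YAML for configuration.  All coordinates are planar meters.

geojson_feature <- function(geom_type, coords, props) {
  list(type = "Feature",
       geometry = list(type = geom_type, coordinates = coords),
       properties = props)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = I(17),
                       pretty = FALSE)
}

#' Write a synthetic county to disk
#'
#' Writes `roads.geojson` (LineString features with `segment_id`, `aadt`,
#' `truck_aadt`, `road_class`), `parcels.geojson` (Point features with
#' `parcel_id`, `is_residential`, `household_size`), `units.geojson`
#' (Polygon features at all three levels with `unit_id`, `level`,
#' `parent_id`), `demographics.csv` and `config.yaml` into a directory.
#' Doubles are serialized at 17 significant digits, so reading the files
#' back reproduces the in-memory county exactly.
#'
#' @param county A `trap_county` from [generate_county()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_county <- function(county, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  r <- county$roads
  write_geojson(lapply(seq_len(nrow(r)), function(i) {
    geojson_feature("LineString", unname(r$geometry[[i]]),
                    list(segment_id = r$segment_id[i], aadt = r$aadt[i],
                         truck_aadt = r$truck_aadt[i],
                         road_class = r$road_class[i]))
  }), file.path(dir, "roads.geojson"))

  p <- county$parcels
  write_geojson(lapply(seq_len(nrow(p)), function(i) {
    geojson_feature("Point", c(p$x[i], p$y[i]),
                    list(parcel_id = p$parcel_id[i],
                         is_residential = p$is_residential[i],
                         household_size = p$household_size[i]))
  }), file.path(dir, "parcels.geojson"))

  u <- county$units
  write_geojson(lapply(seq_len(nrow(u)), function(i) {
    ring <- u$geometry[[i]]
    ring <- unname(rbind(ring, ring[1, ]))  # GeoJSON rings are closed
    geojson_feature("Polygon", list(ring),
                    list(unit_id = u$unit_id[i], level = u$level[i],
                         parent_id = u$parent_id[i]))
  }), file.path(dir, "units.geojson"))

  write_demographics_csv(county$demographics,
                         file.path(dir, "demographics.csv"))
  if (!is.null(county$config)) {
    write_config(county$config, file.path(dir, "config.yaml"))
  }
  invisible(dir)
}

write_demographics_csv <- function(dem, path) {
  out <- data.frame(unit_id = dem$unit_id, level = dem$level,
                    fraction_nh_black = sprintf("%.17g",
                                                dem$fraction_nh_black),
                    deprivation_index = sprintf("%.17g",
                                                dem$deprivation_index),
                    stringsAsFactors = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
}

require_props <- function(props, needed, what) {
  miss <- setdiff(needed, names(props))
  if (length(miss) > 0) {
    stop("schema error in ", what, ": missing attribute(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

read_feature_collection <- function(path) {
  fc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
  if (is.null(fc$type) || fc$type != "FeatureCollection") {
    stop("schema error: ", path, " is not a GeoJSON FeatureCollection",
         call. = FALSE)
  }
  fc$features
}

coords_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(v) {
    c(as.numeric(v[[1]]), as.numeric(v[[2]]))
  }))
}

#' Read road segments from GeoJSON
#'
#' @param path A GeoJSON FeatureCollection of LineString features with
#'   properties `segment_id`, `aadt`, `truck_aadt`, `road_class`.
#' @return A roads data frame as produced by [generate_county()].
#' @export
read_roads_geojson <- function(path) {
  feats <- read_feature_collection(path)
  geoms <- vector("list", length(feats))
  props <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    require_props(f$properties,
                  c("segment_id", "aadt", "truck_aadt", "road_class"),
                  "roads")
    geoms[[i]] <- coords_matrix(f$geometry$coordinates)
    props[[i]] <- f$properties
  }
  data.frame(
    segment_id = vapply(props, function(p) as.character(p$segment_id), ""),
    aadt = vapply(props, function(p) as.numeric(p$aadt), 0),
    truck_aadt = vapply(props, function(p) as.numeric(p$truck_aadt), 0),
    road_class = vapply(props, function(p) as.character(p$road_class), ""),
    geometry = I(geoms), stringsAsFactors = FALSE)
}

#' Read parcels from GeoJSON
#'
#' @param path A GeoJSON FeatureCollection of Point features with
#'   properties `parcel_id`, `is_residential`, `household_size`.
#' @return A parcels data frame as produced by [generate_county()].
#' @export
read_parcels_geojson <- function(path) {
  feats <- read_feature_collection(path)
  for (f in feats) {
    require_props(f$properties,
                  c("parcel_id", "is_residential", "household_size"),
                  "parcels")
  }
  data.frame(
    parcel_id = vapply(feats, function(f)
      as.character(f$properties$parcel_id), ""),
    x = vapply(feats, function(f) as.numeric(f$geometry$coordinates[[1]]), 0),
    y = vapply(feats, function(f) as.numeric(f$geometry$coordinates[[2]]), 0),
    is_residential = vapply(feats, function(f)
      as.logical(f$properties$is_residential), NA),
    household_size = vapply(feats, function(f)
      as.integer(f$properties$household_size), 0L),
    stringsAsFactors = FALSE)
}

#' Read areal units from GeoJSON
#'
#' @param path A GeoJSON FeatureCollection of Polygon features with
#'   properties `unit_id`, `level`, `parent_id`; the exterior ring is
#'   used and its closing vertex dropped.
#' @return A units data frame as produced by [generate_county()].
#' @export
read_units_geojson <- function(path) {
  feats <- read_feature_collection(path)
  geoms <- vector("list", length(feats))
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    require_props(f$properties, c("unit_id", "level", "parent_id"), "units")
    ring <- coords_matrix(f$geometry$coordinates[[1]])
    n <- nrow(ring)
    if (n > 3 && all(ring[1, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
    geoms[[i]] <- ring
  }
  data.frame(
    unit_id = vapply(feats, function(f)
      as.character(f$properties$unit_id), ""),
    level = vapply(feats, function(f) as.character(f$properties$level), ""),
    parent_id = vapply(feats, function(f) {
      p <- f$properties$parent_id
      if (is.null(p) || length(p) == 0) NA_character_ else as.character(p)
    }, ""),
    geometry = I(geoms), stringsAsFactors = FALSE)
}

#' Read demographics from CSV
#'
#' @param path CSV with header
#'   `unit_id,level,fraction_nh_black,deprivation_index`.
#' @return A demographics data frame.
#' @export
read_demographics_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  require_props(d, c("unit_id", "level", "fraction_nh_black",
                     "deprivation_index"), "demographics")
  d
}

#' Read a county directory written by [write_county()]
#'
#' @param dir Directory containing `roads.geojson`, `parcels.geojson`,
#'   `units.geojson`, `demographics.csv` (and optionally `config.yaml`).
#' @return A `trap_county` list.
#' @export
read_county <- function(dir) {
  cfg_path <- file.path(dir, "config.yaml")
  structure(list(
    roads = read_roads_geojson(file.path(dir, "roads.geojson")),
    parcels = read_parcels_geojson(file.path(dir, "parcels.geojson")),
    units = read_units_geojson(file.path(dir, "units.geojson")),
    demographics = read_demographics_csv(file.path(dir, "demographics.csv")),
    config = if (file.exists(cfg_path)) read_config(cfg_path) else NULL),
    class = "trap_county")
}

#' Write / read a county configuration as YAML
#'
#' @param config A [county_config()].
#' @param path YAML file path.
#' @return `write_config` returns `path` invisibly; `read_config` returns
#'   a validated [county_config()].
#' @export
write_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path, precision = 15L)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  do.call(county_config, yaml::read_yaml(path))
}

# Heuristic: coordinates that all fit in [-180, 180] x [-90, 90] are
# almost certainly longitude/latitude degrees, on which metric buffers
# are meaningless.
check_projected <- function(x, y, what) {
  if (length(x) > 0 && all(abs(x) <= 180) && all(abs(y) <= 90)) {
    stop("coordinates in ", what, " look geographic (longitude/latitude ",
         "degrees); project the data to a planar metric CRS (meters) ",
         "before running", call. = FALSE)
  }
  invisible(TRUE)
}

#' Fill demographics to cover every geographic level
#'
#' Units of a level absent from the demographics table get covariates
#' from their neighbours in the nesting: a coarser unit takes the
#' area-weighted mean of its children's records; a finer unit inherits
#' its parent's record (the convention for a tract-level deprivation
#' index applied to block groups).
#'
#' @param units Units data frame with `parent_id` links.
#' @param demographics Demographics covering at least one level.
#' @return Demographics covering every level present in `units`.
#' @export
fill_demographics <- function(units, demographics) {
  lv_order <- c("block_group", "tract", "zcta")
  have <- intersect(lv_order, unique(demographics$level))
  need <- setdiff(intersect(lv_order, unique(units$level)), have)
  if (length(have) == 0) {
    stop("demographics cover no recognized level", call. = FALSE)
  }
  out <- demographics
  for (lv in need) {
    u <- units[units$level == lv, , drop = FALSE]
    child_lv <- lv_order[match(lv, lv_order) - 1][1]
    parent_lv <- if (match(lv, lv_order) < 3) lv_order[match(lv, lv_order) + 1]
                 else NA_character_
    if (!is.na(child_lv) && child_lv %in% unique(out$level)) {
      ch <- units[units$level == child_lv, , drop = FALSE]
      dem <- out[out$level == child_lv, , drop = FALSE]
      idx <- match(ch$unit_id, dem$unit_id)
      w <- vapply(ch$geometry, polygon_area, numeric(1))
      agg <- function(v) {
        vapply(u$unit_id, function(id) {
          sel <- which(ch$parent_id == id)
          sum(v[idx[sel]] * w[sel]) / sum(w[sel])
        }, numeric(1))
      }
      add <- data.frame(unit_id = u$unit_id, level = lv,
                        fraction_nh_black = agg(dem$fraction_nh_black),
                        deprivation_index = agg(dem$deprivation_index),
                        stringsAsFactors = FALSE)
    } else if (!is.na(parent_lv) && parent_lv %in% unique(out$level)) {
      dem <- out[out$level == parent_lv, , drop = FALSE]
      idx <- match(u$parent_id, dem$unit_id)
      add <- data.frame(unit_id = u$unit_id, level = lv,
                        fraction_nh_black = dem$fraction_nh_black[idx],
                        deprivation_index = dem$deprivation_index[idx],
                        stringsAsFactors = FALSE)
    } else {
      stop("cannot fill demographics for level '", lv,
           "': no adjacent level available", call. = FALSE)
    }
    out <- rbind(out, add)
  }
  out
}
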