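# Independent brute-force oracles.  Everything here avoids the package's
# own computational paths: distances by dense point sampling, clipped
# lengths by point-sampled inclusion with a direct convex-polygon inside
# test, ranks/contingency/pairs by explicit enumeration.

# Min distance from point p to segment a-b by sampling points along it.
bf_seg_dist <- function(p, a, b, k = 20001) {
  t <- seq(0, 1, length.out = k)
  min(sqrt((p[1] - (a[1] + t * (b[1] - a[1])))^2 +
             (p[2] - (a[2] + t * (b[2] - a[2])))^2))
}

bf_polyline_dist <- function(p, coords, k = 20001) {
  n <- nrow(coords)
  min(vapply(seq_len(n - 1), function(i) {
    bf_seg_dist(p, coords[i, ], coords[i + 1, ], k)
  }, numeric(1)))
}

# Inside test for a CONVEX polygon (counterclockwise or clockwise):
# the point must be on one side of every edge.
bf_inside_convex <- function(px, py, poly) {
  n <- nrow(poly)
  s <- rep(0, length(px))
  ok <- rep(TRUE, length(px))
  for (i in seq_len(n)) {
    j <- if (i == n) 1 else i + 1
    cr <- (poly[j, 1] - poly[i, 1]) * (py - poly[i, 2]) -
      (poly[j, 2] - poly[i, 2]) * (px - poly[i, 1])
    s_new <- sign(cr)
    ok <- ok & (s == 0 | s_new == 0 | s_new == s)
    s <- ifelse(s == 0, s_new, s)
  }
  ok
}

# Length of polyline inside a convex polygon by dense point sampling.
bf_clip_length <- function(coords, poly, k = 200001) {
  n <- nrow(coords)
  tot <- 0
  for (i in seq_len(n - 1)) {
    a <- coords[i, ]
    b <- coords[i + 1, ]
    len <- sqrt(sum((b - a)^2))
    if (len == 0) next
    t <- (seq_len(k) - 0.5) / k
    inside <- bf_inside_convex(a[1] + t * (b[1] - a[1]),
                               a[2] + t * (b[2] - a[2]), poly)
    tot <- tot + len * mean(inside)
  }
  tot
}

# Weighted median by explicit expansion over integer weights.
bf_weighted_median <- function(x, w) {
  e <- sort(rep(x, times = w))
  e[ceiling(length(e) / 2)]
}

# Deciles by explicit average-rank-then-ceiling arithmetic.
bf_deciles <- function(v) {
  n <- length(v)
  out <- integer(n)
  for (i in seq_len(n)) {
    less <- sum(v < v[i])
    ties <- sum(v == v[i])
    rk <- less + (1 + ties) / 2
    out[i] <- as.integer(ceiling(10 * rk / n))
  }
  out
}

bf_good_agreement <- function(a, b) {
  cnt <- 0
  for (i in seq_along(a)) if (abs(a[i] - b[i]) <= 1) cnt <- cnt + 1
  cnt / length(a)
}

# Kappa from an explicit 10 x 10 contingency table.
bf_kappa <- function(a, b) {
  tab <- matrix(0, 10, 10)
  for (i in seq_along(a)) tab[a[i], b[i]] <- tab[a[i], b[i]] + 1
  tab <- tab / length(a)
  po <- sum(diag(tab))
  pe <- sum(rowSums(tab) * colSums(tab))
  if (abs(1 - pe) < 1e-12) return(1)
  (po - pe) / (1 - pe)
}

# Tau-b by O(n^2) pair enumeration.
bf_tau <- function(a, b) {
  n <- length(a)
  C <- D <- tx <- ty <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      da <- a[j] - a[i]
      db <- b[j] - b[i]
      if (da == 0 && db == 0) {
        tx <- tx + 1
        ty <- ty + 1
      } else if (da == 0) {
        tx <- tx + 1
      } else if (db == 0) {
        ty <- ty + 1
      } else if (sign(da) == sign(db)) {
        C <- C + 1
      } else {
        D <- D + 1
      }
    }
  }
  n0 <- n * (n - 1) / 2
  (C - D) / sqrt((n0 - tx) * (n0 - ty))
}

# Closed-form OLS slope (cross-product ratio).
bf_slope <- function(y, x) {
  sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
}

# ---- tiny fixture builders -------------------------------------------------

make_roads <- function(geoms, aadt, truck_aadt = aadt * 0.1,
                       road_class = "principal_arterial") {
  n <- length(geoms)
  data.frame(segment_id = sprintf("S%03d", seq_len(n)), aadt = aadt,
             truck_aadt = truck_aadt,
             road_class = rep_len(road_class, n),
             geometry = I(geoms), stringsAsFactors = FALSE)
}

no_roads <- function() make_roads(list(), numeric(0))[0, ]

make_unit <- function(poly, unit_id = "U1", level = "tract",
                      parent_id = NA_character_) {
  data.frame(unit_id = unit_id, level = level, parent_id = parent_id,
             geometry = I(list(poly)), stringsAsFactors = FALSE)
}

rect <- function(x0, y0, x1, y1) {
  cbind(c(x0, x1, x1, x0), c(y0, y0, y1, y1))
}

make_parcels <- function(x, y, household_size = rep(1L, length(x)),
                         is_residential = rep(TRUE, length(x))) {
  data.frame(parcel_id = sprintf("P%03d", seq_along(x)), x = x, y = y,
             is_residential = is_residential,
             household_size = as.integer(household_size),
             stringsAsFactors = FALSE)
}

small_config <- function(seed = 7, ...) {
  args <- list(county_width = 12000, county_height = 10000,
               n_block_groups = 48, n_road_segments = 120,
               n_parcels = 1200, parcel_cluster_count = 8,
               parcel_cluster_sd = 800, seed = seed)
  do.call(county_config, utils::modifyList(args, list(...)))
}

# Seeded random convex polygon (a jittered regular k-gon).
random_convex_poly <- function(cx, cy, r, k = 6) {
  th <- sort(stats::runif(k, 0, 2 * pi))
  cbind(cx + r * cos(th), cy + r * sin(th))
}
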