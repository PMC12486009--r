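# Planar geometry primitives.
#
# Everything in this package works in a projected planar frame with
# coordinates in meters; all distances are 2-D Euclidean.  Polygons are
# n x 2 coordinate matrices, simple (non self-intersecting), with the
# closing vertex implicit.  Polylines are n x 2 matrices with n >= 2.

# Distance from point(s) (px, py) to segment(s) (ax, ay)-(bx, by).
# Vectorized over either the points or the segments (recycled).
pt_seg_dist <- function(px, py, ax, ay, bx, by) {
  dx <- bx - ax
  dy <- by - ay
  len2 <- dx * dx + dy * dy
  t <- ifelse(len2 > 0, ((px - ax) * dx + (py - ay) * dy) / len2, 0)
  t <- pmin(pmax(t, 0), 1)
  qx <- ax + t * dx
  qy <- ay + t * dy
  sqrt((px - qx)^2 + (py - qy)^2)
}

polyline_length <- function(coords) {
  sum(sqrt(diff(coords[, 1])^2 + diff(coords[, 2])^2))
}

# Split a polyline into an edge table (one row per consecutive vertex pair).
polyline_edges <- function(coords) {
  n <- nrow(coords)
  cbind(ax = coords[-n, 1], ay = coords[-n, 2],
        bx = coords[-1, 1], by = coords[-1, 2])
}

# Edge table for a whole road set, with the owning segment's row index.
roads_edge_table <- function(roads) {
  if (nrow(roads) == 0) {
    return(cbind(ax = numeric(0), ay = numeric(0), bx = numeric(0),
                 by = numeric(0), seg = numeric(0)))
  }
  parts <- lapply(seq_len(nrow(roads)), function(i) {
    e <- polyline_edges(roads$geometry[[i]])
    cbind(e, seg = rep(i, nrow(e)))
  })
  do.call(rbind, parts)
}

polygon_area <- function(coords) {
  x <- as.numeric(coords[, 1])
  y <- as.numeric(coords[, 2])
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  abs(sum(x * y2 - x2 * y)) / 2
}

polygon_centroid <- function(coords) {
  x <- as.numeric(coords[, 1])
  y <- as.numeric(coords[, 2])
  x2 <- c(x[-1], x[1])
  y2 <- c(y[-1], y[1])
  cr <- x * y2 - x2 * y
  a <- sum(cr) / 2
  if (abs(a) < .Machine$double.xmin) {
    return(c(mean(x), mean(y)))  # degenerate: fall back to vertex mean
  }
  c(sum((x + x2) * cr), sum((y + y2) * cr)) / (6 * a)
}

# Even-odd ray casting; vectorized over the query points.
point_in_polygon <- function(px, py, coords) {
  n <- nrow(coords)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- coords[i, 1]; yi <- coords[i, 2]
    xj <- coords[j, 1]; yj <- coords[j, 2]
    if (yi != yj) {
      crosses <- ((yi > py) != (yj > py)) &
        (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
      inside <- xor(inside, crosses)
    }
    j <- i
  }
  inside
}

# Length of the part of segment (a)-(b) lying inside a simple polygon.
# Parametric: cut the segment at every crossing with a polygon edge, then
# classify each piece by its midpoint.
seg_clip_length <- function(ax, ay, bx, by, poly) {
  dx <- bx - ax
  dy <- by - ay
  len <- sqrt(dx * dx + dy * dy)
  if (len == 0) return(0)
  cx <- poly[, 1]
  cy <- poly[, 2]
  ex <- c(cx[-1], cx[1]) - cx
  ey <- c(cy[-1], cy[1]) - cy
  denom <- dx * ey - dy * ex
  t <- ((cx - ax) * ey - (cy - ay) * ex) / denom
  s <- ((cx - ax) * dy - (cy - ay) * dx) / denom
  ok <- is.finite(t) & is.finite(s) & t > 0 & t < 1 & s >= 0 & s <= 1
  ts <- sort(unique(c(0, 1, t[ok])))
  mid <- (ts[-1] + ts[-length(ts)]) / 2
  inside <- point_in_polygon(ax + mid * dx, ay + mid * dy, poly)
  as.numeric(sum(diff(ts)[inside]) * len)
}

# Total clipped length of a road polyline inside a polygon.
polyline_clip_length <- function(coords, poly) {
  e <- polyline_edges(coords)
  s <- 0
  for (i in seq_len(nrow(e))) {
    s <- s + seg_clip_length(e[i, 1], e[i, 2], e[i, 3], e[i, 4], poly)
  }
  s
}

poly_bbox <- function(coords) {
  c(xmin = min(coords[, 1]), ymin = min(coords[, 2]),
    xmax = max(coords[, 1]), ymax = max(coords[, 2]))
}

bbox_overlap <- function(b1, b2) {
  b1[1] <= b2[3] && b2[1] <= b1[3] && b1[2] <= b2[4] && b2[2] <= b1[4]
}

# Clip an infinite line through (cx, cy) with direction (ux, uy) to the
# rectangle [0, w] x [0, h]; returns a 2 x 2 endpoint matrix or NULL.
clip_chord_to_rect <- function(cx, cy, ux, uy, w, h) {
  tmin <- -Inf
  tmax <- Inf
  for (axis in 1:2) {
    u <- if (axis == 1) ux else uy
    c0 <- if (axis == 1) cx else cy
    hi <- if (axis == 1) w else h
    if (u == 0) {
      if (c0 < 0 || c0 > hi) return(NULL)
    } else {
      t1 <- (0 - c0) / u
      t2 <- (hi - c0) / u
      tmin <- max(tmin, min(t1, t2))
      tmax <- min(tmax, max(t1, t2))
    }
  }
  if (tmin >= tmax) return(NULL)
  rbind(c(cx + tmin * ux, cy + tmin * uy),
        c(cx + tmax * ux, cy + tmax * uy))
}

check_polygon <- function(coords, what = "unit") {
  if (!is.matrix(coords) || ncol(coords) != 2 || nrow(coords) < 3 ||
      anyNA(coords)) {
    stop("degenerate ", what, " polygon: need an n x 2 matrix with n >= 3",
         call. = FALSE)
  }
  if (polygon_area(coords) <= 0) {
    stop("degenerate ", what, " polygon: zero area", call. = FALSE)
  }
  invisible(coords)
}
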