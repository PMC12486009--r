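# Unit square kilometer with centroid at (500, 500) used throughout.
unit1km <- function() make_unit(rect(0, 0, 1000, 1000))

test_that("EJ-Screen proximity follows the inverse-distance sum", {
  u <- unit1km()
  p <- measure_params()
  # nearest point 600 m away: outside the 500 m radius
  r <- make_roads(list(cbind(c(1100, 1100), c(0, 1000))), aadt = 10000)
  expect_equal(ej_screen_proximity(r, u, p), 0)
  # one segment at exactly 100 m -> 10000 / 100
  r <- make_roads(list(cbind(c(600, 600), c(0, 1000))), aadt = 10000)
  expect_equal(ej_screen_proximity(r, u, p), 100)
  # two segments at 100 m and 250 m -> 10000/100 + 5000/250
  r2 <- make_roads(list(cbind(c(600, 600), c(0, 1000)),
                        cbind(c(250, 750), c(250, 250))),
                   aadt = c(10000, 5000))
  expect_equal(ej_screen_proximity(r2, u, p), 120)
  # distances verified against the sampling oracle
  ctr <- c(500, 500)
  expect_equal(bf_polyline_dist(ctr, r2$geometry[[1]]), 100,
               tolerance = 1e-6)
  expect_equal(bf_polyline_dist(ctr, r2$geometry[[2]]), 250,
               tolerance = 1e-6)
})

test_that("EJ-Screen proximity honors class filter and distance floor", {
  u <- unit1km()
  p <- measure_params()
  # non-arterial roads are ignored
  r <- make_roads(list(cbind(c(600, 600), c(0, 1000))), aadt = 10000,
                  road_class = "other")
  expect_equal(ej_screen_proximity(r, u, p), 0)
  # a road through the centroid is capped by the 1 m floor
  r <- make_roads(list(cbind(c(0, 1000), c(500, 500))), aadt = 10000)
  expect_equal(ej_screen_proximity(r, u, p), 10000)
  # degenerate unit polygon
  expect_error(ej_screen_proximity(r, make_unit(cbind(c(0, 1, 2),
                                                      c(0, 1, 2))), p),
               "degenerate")
})

test_that("AADT density is the clipped length-weighted sum over area", {
  u <- unit1km()
  # 100 m fully inside, AADT 1000 -> 1000 * 100 / 1e6
  r <- make_roads(list(cbind(c(450, 550), c(500, 500))), aadt = 1000)
  expect_equal(aadt_density(r, u), 0.1)
  # all road classes count, not just arterials
  r$road_class <- "other"
  expect_equal(aadt_density(r, u), 0.1)
  # nothing intersecting -> 0
  r <- make_roads(list(cbind(c(2000, 2100), c(0, 0))), aadt = 1000)
  expect_equal(aadt_density(r, u), 0)
  # boundary-crossing segment counts only its inside part
  r <- make_roads(list(cbind(c(800, 1200), c(500, 500))), aadt = 1000)
  expect_equal(aadt_density(r, u), 1000 * 200 / 1e6)
})

test_that("parcel proximity reduces parcel scores by weighted median", {
  u <- unit1km()
  p <- measure_params()
  road <- make_roads(list(cbind(c(0, 1000), c(0, 0))), aadt = 50000,
                     truck_aadt = 5000)
  # three parcels, none within 400 m of the road -> 0
  far <- make_parcels(c(100, 500, 900), c(900, 950, 900))
  expect_equal(as.numeric(parcel_traffic_proximity(road, far, u, p)), 0)
  # median of distinct scores with equal weights (roads spaced so each
  # parcel is within 400 m of exactly one)
  r3 <- make_roads(list(cbind(c(0, 1000), c(50, 50)),
                        cbind(c(0, 1000), c(500, 500)),
                        cbind(c(0, 1000), c(950, 950))),
                   aadt = 1, truck_aadt = c(100, 200, 300))
  pk <- make_parcels(c(500, 500, 500), c(50, 500, 950))
  got <- parcel_traffic_proximity(r3, pk, u, p)
  expect_equal(as.numeric(got), 200)
  expect_equal(attr(got, "n_parcels_used"), 3L)
  # household weights pull the weighted median down: {100 w3, 300 w1}
  r2 <- make_roads(list(cbind(c(0, 1000), c(50, 50)),
                        cbind(c(0, 1000), c(950, 950))),
                   aadt = 1, truck_aadt = c(100, 300))
  pw <- make_parcels(c(500, 500), c(50, 950), household_size = c(3, 1))
  expect_equal(as.numeric(parcel_traffic_proximity(r2, pw, u, p)), 100)
  expect_equal(bf_weighted_median(c(100, 300), c(3, 1)), 100)
  # non-residential parcels and empty units use the zero convention
  pn <- make_parcels(500, 500, is_residential = FALSE)
  got <- parcel_traffic_proximity(r2, pn, u, p)
  expect_equal(as.numeric(got), 0)
  expect_equal(attr(got, "n_parcels_used"), 0L)
})

test_that("weighted median matches the expansion oracle and handles edge cases", {
  set.seed(41)
  for (i in 1:30) {
    n <- sample(1:12, 1)
    x <- sample(0:500, n)
    w <- sample(1:5, n, replace = TRUE)
    expect_equal(weighted_median(x, w), bf_weighted_median(x, w))
  }
  expect_equal(weighted_median(c(5, 1), c(1, 1)), 1)
  expect_error(weighted_median(numeric(0), numeric(0)), "weight")
})

test_that("measures are scale-equivariant in traffic volume", {
  set.seed(42)
  county <- generate_county(small_config(seed = 42, n_block_groups = 12,
                                         n_road_segments = 60,
                                         n_parcels = 300))
  u <- county$units[county$units$level == "tract", ]
  et1 <- compute_exposure_table(county$roads, county$parcels, u)
  roads2 <- county$roads
  roads2$aadt <- roads2$aadt * 3
  roads2$truck_aadt <- roads2$truck_aadt * 3
  et2 <- compute_exposure_table(roads2, county$parcels, u)
  expect_equal(et2$ej_screen, 3 * et1$ej_screen)
  expect_equal(et2$aadt_density, 3 * et1$aadt_density)
  expect_equal(et2$parcel_proximity, 3 * et1$parcel_proximity)
})

test_that("measures are invariant under rigid translation", {
  set.seed(43)
  county <- generate_county(small_config(seed = 43, n_block_groups = 12,
                                         n_road_segments = 60,
                                         n_parcels = 300))
  u <- county$units[county$units$level == "tract", ]
  et1 <- compute_exposure_table(county$roads, county$parcels, u)
  shift <- c(12345.6, -7890.1)
  roads2 <- county$roads
  roads2$geometry <- I(lapply(roads2$geometry, function(g) {
    sweep(g, 2, -shift)
  }))
  parcels2 <- county$parcels
  parcels2$x <- parcels2$x + shift[1]
  parcels2$y <- parcels2$y + shift[2]
  u2 <- u
  u2$geometry <- I(lapply(u$geometry, function(g) sweep(g, 2, -shift)))
  et2 <- compute_exposure_table(roads2, parcels2, u2)
  expect_equal(et2$ej_screen, et1$ej_screen, tolerance = 1e-9)
  expect_equal(et2$aadt_density, et1$aadt_density, tolerance = 1e-9)
  expect_equal(et2$parcel_proximity, et1$parcel_proximity, tolerance = 1e-9)
})

test_that("adding an in-radius arterial segment never decreases exposure", {
  u <- unit1km()
  p <- measure_params()
  set.seed(44)
  for (i in 1:10) {
    n <- sample(1:5, 1)
    geoms <- lapply(seq_len(n), function(j) {
      a <- runif(2, 0, 1000)
      rbind(a, a + runif(2, 10, 300))
    })
    r <- make_roads(geoms, aadt = runif(n, 100, 10000))
    ej0 <- ej_screen_proximity(r, u, p)
    den0 <- aadt_density(r, u)
    extra <- rbind(c(400, 450), c(600, 450))
    r2 <- rbind(r, make_roads(list(extra), aadt = 5000))
    expect_gte(ej_screen_proximity(r2, u, p), ej0)
    expect_gte(aadt_density(r2, u), den0)
  }
})

test_that("exposure table equals per-unit calls and ignores input order", {
  county <- generate_county(small_config(seed = 45, n_block_groups = 16,
                                         n_road_segments = 80,
                                         n_parcels = 400))
  u <- county$units[county$units$level == "block_group", ]
  et <- compute_exposure_table(county$roads, county$parcels, u)
  expect_equal(et$unit_id, sort(u$unit_id))
  p <- measure_params()
  for (i in seq_len(nrow(et))) {
    row <- u[u$unit_id == et$unit_id[i], , drop = FALSE]
    expect_identical(et$ej_screen[i],
                     ej_screen_proximity(county$roads, row, p))
    expect_identical(et$aadt_density[i], aadt_density(county$roads, row))
    expect_identical(et$parcel_proximity[i],
                     as.numeric(parcel_traffic_proximity(
                       county$roads, county$parcels, row, p)))
  }
  perm <- u[sample(nrow(u)), , drop = FALSE]
  expect_identical(compute_exposure_table(county$roads, county$parcels,
                                          perm),
                   et)
  mixed <- county$units[county$units$level %in% c("tract", "zcta"), ]
  expect_error(compute_exposure_table(county$roads, county$parcels, mixed),
               "level")
})
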