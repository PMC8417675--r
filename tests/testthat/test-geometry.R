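test_that("point counts use a closed disc and match a distance scan", {
  empty <- data.frame(x = numeric(0), y = numeric(0))
  expect_equal(count_points_in_radius(empty, c(0, 0), 500), 0L)
  # a point exactly on the boundary is counted
  ring <- data.frame(x = c(500, 500.0001), y = c(0, 0))
  expect_equal(count_points_in_radius(ring, c(0, 0), 500), 1L)
  set.seed(14)
  pts <- data.frame(x = runif(500, -1000, 1000), y = runif(500, -1000, 1000))
  got <- count_points_in_radius(pts, c(100, -50), 400)
  want <- sum(sqrt((pts$x - 100)^2 + (pts$y + 50)^2) <= 400)
  expect_equal(got, want)
  expect_error(count_points_in_radius(pts, c(0, 0), -1), "positive")
})

test_that("segment clipping is exact on chords and matches dense sampling", {
  r <- 300
  chord <- line_layer(list(rbind(c(-1000, 0), c(1000, 0))))
  expect_equal(length_in_radius(chord, c(0, 0), r), 2 * r)
  outside <- line_layer(list(rbind(c(1000, 1000), c(2000, 1000))))
  expect_equal(length_in_radius(outside, c(0, 0), r), 0)
  degenerate <- line_layer(list(rbind(c(0, 0), c(0, 0))))
  expect_equal(length_in_radius(degenerate, c(0, 0), r), 0)
  set.seed(26)
  for (i in 1:20) {
    p1 <- runif(2, -800, 800); p2 <- runif(2, -800, 800)
    seg <- line_layer(list(rbind(p1, p2)))
    got <- length_in_radius(seg, c(0, 0), 500)
    tt <- seq(0, 1, length.out = 200001)
    mid <- cbind(p1[1] + tt * (p2[1] - p1[1]), p1[2] + tt * (p2[2] - p1[2]))
    inside <- sqrt(mid[, 1]^2 + mid[, 2]^2) <= 500
    want <- mean(inside) * sqrt(sum((p2 - p1)^2))
    expect_lt(abs(got - want), max(0.001 * max(got, want), 0.05))
  }
})

test_that("polygon-in-disc areas are exact inside and 128-gon-accurate overall", {
  sq <- polygon_layer(list(rect_poly(-50, -50, 100, 100)))
  expect_equal(area_in_radius(sq, c(0, 0), 500), 100 * 100)
  # polygon covering the whole disc: area of the inscribed 128-gon
  big <- polygon_layer(list(rect_poly(-2000, -2000, 4000, 4000)))
  got <- area_in_radius(big, c(0, 0), 500)
  expect_lt(abs(got - pi * 500^2) / (pi * 500^2), 0.001)
  # clockwise-wound polygons give the same area
  cw <- polygon_layer(list(rect_poly(-50, -50, 100, 100)[4:1, ]))
  expect_equal(area_in_radius(cw, c(0, 0), 500), 10000)
  expect_error(
    area_in_radius(polygon_layer(list(rbind(c(0, 0), c(100, 100),
                                            c(100, 0), c(0, 100)))),
                   c(0, 0), 500, validate = TRUE),
    "self-intersecting")
})

test_that("clipped rectangle areas agree with a Monte-Carlo oracle", {
  set.seed(33)
  for (i in 1:10) {
    x0 <- runif(1, -700, 300); y0 <- runif(1, -700, 300)
    w <- runif(1, 100, 800); h <- runif(1, 100, 800)
    poly <- polygon_layer(list(rect_poly(x0, y0, w, h)))
    got <- area_in_radius(poly, c(0, 0), 500)
    n_mc <- 400000
    px <- runif(n_mc, x0, x0 + w); py <- runif(n_mc, y0, y0 + h)
    p_hat <- mean(px^2 + py^2 <= 500^2)
    want <- p_hat * w * h
    se <- w * h * sqrt(max(p_hat * (1 - p_hat), 1e-12) / n_mc)
    expect_lt(abs(got - want), 3 * se + 1e-6)
  }
})

test_that("VKT multiplies volume by clipped kilometres per class", {
  # one link crossing the disc with exactly 0.5 km inside
  link <- line_layer(list(rbind(c(-250, 0), c(250, 0))),
                     data.frame(vol_light = 1000, vol_heavy = 50))
  expect_equal(vkt_in_radius(link, c(0, 0), 400, "light"), 500)
  expect_equal(vkt_in_radius(link, c(0, 0), 400, "heavy"), 25)
  zero <- line_layer(list(rbind(c(-250, 0), c(250, 0))),
                     data.frame(vol_light = 0, vol_heavy = 0))
  expect_equal(vkt_in_radius(zero, c(0, 0), 400, "light"), 0)
  neg <- line_layer(list(rbind(c(0, 0), c(1, 1))),
                    data.frame(vol_light = -5, vol_heavy = 0))
  expect_error(vkt_in_radius(neg, c(0, 0), 400, "light"), "negative")
  set.seed(41)
  coords <- lapply(1:15, function(i) {
    p <- runif(2, -900, 900)
    rbind(p, p + runif(2, -600, 600))
  })
  net <- line_layer(coords, data.frame(vol_light = round(runif(15, 0, 5000)),
                                       vol_heavy = round(runif(15, 0, 500))))
  want <- sum(vapply(seq_along(coords), function(i)
    net$attrs$vol_light[i] *
      length_in_radius(line_layer(coords[i]), c(0, 0), 500) / 1000, 0))
  expect_equal(vkt_in_radius(net, c(0, 0), 500, "light"), want)
})

test_that("LUM index hits its closed-form values exactly", {
  # one class only: perfect homogeneity
  homo <- polygon_layer(list(rect_poly(-100, -100, 200, 200)),
                        data.frame(landuse_class = "residential",
                                   parcel_area_m2 = 4e4, floor_area_m2 = 0))
  expect_identical(lum_index(homo, c(0, 0), 500), 0)
  # equal areas of all six classes fully inside the buffer: maximum mix
  cls <- default_landuse_taxonomy()
  coords <- lapply(seq_along(cls), function(i)
    rect_poly(-180 + (i - 1) * 60, -30, 60, 60))
  mix <- polygon_layer(coords, data.frame(landuse_class = cls,
                                          parcel_area_m2 = 3600,
                                          floor_area_m2 = 0))
  expect_lt(abs(lum_index(mix, c(0, 0), 500) - 1), 1e-12)
  # two classes at shares 3:1 -> closed-form entropy
  two <- polygon_layer(list(rect_poly(0, 0, 30, 10), rect_poly(0, 20, 10, 10)),
                       data.frame(landuse_class = c("residential",
                                                    "commercial"),
                                  parcel_area_m2 = c(300, 100),
                                  floor_area_m2 = 0))
  want <- -(0.75 * log(0.75) + 0.25 * log(0.25)) / log(2)
  expect_equal(lum_index(two, c(15, 15), 400,
                         taxonomy = c("residential", "commercial")),
               want, tolerance = 1e-12)
  expect_equal(round(want, 4), 0.8113)
  # empty buffer: undefined, reported missing
  expect_true(is.na(lum_index(two, c(5000, 5000), 400)))
  expect_error(lum_index(two, c(0, 0), 400, taxonomy = "residential"),
               "k >= 2")
  # permutation of class labels leaves the index unchanged
  two_swapped <- polygon_layer(two$coords,
                               data.frame(landuse_class = c("commercial",
                                                            "residential"),
                                          parcel_area_m2 = c(300, 100),
                                          floor_area_m2 = 0))
  expect_equal(lum_index(two_swapped, c(15, 15), 400,
                         taxonomy = c("residential", "commercial")), want)
})

test_that("RetFAR divides full floor area by clipped retail land", {
  one <- polygon_layer(list(rect_poly(-25, -25, 50, 50)),
                       data.frame(landuse_class = "retail",
                                  parcel_area_m2 = 2500,
                                  floor_area_m2 = 5000))
  expect_equal(retfar(one, c(0, 0), 250), 2)
  none <- polygon_layer(list(rect_poly(-25, -25, 50, 50)),
                        data.frame(landuse_class = "residential",
                                   parcel_area_m2 = 2500,
                                   floor_area_m2 = 0))
  expect_equal(retfar(none, c(0, 0), 250), 0)
  neg <- polygon_layer(list(rect_poly(-25, -25, 50, 50)),
                       data.frame(landuse_class = "retail",
                                  parcel_area_m2 = 2500,
                                  floor_area_m2 = -1))
  expect_error(retfar(neg, c(0, 0)), "negative")
  set.seed(52)
  coords <- lapply(1:12, function(i) {
    p <- runif(2, -400, 300)
    rect_poly(p[1], p[2], runif(1, 40, 200), runif(1, 40, 200))
  })
  att <- data.frame(
    landuse_class = sample(c("retail", "residential"), 12, TRUE),
    parcel_area_m2 = 1,
    floor_area_m2 = round(runif(12, 500, 5000)))
  lay <- polygon_layer(coords, att)
  got <- retfar(lay, c(0, 0), 250)
  land <- vapply(seq_along(coords), function(i)
    area_in_radius(polygon_layer(coords[i], att[i, ]), c(0, 0), 250), 0)
  retail <- att$landuse_class == "retail" & land > 0
  want <- if (any(retail)) sum(att$floor_area_m2[retail]) / sum(land[att$landuse_class == "retail"])
  else 0
  expect_equal(got, want)
})

test_that("indicators are translation-invariant and monotone in radius", {
  cfg <- sim_config(n_patients = 5, region_side = 3000, seed = 77,
                    tract_size = 3000)
  sp <- generate_spatial_region(cfg)
  ctr <- c(1500, 1500)
  radii <- c(100, 250, 500, 800, 1200)
  vals <- function(layers, center) sapply(radii, function(r) c(
    count_points_in_radius(layers$points$bus_stops, center, r),
    length_in_radius(layers$lines$bike_paths, center, r),
    area_in_radius(layers$polygons$green, center, r),
    vkt_in_radius(layers$lines$traffic, center, r, "light")))
  v0 <- vals(sp$layers, ctr)
  expect_true(all(diff(t(v0)) >= 0))     # monotone in r
  shifted <- shift_layers(sp$layers, 12345.6, -9876.5)
  v1 <- vals(shifted, ctr + c(12345.6, -9876.5))
  expect_equal(v1, v0, tolerance = 1e-9)
  # buffers eventually converge to whole-layer totals
  total_bike <- sum(vapply(sp$layers$lines$bike_paths$coords, function(m)
    sum(sqrt(rowSums(diff(m)^2))), 0))
  expect_equal(length_in_radius(sp$layers$lines$bike_paths, ctr, 1e6),
               total_bike)
  expect_equal(count_points_in_radius(sp$layers$points$bus_stops, ctr, 1e6),
               nrow(sp$layers$points$bus_stops))
})

test_that("feature assembly matches indicator-by-indicator recomputation", {
  cfg <- sim_config(n_patients = 8, region_side = 2500, seed = 31,
                    tract_size = 1250)
  b <- simulate_study(cfg)
  pats <- b$patients[!is.na(b$patients$home_x), ]
  f <- assemble_features(pats, b$layers, b$tracts)
  for (i in seq_len(nrow(pats))) {
    ctr <- c(pats$home_x[i], pats$home_y[i])
    expect_equal(f$bus_stops_500[i],
                 count_points_in_radius(b$layers$points$bus_stops, ctr, 500))
    expect_equal(f$bike_len_500[i],
                 length_in_radius(b$layers$lines$bike_paths, ctr, 500))
    expect_equal(f$green_area_500[i],
                 area_in_radius(b$layers$polygons$green, ctr, 500))
    expect_equal(f$vkt_heavy_500[i],
                 vkt_in_radius(b$layers$lines$traffic, ctr, 500, "heavy"))
    expect_equal(f$lum_500[i], lum_index(b$layers$polygons$parcels, ctr, 500))
    expect_equal(f$retfar_250[i], retfar(b$layers$polygons$parcels, ctr, 250))
    expect_equal(f$pm25[i], b$tracts$pm25[b$tracts$tract_id == pats$tract_id[i]])
  }
  # identical homes get identical indicators
  twin <- pats[c(1, 1), ]
  twin$patient_id <- c("T1", "T2")
  ft <- assemble_features(twin, b$layers, b$tracts)
  expect_equal(ft[1, -1], ft[2, -1], ignore_attr = TRUE)
  # empty region: zero counts, missing LUM
  empty <- spatial_layers(
    points = list(bus_stops = data.frame(x = numeric(0), y = numeric(0)),
                  subway = data.frame(x = numeric(0), y = numeric(0)),
                  intersections = data.frame(x = numeric(0), y = numeric(0))),
    lines = list(bike_paths = line_layer(list()),
                 traffic = line_layer(list(), data.frame(vol_light = numeric(0),
                                                         vol_heavy = numeric(0)))),
    polygons = list(parcels = polygon_layer(list(),
                      data.frame(landuse_class = character(0),
                                 parcel_area_m2 = numeric(0),
                                 floor_area_m2 = numeric(0))),
                    green = polygon_layer(list()),
                    sidewalks = polygon_layer(list())))
  fe <- assemble_features(pats[1, ], empty, b$tracts)
  expect_equal(fe$bus_stops_500, 0L)
  expect_equal(fe$green_area_500, 0)
  expect_true(is.na(fe$lum_500))
  bad <- pats[1, ]; bad$tract_id <- "T999"
  expect_error(assemble_features(bad, b$layers, b$tracts), "unknown tract")
})

test_that("GeoJSON layers survive a write/read round trip", {
  cfg <- sim_config(n_patients = 3, region_side = 2000, seed = 8,
                    tract_size = 2000)
  sp <- generate_spatial_region(cfg)
  dir <- withr::local_tempdir()
  write_layers_geojson(sp$layers, dir)
  back <- read_layers_geojson(dir)
  ctr <- c(1000, 1000)
  expect_equal(count_points_in_radius(back$points$bus_stops, ctr, 600),
               count_points_in_radius(sp$layers$points$bus_stops, ctr, 600))
  expect_equal(vkt_in_radius(back$lines$traffic, ctr, 600, "light"),
               vkt_in_radius(sp$layers$lines$traffic, ctr, 600, "light"))
  expect_equal(lum_index(back$polygons$parcels, ctr, 600),
               lum_index(sp$layers$polygons$parcels, ctr, 600))
  expect_equal(retfar(back$polygons$parcels, ctr, 250),
               retfar(sp$layers$polygons$parcels, ctr, 250))
})
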