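# Buffer geometry on planar layers. All membership tests use the closed
# disc (distance <= r); boundary cases are measure-zero but determinism
# matters for tests. Polygon/disc intersections approximate the disc by an
# inscribed regular 128-gon, whose area deficit is under 0.1 %.

#' Count layer points inside a closed disc
#'
#' @param layer data frame with `x`, `y` columns
#' @param center numeric length-2 centre (metres)
#' @param r radius in metres
#' @return integer count
#' @export
count_points_in_radius <- function(layer, center, r) {
  if (r <= 0) stopf("radius must be positive")
  if (!nrow(layer)) return(0L)
  cpp_count_in_disc(layer$x, layer$y, center[1], center[2], r)
}

#' Total polyline length inside a closed disc
#'
#' Each segment is clipped against the circle exactly (quadratic in the
#' segment parameter); zero-length segments are ignored.
#'
#' @param lines a [line_layer()]
#' @param center,r disc centre and radius
#' @return metres of clipped length
#' @export
length_in_radius <- function(lines, center, r) {
  if (r <= 0) stopf("radius must be positive")
  if (!length(lines$coords)) return(0)
  sum(cpp_polyline_disc_length(lines$coords, center[1], center[2], r))
}

# cheap bbox prefilter: features whose box touches the disc's box
bbox_candidates <- function(layer, center, r) {
  if (is.null(layer$bbox) || !nrow(layer$bbox)) return(integer(0))
  b <- layer$bbox
  which(b[, 1] <= center[1] + r & b[, 3] >= center[1] - r &
        b[, 2] <= center[2] + r & b[, 4] >= center[2] - r)
}

# O(m^2) simple-polygon validity check (no crossing non-adjacent edges)
validate_polygon <- function(m) {
  nv <- nrow(m)
  if (nv > 1 && all(m[1, ] == m[nv, ])) { m <- m[-nv, , drop = FALSE]; nv <- nv - 1 }
  if (nv < 3) stopf("polygon needs at least 3 vertices")
  seg <- function(i) rbind(m[i, ], m[if (i == nv) 1 else i + 1, ])
  crosses <- function(a, b) {
    d1 <- (b[2, 1] - b[1, 1]) * (a[1, 2] - b[1, 2]) -
          (b[2, 2] - b[1, 2]) * (a[1, 1] - b[1, 1])
    d2 <- (b[2, 1] - b[1, 1]) * (a[2, 2] - b[1, 2]) -
          (b[2, 2] - b[1, 2]) * (a[2, 1] - b[1, 1])
    d3 <- (a[2, 1] - a[1, 1]) * (b[1, 2] - a[1, 2]) -
          (a[2, 2] - a[1, 2]) * (b[1, 1] - a[1, 1])
    d4 <- (a[2, 1] - a[1, 1]) * (b[2, 2] - a[1, 2]) -
          (a[2, 2] - a[1, 2]) * (b[2, 1] - a[1, 1])
    (d1 * d2 < 0) && (d3 * d4 < 0)
  }
  for (i in seq_len(nv - 2)) {
    jmax <- if (i == 1) nv - 1 else nv
    for (j in (i + 2):jmax)
      if (crosses(seg(i), seg(j)))
        stopf("self-intersecting polygon (edges %d and %d)", i, j)
  }
  invisible(TRUE)
}

#' Polygon area inside a closed disc
#'
#' Sum over features of the area of polygon intersected with the disc,
#' the disc approximated by a regular 128-gon (relative error < 0.1 %).
#' Self-intersecting polygons are rejected.
#'
#' @param polygons a [polygon_layer()]
#' @param center,r disc centre and radius
#' @param ngon number of polygon edges approximating the disc
#' @param validate check polygons for self-intersection first
#' @return square metres
#' @export
area_in_radius <- function(polygons, center, r, ngon = 128L,
                           validate = FALSE) {
  if (r <= 0) stopf("radius must be positive")
  cand <- bbox_candidates(polygons, center, r)
  if (!length(cand)) return(0)
  if (validate) lapply(polygons$coords[cand], validate_polygon)
  sum(cpp_polygon_disc_area(polygons$coords[cand], center[1], center[2],
                            r, as.integer(ngon)))
}

#' Vehicle kilometres travelled inside a buffer
#'
#' For each traffic link, daily volume of the vehicle class times the
#' link's clipped length inside the disc (in kilometres), summed. Light
#' duty covers passenger vehicles and taxis, heavy duty buses and trucks.
#'
#' @param traffic_lines a [line_layer()] whose attrs carry `vol_light`,
#'   `vol_heavy` daily volumes
#' @param center,r disc centre and radius
#' @param vehicle_class `"light"` or `"heavy"`
#' @return vehicle-kilometres (volume x km)
#' @export
vkt_in_radius <- function(traffic_lines, center, r,
                          vehicle_class = c("light", "heavy")) {
  vehicle_class <- match.arg(vehicle_class)
  if (r <= 0) stopf("radius must be positive")
  vol <- traffic_lines$attrs[[paste0("vol_", vehicle_class)]]
  if (is.null(vol)) stopf("traffic layer lacks vol_%s", vehicle_class)
  if (any(vol < 0)) stopf("negative traffic volume")
  if (!length(traffic_lines$coords)) return(0)
  len_m <- cpp_polyline_disc_length(traffic_lines$coords, center[1],
                                    center[2], r)
  sum(vol * len_m / 1000)
}

#' Default land-use taxonomy
#' @return character vector of 6 classes
#' @export
default_landuse_taxonomy <- function() {
  c("residential", "commercial", "retail", "industrial", "recreation",
    "other")
}

#' Entropy-based land-use mix (LUM) index in a buffer
#'
#' LUM = -(sum p_i log p_i) / log k over land-area shares p_i of the
#' land-use classes inside the disc, with 0 log 0 = 0. 0 means a single
#' class (homogeneity), 1 an equal mix of all k classes. By default k is
#' the taxonomy size, so buffers covering few classes score low; set
#' `k_observed = TRUE` to normalise by the classes actually present.
#' Returns NA when no parcel land falls in the buffer.
#'
#' @param parcels a [polygon_layer()] with a `landuse_class` attribute
#' @param center,r disc centre and radius
#' @param taxonomy land-use classes (k >= 2)
#' @param k_observed normalise by observed rather than taxonomy classes
#' @return LUM in \[0, 1\], or NA
#' @export
lum_index <- function(parcels, center, r,
                      taxonomy = default_landuse_taxonomy(),
                      k_observed = FALSE) {
  if (length(taxonomy) < 2) stopf("land-use taxonomy needs k >= 2 classes")
  comp <- landuse_composition(parcels, center, r, taxonomy)
  if (is.null(comp)) return(NA_real_)
  p <- comp$p[comp$p > 0]
  k <- if (k_observed) length(p) else length(taxonomy)
  if (k < 2) return(0)
  ent <- -sum(p * log(p))
  min(max(ent / log(k), 0), 1)
}

# land-area shares by class within the disc; NULL when no land present
landuse_composition <- function(parcels, center, r, taxonomy) {
  cand <- bbox_candidates(parcels, center, r)
  if (!length(cand)) return(NULL)
  areas <- cpp_polygon_disc_area(parcels$coords[cand], center[1], center[2],
                                 r, 128L)
  cls <- parcels$attrs$landuse_class[cand]
  tot <- tapply(areas, factor(cls, levels = taxonomy), sum, default = 0)
  tot[is.na(tot)] <- 0
  s <- sum(tot)
  if (s <= 0) return(NULL)
  list(p = as.numeric(tot) / s, classes = taxonomy, total_area = s)
}

#' Retail floor-area ratio (RetFAR) in a buffer
#'
#' Total retail building floor area of parcels intersecting the disc,
#' divided by the clipped retail land area inside the disc (floor area is
#' not spatially divisible, so intersecting parcels contribute their full
#' floor area). Buffers with no retail land return 0.
#'
#' @param parcels a [polygon_layer()] with `landuse_class` and
#'   `floor_area_m2` attributes
#' @param center centre of the buffer
#' @param r radius, metres (250 in the study design)
#' @return dimensionless ratio
#' @export
retfar <- function(parcels, center, r = 250) {
  if (r <= 0) stopf("radius must be positive")
  fa <- parcels$attrs$floor_area_m2
  if (any(fa < 0, na.rm = TRUE)) stopf("negative floor area")
  cand <- bbox_candidates(parcels, center, r)
  if (!length(cand)) return(0)
  cand <- cand[parcels$attrs$landuse_class[cand] == "retail"]
  if (!length(cand)) return(0)
  land <- cpp_polygon_disc_area(parcels$coords[cand], center[1], center[2],
                                r, 128L)
  touching <- land > 0
  if (!any(touching) || sum(land) <= 0) return(0)
  sum(fa[cand][touching]) / sum(land)
}
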