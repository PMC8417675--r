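# GeoJSON interchange for the spatial layers. Feature geometry maps to
# Point / LineString / Polygon (single outer ring); feature attributes map
# to GeoJSON properties. Documented property keys: landuse_class,
# parcel_area_m2, floor_area_m2 (parcels), vol_light, vol_heavy (traffic).

#' Write a layer to a GeoJSON FeatureCollection
#'
#' @param layer a point data frame, [line_layer()] or [polygon_layer()]
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_geojson <- function(layer, path) {
  feat <- function(geom, props) {
    list(type = "Feature",
         geometry = geom,
         properties = if (length(props)) props else setNames(list(), character(0)))
  }
  features <- if (is.data.frame(layer)) {
    attrs <- layer[setdiff(names(layer), c("x", "y"))]
    lapply(seq_len(nrow(layer)), function(i)
      feat(list(type = "Point", coordinates = c(layer$x[i], layer$y[i])),
           as.list(attrs[i, , drop = FALSE])))
  } else if (inherits(layer, "line_layer")) {
    lapply(seq_along(layer$coords), function(i)
      feat(list(type = "LineString",
                coordinates = unname(apply(layer$coords[[i]], 1, c,
                                           simplify = FALSE))),
           as.list(layer$attrs[i, , drop = FALSE])))
  } else if (inherits(layer, "polygon_layer")) {
    lapply(seq_along(layer$coords), function(i) {
      m <- layer$coords[[i]]
      if (nrow(m) < 1 || any(m[1, ] != m[nrow(m), ]))
        m <- rbind(m, m[1, ])  # GeoJSON rings are explicitly closed
      feat(list(type = "Polygon",
                coordinates = list(unname(apply(m, 1, c, simplify = FALSE)))),
           as.list(layer$attrs[i, , drop = FALSE]))
    })
  } else stopf("unsupported layer class")
  kind <- if (is.data.frame(layer)) "point"
          else if (inherits(layer, "line_layer")) "line" else "polygon"
  # layer_kind is a GeoJSON foreign member; it disambiguates empty layers
  doc <- list(type = "FeatureCollection", layer_kind = kind,
              features = features)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' Read a GeoJSON FeatureCollection into a layer object
#'
#' Point collections become data frames with x, y plus property columns;
#' LineString and Polygon collections become [line_layer()] /
#' [polygon_layer()] objects. Mixed-geometry collections are rejected.
#'
#' @param path GeoJSON file path
#' @return a layer object
#' @export
read_geojson <- function(path) {
  doc <- jsonlite::read_json(path)
  if (!identical(doc$type, "FeatureCollection"))
    stopf("%s is not a GeoJSON FeatureCollection", path)
  feats <- doc$features
  if (!length(feats)) {
    kind <- doc$layer_kind %||% "point"
    return(switch(kind,
                  point = data.frame(x = numeric(0), y = numeric(0)),
                  line = line_layer(list()),
                  polygon = polygon_layer(list())))
  }
  types <- unique(vapply(feats, function(f) f$geometry$type, ""))
  if (length(types) != 1)
    stopf("mixed geometry types in %s", path)
  props <- lapply(feats, function(f) f$properties)
  attrs <- if (all(vapply(props, length, 0L) == 0)) {
    data.frame(row.names = seq_along(feats))
  } else {
    do.call(rbind, lapply(props, function(p)
      as.data.frame(lapply(p, function(v) if (is.null(v)) NA else v),
                    stringsAsFactors = FALSE)))
  }
  if (types == "Point") {
    xy <- t(vapply(feats, function(f)
      as.numeric(unlist(f$geometry$coordinates)), numeric(2)))
    return(cbind(data.frame(x = xy[, 1], y = xy[, 2]), attrs))
  }
  coords <- lapply(feats, function(f) {
    cc <- f$geometry$coordinates
    if (types == "Polygon") cc <- cc[[1]]  # outer ring only
    do.call(rbind, lapply(cc, function(p) as.numeric(unlist(p))))
  })
  if (types == "LineString") line_layer(coords, attrs)
  else if (types == "Polygon") polygon_layer(coords, attrs)
  else stopf("unsupported geometry type %s", types)
}

#' Write every layer of a bundle as GeoJSON files
#'
#' @param layers a [spatial_layers()] object
#' @param dir output directory
#' @return `dir`, invisibly
#' @export
write_layers_geojson <- function(layers, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (nm in names(layers$points))
    write_geojson(layers$points[[nm]], file.path(dir, paste0(nm, ".geojson")))
  for (nm in names(layers$lines))
    write_geojson(layers$lines[[nm]], file.path(dir, paste0(nm, ".geojson")))
  for (nm in names(layers$polygons))
    write_geojson(layers$polygons[[nm]], file.path(dir, paste0(nm, ".geojson")))
  invisible(dir)
}

#' Read a directory of GeoJSON layers back into a spatial_layers bundle
#'
#' Layer kind is inferred from each file's geometry type; layer names come
#' from file names.
#'
#' @param dir directory containing `<layer>.geojson` files
#' @return a [spatial_layers()] object
#' @export
read_layers_geojson <- function(dir) {
  files <- list.files(dir, pattern = "\\.geojson$", full.names = TRUE)
  pts <- list(); lns <- list(); pls <- list()
  for (f in files) {
    nm <- sub("\\.geojson$", "", basename(f))
    l <- read_geojson(f)
    if (is.data.frame(l)) pts[[nm]] <- l
    else if (inherits(l, "line_layer")) lns[[nm]] <- l
    else pls[[nm]] <- l
  }
  spatial_layers(pts, lns, pls)
}
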