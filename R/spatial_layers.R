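#' Spatial layer containers
#'
#' Lightweight planar containers used throughout the built-environment
#' module: point layers are data frames with `x`, `y` columns; line and
#' polygon layers pair a list of coordinate matrices (one two-column matrix
#' per feature; polygon rings need not repeat the closing vertex) with a
#' per-feature attribute data frame. All coordinates are metres in one
#' planar system; longitude/latitude data must be projected upstream.
#'
#' @param coords list of numeric matrices with columns x, y
#' @param attrs data frame with one row per feature
#' @return a `line_layer` / `polygon_layer` object
#' @export
line_layer <- function(coords, attrs = NULL) {
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(coords))
  if (nrow(attrs) != length(coords))
    stopf("attrs must have one row per feature")
  structure(list(coords = coords, attrs = attrs), class = "line_layer")
}

#' @rdname line_layer
#' @export
polygon_layer <- function(coords, attrs = NULL) {
  if (is.null(attrs)) attrs <- data.frame(row.names = seq_along(coords))
  if (nrow(attrs) != length(coords))
    stopf("attrs must have one row per feature")
  structure(list(coords = coords, attrs = attrs,
                 bbox = t(vapply(coords, function(m)
                   c(min(m[, 1]), min(m[, 2]), max(m[, 1]), max(m[, 2])),
                   numeric(4)))),
            class = "polygon_layer")
}

#' Bundle named point, line and polygon layers
#'
#' @param points named list of data frames with x, y columns
#' @param lines named list of [line_layer()] objects
#' @param polygons named list of [polygon_layer()] objects
#' @return a `spatial_layers` object
#' @export
spatial_layers <- function(points = list(), lines = list(),
                           polygons = list()) {
  structure(list(points = points, lines = lines, polygons = polygons),
            class = "spatial_layers")
}

#' @export
print.spatial_layers <- function(x, ...) {
  cat("Spatial layers (planar metres)\n")
  for (nm in names(x$points))
    cat(sprintf("  points   %-14s %d features\n", nm, nrow(x$points[[nm]])))
  for (nm in names(x$lines))
    cat(sprintf("  lines    %-14s %d features\n", nm,
                length(x$lines[[nm]]$coords)))
  for (nm in names(x$polygons))
    cat(sprintf("  polygons %-14s %d features\n", nm,
                length(x$polygons[[nm]]$coords)))
  invisible(x)
}

# shift every coordinate by (dx, dy); used by translation-invariance tests
shift_layers <- function(layers, dx, dy) {
  sh_pts <- lapply(layers$points, function(p) {
    p$x <- p$x + dx; p$y <- p$y + dy; p
  })
  sh <- function(l, ctor) {
    ctor(lapply(l$coords, function(m) cbind(m[, 1] + dx, m[, 2] + dy)),
         l$attrs)
  }
  spatial_layers(sh_pts,
                 lapply(layers$lines, sh, ctor = line_layer),
                 lapply(layers$polygons, sh, ctor = polygon_layer))
}
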