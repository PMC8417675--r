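#' Assemble per-patient built-environment feature vectors
#'
#' Computes, for every patient's home location, the ten buffer indicators —
#' bus stops, subway stations and street intersections within 500 m;
#' bike-path length (m), green area (m2), sidewalk area (m2) within 500 m;
#' light- and heavy-duty vehicle kilometres travelled within 500 m;
#' the entropy land-use mix index at 500 m; and the retail floor-area
#' ratio at 250 m — and joins the census-tract attributes (PM2.5, ozone,
#' GINI, college-degree percent, poverty, uninsured percent, low food
#' access). Buffers with no parcel land get a missing LUM, flagged for
#' imputation downstream.
#'
#' @param patients patient table with `patient_id`, `home_x`, `home_y`,
#'   `tract_id`
#' @param layers a [spatial_layers()] bundle with point layers `bus_stops`,
#'   `subway`, `intersections`, line layers `bike_paths`, `traffic`, and
#'   polygon layers `parcels`, `green`, `sidewalks`
#' @param tract_table data frame keyed by `tract_id`
#' @param r buffer radius for most indicators, metres
#' @param r_retfar buffer radius for RetFAR, metres
#' @param taxonomy land-use classes for the LUM index
#' @return data frame, one row per patient: the indicator columns of the
#'   `BuiltEnvVector` plus the tract joins
#' @export
assemble_features <- function(patients, layers, tract_table, r = 500,
                              r_retfar = 250,
                              taxonomy = default_landuse_taxonomy()) {
  need <- c("patient_id", "home_x", "home_y", "tract_id")
  if (!all(need %in% names(patients)))
    stopf("patient table needs columns: %s", paste(need, collapse = ", "))
  unknown <- setdiff(patients$tract_id, tract_table$tract_id)
  if (length(unknown))
    stopf("unknown tract_id for patients: %s",
          paste(head(patients$patient_id[patients$tract_id %in% unknown], 5),
                collapse = ", "))
  n <- nrow(patients)
  out <- data.frame(
    patient_id = patients$patient_id,
    bus_stops_500 = integer(n), subway_500 = integer(n),
    intersections_500 = integer(n), bike_len_500 = numeric(n),
    green_area_500 = numeric(n), sidewalk_area_500 = numeric(n),
    vkt_light_500 = numeric(n), vkt_heavy_500 = numeric(n),
    lum_500 = numeric(n), retfar_250 = numeric(n),
    stringsAsFactors = FALSE)
  for (i in seq_len(n)) {
    ctr <- c(patients$home_x[i], patients$home_y[i])
    out$bus_stops_500[i] <- count_points_in_radius(layers$points$bus_stops,
                                                   ctr, r)
    out$subway_500[i] <- count_points_in_radius(layers$points$subway, ctr, r)
    out$intersections_500[i] <-
      count_points_in_radius(layers$points$intersections, ctr, r)
    out$bike_len_500[i] <- length_in_radius(layers$lines$bike_paths, ctr, r)
    out$green_area_500[i] <- area_in_radius(layers$polygons$green, ctr, r)
    out$sidewalk_area_500[i] <- area_in_radius(layers$polygons$sidewalks,
                                               ctr, r)
    out$vkt_light_500[i] <- vkt_in_radius(layers$lines$traffic, ctr, r,
                                          "light")
    out$vkt_heavy_500[i] <- vkt_in_radius(layers$lines$traffic, ctr, r,
                                          "heavy")
    out$lum_500[i] <- lum_index(layers$polygons$parcels, ctr, r, taxonomy)
    out$retfar_250[i] <- retfar(layers$polygons$parcels, ctr, r_retfar)
  }
  join_cols <- setdiff(names(tract_table), "tract_id")
  m <- match(patients$tract_id, tract_table$tract_id)
  cbind(out, tract_table[m, join_cols, drop = FALSE], row.names = NULL)
}
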