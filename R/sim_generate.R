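# Urbanicity gradient: feature density and land-use mix increase from the
# west (x = 0) to the east (x = region_side) edge of the synthetic region.
gradient_mult <- function(x, side) 0.4 + 1.2 * (x / side)

#' Generate the synthetic patient cohort
#'
#' Draws each patient's latent care-pattern cluster from the configured
#' mixture, then demographics (age, BMI, gestational week, marital status,
#' race, insurance), a delivery date, and a home location whose placement
#' along the region's urbanicity gradient depends on the latent cluster
#' (`env_shift`), which is what plants the built-environment/cluster
#' associations. A small fraction of ages falls outside 18-45 so inclusion
#' filters have work to do.
#'
#' @param config a [sim_config()]
#' @return list with `patients` (data frame) and `truth` (data frame of
#'   patient_id, latent_cluster)
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_patients
  k <- length(config$mixing_proportions)
  side <- config$region_side

  truth <- with_stream(config$seed, "truth", {
    data.frame(
      patient_id = sprintf("P%06d", seq_len(n)),
      latent_cluster = sample.int(k, n, replace = TRUE,
                                  prob = config$mixing_proportions)
    )
  })

  patients <- with_stream(config$seed, "cohort", {
    # cluster 1 skews older, cluster 3 younger (post-hoc table structure)
    age_shift <- c(1.3, 0.1, -1.0)[pmin(truth$latent_cluster, 3)]
    age <- rnorm(n, 33.7 + age_shift, 4.6)
    outlier <- runif(n) < 0.02
    age[outlier] <- runif(sum(outlier), 15, 52)
    bmi <- pmax(rnorm(n, 23.8, 4.3), 15)
    gw <- pmin(pmax(rnorm(n, 38.7, 2.1), 24), 43)
    marital <- ifelse(runif(n) < 0.867, "married", "single")
    race <- sample(c("White", "Asian", "Black", "Other", "Unknown"), n,
                   replace = TRUE,
                   prob = c(0.4927, 0.1887, 0.0626, 0.1091, 0.1469))
    insurance <- sample(c("Commercial", "Medicaid", "Other"), n,
                        replace = TRUE, prob = c(0.8402, 0.1370, 0.0228))
    delivery_date <- as.Date("2015-01-01") + sample.int(1095, n, TRUE) - 1L
    mu_x <- config$env_shift[truth$latent_cluster] * side
    home_x <- pmin(pmax(rnorm(n, mu_x, config$env_sd * side), 1), side - 1)
    home_y <- runif(n, 0, side)
    # rare missing home locations exercise the exclusion filter
    drop_home <- runif(n) < 0.005
    home_x[drop_home] <- NA_real_
    home_y[drop_home] <- NA_real_
    data.frame(
      patient_id = truth$patient_id,
      age = round(age, 1), bmi = round(bmi, 1),
      gestational_week = round(gw, 1),
      marital = marital, race = race, insurance = insurance,
      delivery_date = delivery_date,
      home_x = home_x, home_y = home_y,
      tract_id = tract_of(home_x, home_y, config$tract_size, side),
      stringsAsFactors = FALSE
    )
  })
  list(patients = patients, truth = truth)
}

tract_of <- function(x, y, tract_size, side) {
  n_across <- max(1L, as.integer(ceiling(side / tract_size)))
  ix <- pmin(floor(x / tract_size), n_across - 1)
  iy <- pmin(floor(y / tract_size), n_across - 1)
  ifelse(is.na(x) | is.na(y), NA_character_,
         sprintf("T%03d", as.integer(iy * n_across + ix + 1)))
}

#' Generate trimester-stamped clinical event sequences
#'
#' For each patient an event count is drawn as 1 + Poisson(length_mean - 1)
#' (so every patient has at least one event), event days are sampled without
#' replacement from the prenatal window \[-7 x gestational week, 0\] days
#' relative to delivery, and codes follow the patient's cluster-specific
#' first-order Markov chain. Timestamps strictly increase within a patient.
#'
#' @param config a [sim_config()]
#' @param truth truth table from [generate_cohort()]
#' @param patients patient table (for gestational weeks); optional, a
#'   280-day pregnancy is assumed when absent
#' @return event data frame: patient_id, t (integer days, delivery = 0),
#'   event_type, code
#' @export
generate_event_sequences <- function(config, truth, patients = NULL) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$mixing_proportions)
  if (any(!truth$latent_cluster %in% seq_len(k)))
    stopf("unknown cluster label in truth table")
  gw <- rep(40, nrow(truth))
  if (!is.null(patients))
    gw <- patients$gestational_week[match(truth$patient_id,
                                          patients$patient_id)]
  type_of <- function(code) {
    c(ENC = "encounter", DX = "diagnosis", RX = "medication")[
      sub(":.*", "", code)]
  }
  with_stream(config$seed, "events", {
    out <- vector("list", nrow(truth))
    for (i in seq_len(nrow(truth))) {
      tm <- config$transition_specs[[truth$latent_cluster[i]]]
      tokens <- rownames(tm)
      len <- 1L + rpois(1, max(config$length_mean - 1, 0))
      window <- -(round(7 * gw[i]):0)
      window <- sort(window)
      len <- min(len, length(window))
      days <- sort(sample(window, len))
      codes <- character(len)
      codes[1] <- sample(tokens, 1, prob = colSums(tm) / nrow(tm))
      if (len > 1) for (j in 2:len)
        codes[j] <- sample(tokens, 1, prob = tm[codes[j - 1], ])
      out[[i]] <- data.frame(
        patient_id = truth$patient_id[i], t = days,
        event_type = unname(type_of(codes)), code = codes,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
}

#' Generate synthetic spatial layers and census-tract attributes
#'
#' Builds point layers (bus stops, subway stations, intersections) as
#' inhomogeneous Poisson processes thinned along the urbanicity gradient,
#' polyline layers (bike paths; traffic links carrying light/heavy daily
#' volumes), polygon layers (a land-use parcel grid with class, parcel area
#' and retail floor area; green spaces; sidewalk strips), and a square tract
#' grid carrying PM2.5, ozone, GINI, college-degree percent, poverty,
#' uninsured percent and a low-food-access flag, all varying smoothly with
#' the gradient. All geometry is planar, in metres.
#'
#' @param config a [sim_config()]
#' @return list with `layers` (a `spatial_layers` object) and `tracts`
#'   (data frame keyed by tract_id)
#' @export
generate_spatial_region <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  side <- config$region_side
  area_km2 <- (side / 1000)^2
  li <- config$layer_intensities
  if (any(unlist(li) < 0)) stopf("layer intensities must be non-negative")

  pois_points <- function(stream, per_km2) {
    with_stream(config$seed, stream, {
      # thinning an upper-bound homogeneous process by the gradient
      n_max <- rpois(1, per_km2 * 1.6 / 1.0 * area_km2)
      if (n_max == 0)
        return(data.frame(x = numeric(0), y = numeric(0)))
      x <- runif(n_max, 0, side); y <- runif(n_max, 0, side)
      keep <- runif(n_max) < gradient_mult(x, side) / 1.6
      data.frame(x = x[keep], y = y[keep])
    })
  }
  rand_segments <- function(stream, per_km2, len_range) {
    with_stream(config$seed, stream, {
      n <- rpois(1, per_km2 * area_km2)
      coords <- vector("list", n)
      if (n > 0) for (i in seq_len(n)) {
        x0 <- runif(1, 0, side); y0 <- runif(1, 0, side)
        ang <- runif(1, 0, 2 * pi)
        len <- runif(1, len_range[1], len_range[2])
        coords[[i]] <- cbind(c(x0, x0 + len * cos(ang)),
                             c(y0, y0 + len * sin(ang)))
      }
      coords
    })
  }

  bus <- pois_points("bus_stops", li$bus_stops)
  subway <- pois_points("subway", li$subway)
  inters <- pois_points("intersections", li$intersections)

  bike <- rand_segments("bike_paths", li$bike_paths, c(400, 1500))
  traffic_coords <- rand_segments("traffic", li$traffic, c(300, 1200))
  traffic_attrs <- with_stream(config$seed, "traffic_vol", {
    n <- length(traffic_coords)
    xmid <- vapply(traffic_coords, function(m) mean(m[, 1]), 0)
    g <- if (n) gradient_mult(xmid, side) else numeric(0)
    data.frame(
      vol_light = round(exp(rnorm(n, log(4000), 0.5)) * g),
      vol_heavy = round(exp(rnorm(n, log(400), 0.6)) * g)
    )
  })

  classes <- c("residential", "commercial", "retail", "industrial",
               "recreation", "other")
  parcel <- with_stream(config$seed, "parcels", {
    ps <- li$parcel_size
    nx <- max(1L, floor(side / ps))
    gx <- rep(seq_len(nx) - 1, times = nx) * ps
    gy <- rep(seq_len(nx) - 1, each = nx) * ps
    xf <- (gx + ps / 2) / side
    # class mix shifts toward commercial/retail with urbanicity
    w <- cbind(residential = 0.65 - 0.35 * xf,
               commercial = 0.08 + 0.20 * xf,
               retail = 0.05 + 0.17 * xf,
               industrial = 0.10 - 0.04 * xf,
               recreation = 0.06,
               other = 0.06 + 0.02 * xf)
    cls <- vapply(seq_along(gx), function(i)
      sample(classes, 1, prob = w[i, ]), "")
    coords <- lapply(seq_along(gx), function(i)
      rbind(c(gx[i], gy[i]), c(gx[i] + ps, gy[i]),
            c(gx[i] + ps, gy[i] + ps), c(gx[i], gy[i] + ps)))
    far <- ifelse(cls == "retail", exp(rnorm(length(gx), log(0.9), 0.5)), NA)
    list(coords = coords,
         attrs = data.frame(
           landuse_class = cls,
           parcel_area_m2 = rep(ps^2, length(gx)),
           floor_area_m2 = ifelse(is.na(far), 0, round(far * ps^2))
         ))
  })

  green <- with_stream(config$seed, "green", {
    n <- rpois(1, li$green * area_km2)
    coords <- vector("list", n)
    if (n > 0) for (i in seq_len(n)) {
      x0 <- runif(1, 0, side); y0 <- runif(1, 0, side)
      w <- runif(1, 80, 500); h <- runif(1, 80, 500)
      coords[[i]] <- rbind(c(x0, y0), c(x0 + w, y0),
                           c(x0 + w, y0 + h), c(x0, y0 + h))
    }
    list(coords = coords,
         attrs = data.frame(area_m2 = vapply(coords, cpp_polygon_area, 0)))
  })

  sidewalks <- with_stream(config$seed, "sidewalks", {
    n <- rpois(1, li$sidewalks * area_km2)
    coords <- vector("list", n)
    if (n > 0) for (i in seq_len(n)) {
      x0 <- runif(1, 0, side); y0 <- runif(1, 0, side)
      horiz <- runif(1) < 0.5
      len <- runif(1, 100, 400); wid <- runif(1, 2, 5)
      w <- if (horiz) len else wid
      h <- if (horiz) wid else len
      coords[[i]] <- rbind(c(x0, y0), c(x0 + w, y0),
                           c(x0 + w, y0 + h), c(x0, y0 + h))
    }
    list(coords = coords, attrs = data.frame(row.names = seq_len(n)))
  })

  layers <- spatial_layers(
    points = list(bus_stops = bus, subway = subway, intersections = inters),
    lines = list(
      bike_paths = line_layer(bike,
                              data.frame(row.names = seq_along(bike))),
      traffic = line_layer(traffic_coords, traffic_attrs)
    ),
    polygons = list(
      parcels = polygon_layer(parcel$coords, parcel$attrs),
      green = polygon_layer(green$coords, green$attrs),
      sidewalks = polygon_layer(sidewalks$coords, sidewalks$attrs)
    )
  )

  tracts <- with_stream(config$seed, "tracts", {
    n_across <- max(1L, as.integer(ceiling(side / config$tract_size)))
    idx <- seq_len(n_across^2)
    ix <- (idx - 1) %% n_across
    xf <- (ix + 0.5) / n_across
    data.frame(
      tract_id = sprintf("T%03d", idx),
      pm25 = round(9.28 + 1.0 * (xf - 0.5) + rnorm(length(idx), 0, 0.15), 3),
      o3 = round(46.56 - 0.6 * (xf - 0.5) + rnorm(length(idx), 0, 0.2), 3),
      gini = round(pmin(pmax(
        0.42 - 0.04 * (xf - 0.5) + rnorm(length(idx), 0, 0.03), 0.2), 0.7), 4),
      college_pct = round(pmin(pmax(
        35.8 - 15 * (xf - 0.5) + rnorm(length(idx), 0, 4), 2), 95), 2),
      poverty = round(pmax(
        1.62 + 1.5 * (xf - 0.5) + rnorm(length(idx), 0, 0.8), 0), 2),
      uninsured_pct = round(pmax(
        8.26 + 3 * (xf - 0.5) + rnorm(length(idx), 0, 2), 0), 2),
      low_food_access = as.integer(runif(length(idx)) < 0.033)
    )
  })

  list(layers = layers, tracts = tracts)
}

#' Generate PPD outcomes from latent cluster membership
#'
#' PPD is Bernoulli with probability inverse-logit(b0 + log(OR_c)) where
#' b0 = logit(baseline_ppd) and OR_c is the configured odds ratio of the
#' patient's cluster (1 for the reference, the last cluster).
#'
#' @param config a [sim_config()]
#' @param truth truth table from [generate_cohort()]
#' @return data frame: patient_id, ppd (logical)
#' @export
generate_outcomes <- function(config, truth) {
  stopifnot(inherits(config, "sim_config"))
  k <- length(config$mixing_proportions)
  lor <- c(log(config$outcome_or), 0)   # reference = last cluster
  b0 <- qlogis(config$baseline_ppd)
  with_stream(config$seed, "outcomes", {
    p <- plogis(b0 + lor[truth$latent_cluster])
    data.frame(patient_id = truth$patient_id,
               ppd = runif(nrow(truth)) < p)
  })
}

#' Generate a complete synthetic study bundle
#'
#' Runs the cohort, event, spatial and outcome generators under one master
#' seed, injects the downstream-observable consequences of the outcome (a
#' postpartum depression diagnosis event within a year of delivery for each
#' PPD-positive patient) plus pre-/post-delivery emergency-department
#' visits, and optionally writes the bundle (patients.csv, events.csv,
#' tracts.csv, truth.csv, one GeoJSON file per layer) to a directory.
#'
#' @param config a [sim_config()]
#' @param out_dir optional output directory; created if needed
#' @param ppd_code diagnosis token recorded for a PPD diagnosis
#' @return list: patients, events, truth, layers, tracts, outcomes
#' @export
simulate_study <- function(config, out_dir = NULL, ppd_code = "DX:PPD") {
  cohort <- generate_cohort(config)
  events <- generate_event_sequences(config, cohort$truth, cohort$patients)
  spatial <- generate_spatial_region(config)
  outcomes <- generate_outcomes(config, cohort$truth)

  extra <- with_stream(config$seed, "postpartum_events", {
    n <- nrow(cohort$patients)
    rows <- list()
    pos <- which(outcomes$ppd)
    if (length(pos))
      rows$ppd <- data.frame(
        patient_id = outcomes$patient_id[pos],
        t = sample.int(365, length(pos), replace = TRUE),
        event_type = "diagnosis", code = ppd_code,
        stringsAsFactors = FALSE)
    # ED visit propensity is higher in the high-complexity cluster
    p_pre <- c(0.55, 0.45, 0.35)[pmin(cohort$truth$latent_cluster, 3)]
    pre <- which(runif(n) < p_pre)
    if (length(pre))
      rows$pre_ed <- data.frame(
        patient_id = cohort$patients$patient_id[pre],
        t = -sample.int(365, length(pre), replace = TRUE),
        event_type = "encounter", code = "ENC:ED",
        stringsAsFactors = FALSE)
    post <- which(runif(n) < 0.054)
    if (length(post))
      rows$post_ed <- data.frame(
        patient_id = cohort$patients$patient_id[post],
        t = sample.int(365, length(post), replace = TRUE),
        event_type = "encounter", code = "ENC:ED",
        stringsAsFactors = FALSE)
    do.call(rbind, rows)
  })
  if (!is.null(extra)) {
    events <- rbind(events, extra)
    events <- events[order(events$patient_id, events$t,
                           events$event_type, events$code), ]
    rownames(events) <- NULL
  }

  bundle <- list(patients = cohort$patients, events = events,
                 truth = cohort$truth, layers = spatial$layers,
                 tracts = spatial$tracts, outcomes = outcomes)
  if (!is.null(out_dir)) write_study_bundle(bundle, out_dir)
  bundle
}

#' Write a synthetic study bundle to disk
#'
#' @param bundle as returned by [simulate_study()]
#' @param out_dir output directory
#' @return `out_dir`, invisibly
#' @export
write_study_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write.csv(bundle$patients, file.path(out_dir, "patients.csv"),
            row.names = FALSE)
  write.csv(bundle$events, file.path(out_dir, "events.csv"),
            row.names = FALSE)
  write.csv(bundle$tracts, file.path(out_dir, "tracts.csv"),
            row.names = FALSE)
  write.csv(bundle$truth, file.path(out_dir, "truth.csv"),
            row.names = FALSE)
  write.csv(bundle$outcomes, file.path(out_dir, "outcomes.csv"),
            row.names = FALSE)
  write_layers_geojson(bundle$layers, out_dir)
  invisible(out_dir)
}
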