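#' Default clinical event vocabulary
#'
#' Opaque tokens shaped like the coding systems an EHR export would carry:
#' visit types for encounters, SNOMED-like concept tags for diagnoses and
#' ATC-class-like tags for medications. Codes are treated as opaque strings
#' throughout; no terminology mapping is attempted.
#'
#' @return list with components `encounter`, `diagnosis`, `medication`
#' @export
default_vocab <- function() {
  list(
    encounter = c("ENC:OB", "ENC:ULTRASOUND", "ENC:LAB", "ENC:ED",
                  "ENC:MFM", "ENC:CLASS"),
    diagnosis = c("DX:SUPERVISION", "DX:ANXIETY", "DX:DEPRESSION_HX",
                  "DX:HYPOTHYROID", "DX:THREAT_MISC", "DX:ABD_PAIN",
                  "DX:GLUCOSE_ABN", "DX:HIGH_RISK", "DX:UNPLANNED",
                  "DX:FALSE_LABOR", "DX:PREECLAMPSIA"),
    medication = c("RX:PRENATAL_VIT", "RX:PROGESTOGEN", "RX:OPIOID",
                   "RX:ANALGESIC", "RX:ANTIEMETIC", "RX:THYROID",
                   "RX:ANTIBIOTIC", "RX:ANTIHISTAMINE")
  )
}

# Per-cluster signature tokens used to build the default transition
# structure: cluster 1 = high-complexity care (mental-health history,
# high-risk pregnancy, heavy prescribing), cluster 2 = intermediate,
# cluster 3 = routine low-intervention care.
cluster_signatures <- function() {
  list(
    c("DX:ANXIETY", "DX:DEPRESSION_HX", "DX:HIGH_RISK", "DX:THREAT_MISC",
      "DX:HYPOTHYROID", "RX:OPIOID", "RX:THYROID", "RX:PROGESTOGEN",
      "ENC:ED", "ENC:MFM"),
    c("DX:GLUCOSE_ABN", "DX:ABD_PAIN", "DX:UNPLANNED", "DX:PREECLAMPSIA",
      "RX:ANALGESIC", "RX:ANTIHISTAMINE", "RX:ANTIBIOTIC", "RX:ANTIEMETIC"),
    c("DX:SUPERVISION", "DX:FALSE_LABOR", "ENC:CLASS", "ENC:ULTRASOUND",
      "RX:PRENATAL_VIT")
  )
}

#' Build default per-cluster transition matrices
#'
#' Each cluster's chain mixes a signature token distribution with a common
#' routine-care distribution; `separation` in \[0,1\] controls how distinct
#' the clusters are (0 = identical chains, 1 = fully signature-driven).
#' Rows of each matrix are the cluster's stationary token distribution, so
#' the chain is exchangeable but first-order by construction.
#'
#' @param vocab vocabulary list as from [default_vocab()]
#' @param separation mixing weight on the signature distribution
#' @return list of k row-stochastic matrices with token dimnames
#' @export
default_transition_specs <- function(vocab = default_vocab(),
                                     separation = 0.75) {
  tokens <- unlist(vocab, use.names = FALSE)
  common <- c("ENC:OB", "ENC:ULTRASOUND", "ENC:LAB", "DX:SUPERVISION",
              "RX:PRENATAL_VIT")
  sigs <- cluster_signatures()
  lapply(sigs, function(sig) {
    sig <- intersect(sig, tokens)
    p <- setNames(rep(0, length(tokens)), tokens)
    p[common] <- p[common] + (1 - separation) / length(common)
    p[sig] <- p[sig] + separation / length(sig)
    p <- p / sum(p)
    # identical rows: the stationary distribution, an exchangeable chain
    matrix(rep(p, times = length(tokens)), nrow = length(tokens),
           byrow = TRUE, dimnames = list(tokens, tokens))
  })
}

#' Simulation configuration for a synthetic study bundle
#'
#' Collects every parameter of the synthetic-data generator: cohort size and
#' latent cluster mixture, the event vocabulary and per-cluster first-order
#' transition matrices, expected sequence length, the planar region and
#' spatial layer intensities, cluster-specific home-placement shifts along
#' the urbanicity gradient, and the outcome model (PPD odds ratios for
#' clusters 1 and 2 against the reference cluster, and the reference
#' cluster's baseline PPD probability).
#'
#' @param n_patients number of patients to generate
#' @param mixing_proportions probability vector over latent clusters
#' @param vocab event vocabulary, as [default_vocab()]
#' @param transition_specs list of per-cluster row-stochastic transition
#'   matrices over the flattened vocabulary
#' @param length_mean expected number of prenatal events per patient
#'   (sequence length is 1 + Poisson(length_mean - 1), so always >= 1)
#' @param region_side edge length of the square planar region, metres
#'   (must exceed 1000 so 500 m buffers fit)
#' @param tract_size census-tract grid cell size, metres
#' @param layer_intensities named list of expected feature densities per
#'   square kilometre (points/lines) and parcel grid size in metres
#' @param env_shift per-cluster home-placement centres as fractions of the
#'   region side along the urbanicity (x) gradient
#' @param env_sd spatial SD of home placement as a fraction of the side
#' @param outcome_or odds ratios of PPD for clusters 1 and 2 versus the
#'   reference (last) cluster
#' @param baseline_ppd PPD probability in the reference cluster
#' @param seed master integer seed; every table/layer derives its own
#'   substream from it
#' @return an object of class `sim_config`
#' @export
sim_config <- function(n_patients = 2000,
                       mixing_proportions = c(0.22, 0.46, 0.32),
                       vocab = default_vocab(),
                       transition_specs = NULL,
                       length_mean = 18,
                       region_side = 12000,
                       tract_size = 2000,
                       layer_intensities = list(
                         bus_stops = 20, subway = 1.5, intersections = 12,
                         bike_paths = 2, traffic = 3, green = 0.8,
                         sidewalks = 4, parcel_size = 200
                       ),
                       env_shift = c(0.30, 0.50, 0.70),
                       env_sd = 0.15,
                       outcome_or = c(6.3, 2.43),
                       baseline_ppd = 0.0114,
                       seed = 1L) {
  if (!is_count(n_patients) || n_patients < 1)
    stopf("n_patients must be a positive integer")
  if (any(mixing_proportions < 0) ||
      abs(sum(mixing_proportions) - 1) > 1e-12)
    stopf("mixing_proportions must be non-negative and sum to 1")
  k <- length(mixing_proportions)
  if (is.null(transition_specs))
    transition_specs <- default_transition_specs(vocab)[seq_len(k)]
  if (length(transition_specs) != k)
    stopf("transition_specs must have one matrix per mixture component")
  for (m in transition_specs) {
    if (any(m < 0) || any(abs(rowSums(m) - 1) > 1e-12))
      stopf("every transition matrix row must be a probability vector")
  }
  if (length_mean < 0) stopf("length_mean must be non-negative")
  if (region_side <= 1000)
    stopf("region_side must exceed 1000 m so 500 m buffers fit")
  if (any(unlist(layer_intensities) < 0))
    stopf("layer intensities must be non-negative")
  if (length(env_shift) != k)
    stopf("env_shift must give one placement centre per cluster")
  if (any(outcome_or <= 0)) stopf("outcome_or must be positive")
  if (length(outcome_or) != k - 1 && k > 1)
    stopf("outcome_or must have length k - 1 (reference = last cluster)")
  if (baseline_ppd <= 0 || baseline_ppd >= 1)
    stopf("baseline_ppd must lie strictly in (0, 1)")
  structure(list(
    n_patients = as.integer(n_patients),
    mixing_proportions = mixing_proportions,
    vocab = vocab,
    transition_specs = transition_specs,
    length_mean = length_mean,
    region_side = region_side,
    tract_size = tract_size,
    layer_intensities = layer_intensities,
    env_shift = env_shift,
    env_sd = env_sd,
    outcome_or = outcome_or,
    baseline_ppd = baseline_ppd,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic study configuration\n")
  cat(sprintf("  patients: %d in %d latent clusters (%s)\n", x$n_patients,
              length(x$mixing_proportions),
              paste(x$mixing_proportions, collapse = "/")))
  cat(sprintf("  region: %.0f m square, tracts %.0f m; seed %d\n",
              x$region_side, x$tract_size, x$seed))
  cat(sprintf("  outcome ORs: %s; baseline PPD %.4f\n",
              paste(x$outcome_or, collapse = ", "), x$baseline_ppd))
  invisible(x)
}
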