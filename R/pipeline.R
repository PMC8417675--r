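#' Build a pipeline run configuration
#'
#' Collects every stage parameter with study defaults. `sim` may be a
#' [sim_config()] (used by the simulate stage) or NULL when inputs are
#' supplied externally in `out_dir`.
#'
#' @param sim a [sim_config()] or NULL
#' @param stages character vector of stages to run, in order, from
#'   `c("simulate", "cohort", "cluster", "mine", "features", "model")`
#' @param vocabulary_filter token allow-list for sequence building;
#'   defaults to the full simulated vocabulary
#' @param ppd_codes diagnosis codes defining PPD
#' @param normalization LCS distance normalisation for the clustering
#'   stage. The pipeline default is `"mean"`: max-length normalisation
#'   turns the few patients with very short event histories into isolates
#'   (their distance to everyone is close to 1), which destabilises
#'   silhouette-based selection of k; mean-length normalisation keeps
#'   distances in \[0, 1\] while penalising length mismatch symmetrically
#' @param linkage clustering linkage
#' @param k_range candidate cluster counts
#' @param minsup,max_len,use_istep pattern-mining parameters
#' @param buffer_r,retfar_r buffer radii in metres
#' @param taxonomy land-use taxonomy
#' @param mediator_covariates covariates of the cluster equation
#' @param reference_cluster reference cluster for both equations ("largest
#'   silhouette label with the lowest PPD rate" is not assumed; the label
#'   is taken as given)
#' @param n_imputations imputations if features carry missing cells
#' @param seed master seed for stochastic stages
#' @return object of class `run_config`
#' @export
run_config <- function(sim = sim_config(),
                       stages = c("simulate", "cohort", "cluster", "mine",
                                  "features", "model"),
                       vocabulary_filter = NULL,
                       ppd_codes = "DX:PPD",
                       normalization = "mean",
                       linkage = "average",
                       k_range = 2:8,
                       minsup = 0.10, max_len = 5, use_istep = TRUE,
                       buffer_r = 500, retfar_r = 250,
                       taxonomy = default_landuse_taxonomy(),
                       mediator_covariates = c("lum_500", "retfar_250",
                                               "pm25", "gini",
                                               "college_pct", "age",
                                               "married"),
                       reference_cluster = NULL,
                       n_imputations = 5,
                       seed = 1L) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(as.list(environment()), class = "run_config")
}

#' Load a run configuration from a YAML document
#'
#' Top-level keys mirror [run_config()] arguments; a `sim:` block mirrors
#' [sim_config()] arguments (vocab/transition matrices fall back to the
#' package defaults). Unknown keys raise an error naming them.
#'
#' @param path YAML file
#' @return a [run_config()]
#' @export
load_run_config <- function(path) {
  doc <- yaml::read_yaml(path)
  sim_args <- doc$sim %||% list()
  bad <- setdiff(names(sim_args), names(formals(sim_config)))
  if (length(bad)) stopf("unknown sim config keys: %s",
                         paste(bad, collapse = ", "))
  doc$sim <- NULL
  bad <- setdiff(names(doc), names(formals(run_config)))
  if (length(bad)) stopf("unknown run config keys: %s",
                         paste(bad, collapse = ", "))
  doc$sim <- do.call(sim_config, sim_args)
  do.call(run_config, doc)
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  ser <- rapply(unclass(config), function(x) {
    if (is.function(x)) deparse(x) else x
  }, how = "replace")
  jsonlite::write_json(ser, tmp, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  unname(tools::md5sum(tmp))
}

stage_done <- function(out_dir, files) {
  all(file.exists(file.path(out_dir, files)))
}

#' Run the analysis pipeline
#'
#' Executes the enabled stages in order — simulate (synthetic bundle),
#' cohort (inclusion/exclusion, PPD labels, sequences, summary), cluster
#' (LCS distances, hierarchy, silhouette selection), mine (per-cluster
#' SPADE patterns with outcome splits), features (built-environment
#' vectors), model (group comparisons and the two-equation path model) —
#' writing each stage's outputs to `out_dir` before the next starts, and
#' ends with a manifest (config hash, stage timings, row counts). With
#' `resume = TRUE`, stages whose outputs already exist are skipped.
#'
#' @param config a [run_config()]
#' @param out_dir output directory
#' @param resume skip stages whose outputs exist
#' @return the run manifest, invisibly (also written as `manifest.json`)
#' @export
run_pipeline <- function(config, out_dir, resume = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(config_hash = config_hash(config),
                   package_version = as.character(
                     utils::packageVersion("carepathways")),
                   stages = list())
  t_stage <- function(name, outputs, expr) {
    if (resume && stage_done(out_dir, outputs)) {
      message(sprintf("[%s] outputs present, skipped (resume)", name))
      manifest$stages[[name]] <<- list(skipped = TRUE)
      return(invisible())
    }
    t0 <- Sys.time()
    counts <- expr
    manifest$stages[[name]] <<- c(
      list(seconds = round(as.numeric(Sys.time() - t0, units = "secs"), 2)),
      as.list(counts))
    message(sprintf("[%s] done in %.1fs", name,
                    manifest$stages[[name]]$seconds))
  }
  stages <- config$stages

  if ("simulate" %in% stages)
    t_stage("simulate", "patients.csv", {
      bundle <- simulate_study(config$sim, out_dir)
      c(patients = nrow(bundle$patients), events = nrow(bundle$events))
    })

  if ("cohort" %in% stages)
    t_stage("cohort", c("cohort.csv", "sequences.csv", "exclusions.json"), {
      patients <- read.csv(file.path(out_dir, "patients.csv"))
      events <- read.csv(file.path(out_dir, "events.csv"))
      filt <- apply_inclusion_exclusion(patients, events)
      ppd <- label_ppd(filt$events, config$ppd_codes,
                       filt$patients$patient_id)
      filt$patients$ppd <- unname(ppd)
      vf <- config$vocabulary_filter %||%
        unlist(config$sim$vocab, use.names = FALSE)
      seqs <- build_sequences(filt$events, vf)
      write.csv(filt$patients, file.path(out_dir, "cohort.csv"),
                row.names = FALSE)
      seq_tab <- do.call(rbind, lapply(seqs, function(s)
        data.frame(patient_id = s$patient_id, t = s$times, code = s$tokens)))
      write.csv(seq_tab, file.path(out_dir, "sequences.csv"),
                row.names = FALSE)
      jsonlite::write_json(as.list(filt$exclusions),
                           file.path(out_dir, "exclusions.json"),
                           auto_unbox = TRUE)
      summ <- cohort_summary(filt$patients, filt$events)
      write_cohort_summary_tsv(summ, file.path(out_dir, "cohort_summary.tsv"))
      c(patients_in = nrow(patients), patients_kept = nrow(filt$patients),
        sequences = length(seqs), dropped_empty = attr(seqs, "n_dropped"))
    })

  if ("cluster" %in% stages)
    t_stage("cluster", c("labels.csv", "distances.csv"), {
      seqs <- read_sequences_csv(file.path(out_dir, "sequences.csv"))
      D <- pairwise_distance_matrix(seqs, config$normalization)
      res <- silhouette_and_select_k(D, config$k_range, config$linkage)
      write.csv(data.frame(patient_id = names(res$labels),
                           cluster = unname(res$labels)),
                file.path(out_dir, "labels.csv"), row.names = FALSE)
      # square matrix CSV with ids in the header
      dd <- as.data.frame(D)
      write.csv(cbind(patient_id = rownames(D), dd),
                file.path(out_dir, "distances.csv"), row.names = FALSE)
      jsonlite::write_json(
        list(k = res$k, linkage = res$linkage,
             silhouette_by_k = as.list(res$silhouette_by_k)),
        file.path(out_dir, "clustering.json"), auto_unbox = TRUE,
        digits = NA)
      c(n = nrow(D), k = res$k)
    })

  if ("mine" %in% stages)
    t_stage("mine", "patterns.tsv", {
      seqs <- read_sequences_csv(file.path(out_dir, "sequences.csv"))
      labels <- read.csv(file.path(out_dir, "labels.csv"))
      cohort <- read.csv(file.path(out_dir, "cohort.csv"))
      db <- as_sequence_db(seqs)
      lab <- setNames(labels$cluster, labels$patient_id)
      ppd <- setNames(cohort$ppd, cohort$patient_id)
      mined <- mine_per_cluster(db, lab, config$minsup, config$max_len,
                                config$use_istep, ppd_labels = ppd)
      write_patterns_tsv(mined, file.path(out_dir, "patterns.tsv"))
      c(clusters = length(mined),
        patterns = sum(vapply(mined, nrow, 0L)))
    })

  if ("features" %in% stages)
    t_stage("features", "built_env.csv", {
      cohort <- read.csv(file.path(out_dir, "cohort.csv"))
      layers <- read_layers_geojson(out_dir)
      tracts <- read.csv(file.path(out_dir, "tracts.csv"))
      feats <- assemble_features(cohort, layers, tracts,
                                 r = config$buffer_r,
                                 r_retfar = config$retfar_r,
                                 taxonomy = config$taxonomy)
      write.csv(feats, file.path(out_dir, "built_env.csv"),
                row.names = FALSE)
      c(patients = nrow(feats), lum_missing = sum(is.na(feats$lum_500)))
    })

  if ("model" %in% stages)
    t_stage("model", c("path_model.tsv", "group_compare.tsv"), {
      cohort <- read.csv(file.path(out_dir, "cohort.csv"))
      labels <- read.csv(file.path(out_dir, "labels.csv"))
      feats <- read.csv(file.path(out_dir, "built_env.csv"))
      d <- merge(merge(cohort, labels, by = "patient_id"),
                 feats, by = "patient_id")
      d$married <- as.integer(d$marital == "married")
      covs <- intersect(config$mediator_covariates, names(d))
      ref <- config$reference_cluster %||% max(d$cluster)
      # VIF screen on the mediator covariates (complete rows only)
      scr <- vif_screen(na.omit(d[covs]), config$vif_threshold %||% 10)
      covs <- scr$retained
      model_data <- d[c("ppd", "cluster", covs)]
      datasets <- if (anyNA(model_data))
        chained_imputation(model_data, m = config$n_imputations,
                           seed = config$seed)
      else model_data
      spec <- path_model_spec(covs, reference_cluster = ref,
                              n_imputations = config$n_imputations)
      fit <- fit_path_model(datasets, spec)
      write_path_model_tsv(fit, file.path(out_dir, "path_model.tsv"))
      cmp_vars <- intersect(c("age", "bmi", "gestational_week", "marital",
                              "race", "insurance", "ppd"), names(d))
      cmp <- suppressWarnings(group_compare(d[cmp_vars], d$cluster))
      utils::write.table(cmp, file.path(out_dir, "group_compare.tsv"),
                         sep = "\t", row.names = FALSE, quote = FALSE)
      c(n = nrow(d), covariates = length(covs),
        dropped_by_vif = length(scr$dropped))
    })

  manifest$finished <- format(Sys.time(), tz = "UTC")
  tmp <- file.path(out_dir, ".manifest.tmp")
  jsonlite::write_json(manifest, tmp, auto_unbox = TRUE, digits = NA)
  file.rename(tmp, file.path(out_dir, "manifest.json"))  # atomic finish
  invisible(manifest)
}

read_sequences_csv <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  sp <- split(tab[c("t", "code")], tab$patient_id)
  out <- lapply(names(sp), function(id) {
    d <- sp[[id]][order(sp[[id]]$t, sp[[id]]$code), ]
    list(patient_id = id, tokens = d$code, times = d$t)
  })
  names(out) <- names(sp)
  out
}

write_cohort_summary_tsv <- function(summ, path) {
  rows <- rbind(
    data.frame(variable = summ$continuous$variable, level = "",
               value = sprintf("%.2f (%.2f)", summ$continuous$mean,
                               summ$continuous$sd)),
    data.frame(variable = summ$categorical$variable,
               level = summ$categorical$level,
               value = sprintf("%d (%.2f%%)", summ$categorical$n,
                               summ$categorical$pct)))
  if (!is.null(summ$ed_visits))
    rows <- rbind(rows, data.frame(
      variable = paste0("ed_visit_", summ$ed_visits$period), level = ">=1",
      value = sprintf("%d (%.2f%%)", summ$ed_visits$n, summ$ed_visits$pct)))
  utils::write.table(rows, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

write_path_model_tsv <- function(fit, path) {
  out <- rbind(
    cbind(equation = "outcome", cluster = NA,
          fit$outcome_eq[c("term", "or", "ci_lo", "ci_hi", "p")]),
    if (!is.null(fit$mediator_eq))
      cbind(equation = "mediator",
            fit$mediator_eq[c("cluster", "term", "or", "ci_lo", "ci_hi",
                              "p")]))
  utils::write.table(out, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Summarise a completed run
#'
#' Renders, from the stage outputs in a run directory: the cohort summary,
#' cluster sizes with per-cluster PPD rates, the top frequent care
#' patterns per cluster with their outcome splits, and the path-model
#' odds-ratio tables. Errors name any stage whose output is missing.
#'
#' @param run_dir directory written by [run_pipeline()]
#' @param top_n patterns to show per cluster
#' @return the assembled report list, invisibly (printed as a side effect)
#' @export
report <- function(run_dir, top_n = 5) {
  need <- function(f, stage) {
    p <- file.path(run_dir, f)
    if (!file.exists(p))
      stopf("missing %s: run the '%s' stage first", f, stage)
    p
  }
  cohort <- read.csv(need("cohort.csv", "cohort"))
  cat(sprintf("== Run report: %s ==\n", run_dir))
  print(cohort_summary(cohort))

  out <- list(n = nrow(cohort))
  lab_path <- file.path(run_dir, "labels.csv")
  if (file.exists(lab_path)) {
    labels <- read.csv(lab_path)
    d <- merge(cohort, labels, by = "patient_id")
    tab <- table(d$cluster)
    cat("\nClusters:\n")
    for (cl in names(tab)) {
      rate <- 100 * mean(d$ppd[d$cluster == cl])
      cat(sprintf("  cluster %s: n = %d, PPD %.2f%%\n", cl, tab[[cl]], rate))
    }
    out$cluster_sizes <- as.integer(tab)
    if (length(tab) > 1) {
      cmp <- group_compare(d["ppd"], d$cluster)
      cat(sprintf("  PPD x cluster chi-square = %.2f (df %d), p = %.3g\n",
                  cmp$statistic[1], cmp$df1[1], cmp$p[1]))
    }
  }
  pat_path <- file.path(run_dir, "patterns.tsv")
  if (file.exists(pat_path)) {
    pats <- read.csv(pat_path, sep = "\t")
    cat("\nTop patterns per cluster (support, PPD split):\n")
    if (!nrow(pats)) cat("  no frequent patterns\n")
    else for (cl in unique(pats$cluster)) {
      sub <- head(pats[pats$cluster == cl, ], top_n)
      for (i in seq_len(nrow(sub)))
        cat(sprintf("  [%s] %-40s %4d (%.0f%%)%s\n", cl, sub$pattern[i],
                    sub$support[i], 100 * sub$support_frac[i],
                    if ("ppd_n" %in% names(sub))
                      sprintf("  PPD %d / %d", sub$ppd_n[i], sub$no_ppd_n[i])
                    else ""))
    }
    out$n_patterns <- nrow(pats)
  }
  pm_path <- file.path(run_dir, "path_model.tsv")
  if (file.exists(pm_path)) {
    pm <- read.csv(pm_path, sep = "\t")
    cat("\nPath model odds ratios:\n")
    print(pm, digits = 3, row.names = FALSE)
    out$path_model <- pm
  }
  invisible(out)
}
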