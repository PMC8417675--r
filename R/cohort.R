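#' Apply cohort inclusion/exclusion rules
#'
#' Retains patients aged 18-45 (inclusive) at their first prenatal contact,
#' with at least one recorded event in the encounter window (by default one
#' year before a 280-day pregnancy start through one year after delivery,
#' i.e. day -645 to day +365 relative to delivery), and with a non-missing
#' home location. Events of excluded patients are dropped too. Patients can
#' violate several criteria; each violated criterion is tallied.
#'
#' @param patients patient table with at least `patient_id`, `age`,
#'   `home_x`, `home_y`
#' @param events event table with `patient_id`, `t` (days, delivery = 0)
#' @param age_range inclusive age bounds
#' @param window_days encounter window in days relative to delivery
#' @return list: `patients`, `events` (filtered), `exclusions` (named
#'   counts per criterion plus `n_excluded`)
#' @export
apply_inclusion_exclusion <- function(patients, events,
                                      age_range = c(18, 45),
                                      window_days = c(-645, 365)) {
  if (!"age" %in% names(patients)) stopf("patient table lacks an age column")
  if (!all(c("patient_id", "t") %in% names(events)))
    stopf("event table needs patient_id and t columns")
  ok_age <- !is.na(patients$age) &
    patients$age >= age_range[1] & patients$age <= age_range[2]
  in_win <- events$t >= window_days[1] & events$t <= window_days[2]
  has_event <- patients$patient_id %in% events$patient_id[in_win]
  has_home <- !is.na(patients$home_x) & !is.na(patients$home_y)
  keep <- ok_age & has_event & has_home
  list(
    patients = patients[keep, , drop = FALSE],
    events = events[events$patient_id %in% patients$patient_id[keep], ,
                    drop = FALSE],
    exclusions = c(age = sum(!ok_age),
                   no_event_in_window = sum(!has_event),
                   missing_home = sum(!has_home),
                   n_excluded = sum(!keep))
  )
}

#' Label postpartum depression from diagnosis events
#'
#' A patient is PPD-positive iff some diagnosis event with a code in
#' `ppd_code_set` occurs strictly after delivery and no later than day 365
#' ("within one year after childbirth", the year read as inclusive of its
#' last day).
#'
#' @param events event table (`patient_id`, `t`, `event_type`, `code`)
#' @param ppd_code_set character vector of qualifying diagnosis codes
#' @param patient_ids ids to label; defaults to ids present in `events`
#' @return named logical vector keyed by patient id
#' @export
label_ppd <- function(events, ppd_code_set,
                      patient_ids = unique(events$patient_id)) {
  if (length(ppd_code_set) == 0) stopf("ppd_code_set must be non-empty")
  hit <- events$event_type == "diagnosis" &
    events$code %in% ppd_code_set & events$t > 0 & events$t <= 365
  setNames(patient_ids %in% events$patient_id[hit], patient_ids)
}

#' Read a PPD code set from a one-column text file
#'
#' Blank lines and `#` comments are ignored.
#' @param path file path
#' @return character vector of codes
#' @export
read_code_set <- function(path) {
  x <- trimws(readLines(path, warn = FALSE))
  x <- x[nzchar(x) & !startsWith(x, "#")]
  if (!length(x)) stopf("code set file %s is empty", path)
  x
}

#' Assign pregnancy periods to event times
#'
#' Pregnancy start is delivery minus 7 x gestational_week days. The first
#' trimester covers the first 13 completed weeks from that start, the
#' second weeks 14-27, the third week 28 through delivery (day 0); times
#' before start are pre-pregnancy and times after delivery postpartum.
#'
#' @param t integer days relative to delivery (vectorised)
#' @param gestational_week gestational length in weeks (scalar or parallel)
#' @return character vector in {pre-pregnancy, T1, T2, T3, postpartum}
#' @export
assign_trimester <- function(t, gestational_week) {
  if (any(gestational_week <= 0)) stopf("gestational_week must be positive")
  start <- -7 * gestational_week
  wk <- floor((t - start) / 7)   # completed weeks since pregnancy start
  out <- ifelse(t > 0, "postpartum",
         ifelse(t < start, "pre-pregnancy",
         ifelse(wk < 13, "T1",
         ifelse(wk < 27, "T2", "T3"))))
  out
}

#' Build per-patient ordered event sequences
#'
#' Restricts to prenatal events (t <= 0) whose codes are in the configured
#' allow-list, orders each patient's events by time with same-day ties
#' broken by (event_type, code) lexicographic order, and collapses
#' consecutive same-day duplicate tokens. Patients left with no allowed
#' events are dropped; their count is attached as attribute `n_dropped`.
#'
#' @param events event table
#' @param vocabulary_filter allow-list of codes to keep
#' @param max_t latest event time retained (0 = delivery)
#' @return named list of sequences, each `list(patient_id, tokens, times)`,
#'   with attribute `n_dropped`
#' @export
build_sequences <- function(events, vocabulary_filter, max_t = 0) {
  if (length(vocabulary_filter) == 0)
    stopf("vocabulary_filter must be non-empty")
  all_ids <- unique(events$patient_id)
  e <- events[events$t <= max_t & events$code %in% vocabulary_filter, ,
              drop = FALSE]
  e <- e[order(e$patient_id, e$t, e$event_type, e$code,
               method = "radix"), , drop = FALSE]
  # collapse consecutive same-day duplicates within a patient
  if (nrow(e) > 1) {
    dup <- c(FALSE, e$patient_id[-1] == e$patient_id[-nrow(e)] &
               e$t[-1] == e$t[-nrow(e)] &
               e$code[-1] == e$code[-nrow(e)])
    e <- e[!dup, , drop = FALSE]
  }
  seqs <- lapply(split(e[c("t", "code")], e$patient_id), function(d) d)
  out <- lapply(names(seqs), function(id)
    list(patient_id = id, tokens = seqs[[id]]$code, times = seqs[[id]]$t))
  names(out) <- names(seqs)
  attr(out, "n_dropped") <- length(setdiff(all_ids, names(seqs)))
  out
}

#' Descriptive cohort summary
#'
#' Mean (SD) for continuous variables, N (percent of non-missing) for
#' categorical ones, overall n, the PPD rate, and the share of patients
#' with at least one pre-/post-delivery emergency-department visit. The SD
#' of a single observation is reported as 0.
#'
#' @param patients patient table; a logical `ppd` column is summarised when
#'   present
#' @param events event table used for the ED-visit shares
#' @param continuous names of continuous columns to summarise
#' @param categorical names of categorical columns to summarise
#' @param ed_code encounter code identifying emergency-department visits
#' @return object of class `cohort_summary` with `n`, `continuous`
#'   (variable, mean, sd), `categorical` (variable, level, n, pct)
#' @export
cohort_summary <- function(patients, events = NULL,
                           continuous = intersect(
                             c("age", "bmi", "gestational_week"),
                             names(patients)),
                           categorical = intersect(
                             c("marital", "race", "insurance", "ppd"),
                             names(patients)),
                           ed_code = "ENC:ED") {
  n <- nrow(patients)
  cont <- do.call(rbind, lapply(continuous, function(v) {
    x <- patients[[v]][!is.na(patients[[v]])]
    data.frame(variable = v,
               mean = if (length(x)) mean(x) else NA_real_,
               sd = if (length(x) > 1) sd(x) else if (length(x) == 1) 0
                    else NA_real_)
  }))
  cat_tab <- do.call(rbind, lapply(categorical, function(v) {
    x <- patients[[v]][!is.na(patients[[v]])]
    if (is.logical(x)) x <- ifelse(x, "yes", "no")
    tt <- table(x)
    if (!length(tt)) return(NULL)
    data.frame(variable = v, level = names(tt), n = as.integer(tt),
               pct = if (length(x)) 100 * as.integer(tt) / length(x)
                     else numeric(0),
               row.names = NULL)
  }))
  ed <- NULL
  if (!is.null(events) && n > 0) {
    ed_ev <- events[events$code == ed_code, , drop = FALSE]
    pre_ids <- unique(ed_ev$patient_id[ed_ev$t <= 0])
    post_ids <- unique(ed_ev$patient_id[ed_ev$t > 0])
    ed <- data.frame(
      period = c("pre-delivery", "post-delivery"),
      n = c(sum(patients$patient_id %in% pre_ids),
            sum(patients$patient_id %in% post_ids)))
    ed$pct <- 100 * ed$n / n
  }
  structure(list(n = n, continuous = cont, categorical = cat_tab,
                 ed_visits = ed),
            class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Cohort summary (n = %d)\n", x$n))
  if (!is.null(x$continuous) && nrow(x$continuous)) {
    cat("  continuous, mean (SD):\n")
    for (i in seq_len(nrow(x$continuous)))
      cat(sprintf("    %-18s %.2f (%.2f)\n", x$continuous$variable[i],
                  x$continuous$mean[i], x$continuous$sd[i]))
  }
  if (!is.null(x$categorical) && nrow(x$categorical)) {
    cat("  categorical, N (%):\n")
    for (i in seq_len(nrow(x$categorical)))
      cat(sprintf("    %-12s %-12s %5d (%.2f)\n", x$categorical$variable[i],
                  x$categorical$level[i], x$categorical$n[i],
                  x$categorical$pct[i]))
  }
  if (!is.null(x$ed_visits)) {
    for (i in seq_len(nrow(x$ed_visits)))
      cat(sprintf("  >=1 %s ED visit: %d (%.2f%%)\n", x$ed_visits$period[i],
                  x$ed_visits$n[i], x$ed_visits$pct[i]))
  }
  invisible(x)
}
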