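# SPADE-style frequent sequential pattern mining over a vertical database.
#
# A sequence database holds, per patient, a strictly time-ordered list of
# itemsets (the set of event tokens recorded that day). Patterns are ordered
# lists of itemsets; a pattern is contained in a patient's sequence if its
# itemsets map to strictly increasing days whose recorded itemsets are
# supersets. Support counts distinct patients, once each, no matter how many
# embeddings exist.
#
# Mining works on vertical id-lists: for each pattern, the set of
# (patient, end-day) pairs at which some embedding of the pattern ends.
# Extensions are temporal joins of a pattern's id-list with a single item's
# occurrence list: the S-step appends the item as a new itemset at a
# strictly later day, the I-step adds it (in canonical lexicographic order)
# to the pattern's last itemset at the same day. Depth-first search over
# these prefix-equivalence classes with support pruning (anti-monotonicity)
# enumerates every frequent pattern exactly once.

#' Build a sequence database from patient sequences
#'
#' Groups each patient's same-day tokens into an itemset; days are strictly
#' increasing within a patient and itemsets are non-empty sets (duplicates
#' within a day are collapsed).
#'
#' @param sequences named list from [build_sequences()] (each element
#'   `list(patient_id, tokens, times)`)
#' @return object of class `sequence_db`: named list, per patient, of
#'   `times` (integer vector) and `itemsets` (list of sorted character
#'   vectors)
#' @export
as_sequence_db <- function(sequences) {
  db <- lapply(sequences, function(s) {
    sp <- split(s$tokens, s$times)
    times <- as.integer(names(sp))
    o <- order(times)
    list(times = times[o],
         itemsets = unname(lapply(sp[o], function(x) sort(unique(x)))))
  })
  names(db) <- names(sequences) %||%
    vapply(sequences, function(s) s$patient_id, "")
  structure(db, class = "sequence_db")
}

#' Vertical id-lists of single items
#'
#' For every distinct token, the (patient, day) occurrence list sorted by
#' (patient, day). The support of an item is its number of distinct
#' patients.
#'
#' @param db a [as_sequence_db()] database
#' @return named list of data frames with columns `sid`, `eid`
#' @export
to_vertical <- function(db) {
  if (!length(db)) stopf("empty sequence database")
  sids <- names(db)
  rows <- list()
  for (i in seq_along(db)) {
    times <- db[[i]]$times
    for (j in seq_along(times))
      for (item in db[[i]]$itemsets[[j]])
        rows[[length(rows) + 1L]] <- c(item = item, sid = sids[i],
                                       eid = times[j])
  }
  if (!length(rows)) return(list())
  m <- as.data.frame(do.call(rbind, rows), stringsAsFactors = FALSE)
  m$eid <- as.integer(m$eid)
  out <- split(m[c("sid", "eid")], m$item)
  lapply(out, function(d) {
    d <- d[order(d$sid, d$eid), , drop = FALSE]
    rownames(d) <- NULL
    d
  })
}

# distinct-patient support of an id-list
idlist_support <- function(idl) length(unique(idl$sid))

# S-step: item occurrences strictly later than some embedding end of P
s_join <- function(idl_p, idl_x) {
  first_end <- tapply(idl_p$eid, idl_p$sid, min)
  m <- first_end[idl_x$sid]
  keep <- !is.na(m) & idl_x$eid > m
  idl_x[keep, , drop = FALSE]
}

# I-step: item occurs on the very day an embedding of P ends
i_join <- function(idl_p, idl_x) {
  key_p <- paste(idl_p$sid, idl_p$eid)
  idl_x[paste(idl_x$sid, idl_x$eid) %in% key_p, , drop = FALSE]
}

pattern_length <- function(elements) sum(lengths(elements))

#' Render a pattern as a string
#'
#' Itemsets are joined with `+`, successive elements with `->`.
#' @param elements list of character vectors
#' @return character scalar
#' @export
pattern_string <- function(elements) {
  paste(vapply(elements, paste, "", collapse = "+"), collapse = " -> ")
}

#' Enumerate frequent sequential patterns (SPADE)
#'
#' Depth-first vertical mining: frequent single items seed the search, and
#' each frequent pattern is extended by every frequent item through the
#' S-step (new itemset, strictly later day) and, optionally, the I-step
#' (same-day addition to the last itemset, restricted to items
#' lexicographically after the itemset's current maximum so each pattern is
#' generated once). Candidates below the support floor are pruned, which is
#' exact by anti-monotonicity. Pattern length is the total number of items
#' across itemsets.
#'
#' @param db a [as_sequence_db()] database
#' @param minsup minimum support as a fraction of patients (0 < minsup <= 1);
#'   the count floor is `ceiling(minsup * n)`
#' @param max_len maximum pattern length
#' @param use_istep allow multi-item (same-day) elements; disable to mine
#'   pure event chains
#' @return list of patterns, each `list(elements, support, support_ids)`,
#'   sorted by support (desc) then pattern string
#' @export
enumerate_frequent <- function(db, minsup = 0.10, max_len = 5,
                               use_istep = TRUE) {
  if (minsup <= 0 || minsup > 1) stopf("minsup must lie in (0, 1]")
  if (max_len < 1) stopf("max_len must be at least 1")
  n <- length(db)
  floor_n <- ceiling(minsup * n)
  vert <- to_vertical(db)
  freq_items <- names(vert)[vapply(vert, idlist_support, 0L) >= floor_n]
  freq_items <- sort(freq_items)
  results <- list()
  grow <- function(elements, idl) {
    results[[length(results) + 1L]] <<- list(
      elements = elements, support = idlist_support(idl),
      support_ids = sort(unique(idl$sid)))
    if (pattern_length(elements) >= max_len) return(invisible())
    last <- elements[[length(elements)]]
    for (x in freq_items) {
      sx <- s_join(idl, vert[[x]])
      if (idlist_support(sx) >= floor_n)
        grow(c(elements, list(x)), sx)
      if (use_istep && x > last[length(last)]) {
        ix <- i_join(idl, vert[[x]])
        if (idlist_support(ix) >= floor_n) {
          el <- elements
          el[[length(el)]] <- c(last, x)
          grow(el, ix)
        }
      }
    }
  }
  for (x in freq_items) grow(list(x), vert[[x]])
  ord <- order(-vapply(results, `[[`, 0L, "support"),
               vapply(results, function(p) pattern_string(p$elements), ""))
  results[ord]
}

#' Does a sequence contain a pattern?
#'
#' Greedy earliest-match containment test: each pattern element must be a
#' subset of some itemset at a strictly later day than the previous match.
#' Greedy matching is exact for subsequence containment.
#'
#' @param seq one `sequence_db` entry (`times`, `itemsets`)
#' @param elements pattern as a list of character vectors
#' @return logical
#' @export
contains_pattern <- function(seq, elements) {
  j <- 1L
  last_t <- -Inf
  for (el in elements) {
    found <- FALSE
    while (j <= length(seq$times)) {
      if (seq$times[j] > last_t && all(el %in% seq$itemsets[[j]])) {
        last_t <- seq$times[j]
        found <- TRUE
        j <- j + 1L
        break
      }
      j <- j + 1L
    }
    if (!found) return(FALSE)
  }
  TRUE
}

#' Outcome-stratified support of a pattern
#'
#' Splits a pattern's supporting patients by PPD status via a containment
#' scan of the database (independent of the id-lists used for mining).
#'
#' @param pattern a pattern (`list(elements, ...)`) or bare element list
#' @param db a [as_sequence_db()] database
#' @param ppd_labels named logical vector covering the supporting patients
#' @return named integer vector `c(ppd, no_ppd)`
#' @export
stratify_pattern_support <- function(pattern, db, ppd_labels) {
  elements <- if (!is.null(pattern$elements)) pattern$elements else pattern
  sup <- names(db)[vapply(db, contains_pattern, TRUE, elements = elements)]
  if (any(!sup %in% names(ppd_labels)))
    stopf("PPD label missing for supporting patients: %s",
          paste(head(setdiff(sup, names(ppd_labels)), 5), collapse = ", "))
  lab <- ppd_labels[sup]
  c(ppd = sum(lab), no_ppd = sum(!lab))
}

#' Mine frequent patterns within each cluster
#'
#' Runs [enumerate_frequent()] on each cluster's sub-database and reports
#' per-pattern support, support fraction of the cluster, and the
#' PPD/no-PPD split when labels are supplied. Empty clusters yield empty
#' tables.
#'
#' @param db a [as_sequence_db()] database
#' @param cluster_labels named cluster labels covering `db`
#' @param minsup,max_len,use_istep passed to [enumerate_frequent()]
#' @param ppd_labels optional named logical vector for outcome splits
#' @return named list of data frames (pattern, length, support,
#'   support_frac, and ppd_n / no_ppd_n when labelled), one per cluster
#' @export
mine_per_cluster <- function(db, cluster_labels, minsup = 0.10, max_len = 5,
                             use_istep = TRUE, ppd_labels = NULL) {
  if (any(!names(db) %in% names(cluster_labels)))
    stopf("cluster label missing for some patients")
  out <- list()
  for (cl in sort(unique(cluster_labels[names(db)]))) {
    ids <- names(db)[cluster_labels[names(db)] == cl]
    sub <- structure(db[ids], class = "sequence_db")
    if (!length(sub)) {
      out[[as.character(cl)]] <- data.frame(pattern = character(0))
      next
    }
    pats <- enumerate_frequent(sub, minsup, max_len, use_istep)
    tab <- data.frame(
      pattern = vapply(pats, function(p) pattern_string(p$elements), ""),
      length = vapply(pats, function(p) pattern_length(p$elements), 0L),
      support = vapply(pats, `[[`, 0L, "support"),
      support_frac = vapply(pats, `[[`, 0L, "support") / length(sub),
      stringsAsFactors = FALSE)
    if (!is.null(ppd_labels)) {
      sp <- t(vapply(pats, stratify_pattern_support, c(ppd = 0L, no_ppd = 0L),
                     db = sub, ppd_labels = ppd_labels))
      tab$ppd_n <- sp[, "ppd"]
      tab$no_ppd_n <- sp[, "no_ppd"]
    }
    out[[as.character(cl)]] <- tab
  }
  out
}

#' Export per-cluster patterns as a tab-separated table
#'
#' @param mined result of [mine_per_cluster()]
#' @param path output TSV path
#' @return `path`, invisibly
#' @export
write_patterns_tsv <- function(mined, path) {
  rows <- lapply(names(mined), function(cl) {
    t <- mined[[cl]]
    if (!nrow(t)) return(NULL)
    cbind(cluster = cl, t)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab)) tab <- data.frame(cluster = character(0),
                                      pattern = character(0))
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
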