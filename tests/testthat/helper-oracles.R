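# Independent reference implementations used as oracles. These are written
# against the definitions, not against the package internals, and stay
# deliberately naive (full DP tables, exhaustive enumeration, O(n^3) loops).

# full-table LCS dynamic program in plain R
lcs_oracle <- function(a, b) {
  na <- length(a); nb <- length(b)
  M <- matrix(0L, na + 1, nb + 1)
  for (i in seq_len(na)) for (j in seq_len(nb))
    M[i + 1, j + 1] <- if (a[i] == b[j]) M[i, j] + 1L else
      max(M[i, j + 1], M[i + 1, j])
  M[na + 1, nb + 1]
}

random_sequence <- function(max_len = 30, vocab_size = 8, min_len = 0) {
  n <- sample(min_len:max_len, 1)
  if (n == 0) character(0) else
    sample(LETTERS[seq_len(vocab_size)], n, replace = TRUE)
}

# naive O(n^3) average-linkage agglomeration returning the partition at
# every k from n down to 2
naive_average_linkage <- function(D) {
  n <- nrow(D)
  groups <- as.list(seq_len(n))
  partitions <- list()
  partitions[[n]] <- seq_len(n)
  while (length(groups) > 2) {
    m <- length(groups)
    best <- c(Inf, NA, NA)
    for (i in seq_len(m - 1)) for (j in (i + 1):m) {
      d <- mean(D[groups[[i]], groups[[j]]])
      if (d < best[1]) best <- c(d, i, j)
    }
    groups[[best[2]]] <- c(groups[[best[2]]], groups[[best[3]]])
    groups[[best[3]]] <- NULL
    lab <- integer(n)
    for (g in seq_along(groups)) lab[groups[[g]]] <- g
    partitions[[length(groups)]] <- lab
  }
  partitions
}

# silhouette widths straight from the definition, one point at a time
silhouette_oracle <- function(D, labels) {
  n <- nrow(D)
  vapply(seq_len(n), function(i) {
    own <- setdiff(which(labels == labels[i]), i)
    if (!length(own)) return(0)
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(cl)
      mean(D[i, labels == cl]), 0))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, 0)
}

# --- sequential-pattern brute force -----------------------------------------

# backtracking containment check (independent of the greedy one in-package)
contains_oracle <- function(seq, elements, ei = 1L, from = 1L) {
  if (ei > length(elements)) return(TRUE)
  if (from > length(seq$times)) return(FALSE)
  for (j in from:length(seq$times)) {
    if (all(elements[[ei]] %in% seq$itemsets[[j]]) &&
        contains_oracle(seq, elements, ei + 1L, j + 1L))
      return(TRUE)
  }
  FALSE
}

pattern_key <- function(elements)
  paste(vapply(elements, paste, "", collapse = "+"), collapse = " -> ")

# every pattern (sequence of itemsets) embeddable in one patient sequence,
# up to max_len total items, by exhaustive day-subset/itemset-subset choice
patient_patterns <- function(seq, max_len) {
  nonempty_subsets <- function(x) {
    out <- list()
    for (sz in seq_along(x))
      out <- c(out, combn(x, sz, simplify = FALSE))
    out
  }
  acc <- new.env()
  extend <- function(elements, used, from) {
    if (used > 0) assign(pattern_key(elements), elements, envir = acc)
    if (used >= max_len || from > length(seq$times)) return(invisible())
    for (j in from:length(seq$times)) {
      for (sub in nonempty_subsets(seq$itemsets[[j]])) {
        if (used + length(sub) > max_len) next
        extend(c(elements, list(sort(sub))), used + length(sub), j + 1L)
      }
    }
  }
  extend(list(), 0L, 1L)
  as.list(acc)
}

# exhaustive frequent-pattern enumeration with direct containment counting
spade_bruteforce <- function(db, minsup, max_len) {
  floor_n <- ceiling(minsup * length(db))
  cand <- list()
  for (p in db) {
    pp <- patient_patterns(p, max_len)
    cand[names(pp)] <- pp
  }
  out <- list()
  for (key in names(cand)) {
    sup <- sum(vapply(db, contains_oracle, TRUE,
                      elements = cand[[key]]))
    if (sup >= floor_n) out[[key]] <- sup
  }
  out
}

random_sequence_db <- function(n_patients = 12, vocab_size = 4,
                               max_days = 6, max_per_day = 2) {
  vocab <- LETTERS[seq_len(vocab_size)]
  db <- lapply(seq_len(n_patients), function(i) {
    nd <- sample.int(max_days, 1)
    days <- sort(sample.int(30, nd))
    list(times = days,
         itemsets = lapply(seq_len(nd), function(j)
           sort(sample(vocab, sample.int(max_per_day, 1)))))
  })
  names(db) <- sprintf("S%02d", seq_len(n_patients))
  structure(db, class = "sequence_db")
}

# small event table helper
event_row <- function(id, t, type, code)
  data.frame(patient_id = id, t = t, event_type = type, code = code,
             stringsAsFactors = FALSE)

# rectangle polygon helper
rect_poly <- function(x0, y0, w, h)
  rbind(c(x0, y0), c(x0 + w, y0), c(x0 + w, y0 + h), c(x0, y0 + h))
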