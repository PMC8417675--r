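#' Longest common subsequence length
#'
#' Length of the longest ordered (not necessarily contiguous) token
#' sequence shared by `a` and `b`, by the classic dynamic program.
#' Symmetric in its arguments; zero when either sequence is empty.
#'
#' @param a,b character vectors of tokens
#' @return non-negative integer
#' @export
lcs_length <- function(a, b) {
  u <- unique(c(a, b))
  cpp_lcs_length(match(a, u), match(b, u))
}

#' LCS distance between two token sequences
#'
#' The similarity LCS(a, b) is turned into a distance in \[0, 1\]. With the
#' default max-length normalisation d = 1 - LCS/max(|a|, |b|): identical
#' sequences score 0, sequences with no common token score 1, and length
#' mismatch is penalised. Alternatives: `"mean"` (d = 1 - 2 LCS/(|a|+|b|))
#' and `"sum"` (d = 1 - LCS/(|a|+|b|), range \[1/2, 1\]).
#'
#' @param a,b character vectors; at least one must be non-empty
#' @param normalization `"max"`, `"mean"` or `"sum"`
#' @return distance in \[0, 1\]
#' @export
lcs_distance <- function(a, b, normalization = c("max", "mean", "sum")) {
  normalization <- match.arg(normalization)
  la <- length(a); lb <- length(b)
  if (la == 0 && lb == 0)
    stopf("LCS distance is undefined for two empty sequences")
  L <- lcs_length(a, b)
  denom <- switch(normalization, max = max(la, lb), mean = (la + lb) / 2,
                  sum = la + lb)
  1 - L / denom
}

#' Pairwise LCS distance matrix
#'
#' Computes all n(n-1)/2 pairwise LCS distances between patient sequences.
#' The heavy dynamic program runs in compiled code over integer-encoded
#' tokens; results are exact (no approximation or blocking artefacts).
#'
#' @param sequences named list of sequences: either character vectors or
#'   `list(patient_id, tokens, times)` records from [build_sequences()]
#' @param normalization passed to [lcs_distance()]
#' @return symmetric numeric matrix with patient ids as dimnames
#' @export
pairwise_distance_matrix <- function(sequences,
                                     normalization = c("max", "mean", "sum")) {
  normalization <- match.arg(normalization)
  toks <- lapply(sequences, function(s) if (is.list(s)) s$tokens else s)
  ids <- names(sequences) %||% as.character(seq_along(sequences))
  if (length(toks) < 2) stopf("need at least two sequences")
  if (any(lengths(toks) == 0)) stopf("empty sequences must be dropped upstream")
  vocab <- unique(unlist(toks, use.names = FALSE))
  enc <- lapply(toks, match, table = vocab)
  norm_code <- match(normalization, c("max", "mean", "sum")) - 1L
  D <- cpp_lcs_dist_matrix(enc, norm_code)
  dimnames(D) <- list(ids, ids)
  D
}

#' Cut an average-linkage hierarchy at k clusters
#'
#' Agglomerative clustering on a precomputed dissimilarity matrix.
#' Average linkage is the default because LCS distances carry no Euclidean
#' geometry (Ward assumes one); the hierarchy is deterministic given D.
#'
#' @param D symmetric distance matrix (as from
#'   [pairwise_distance_matrix()])
#' @param k number of clusters, 2 <= k <= n - 1 (k = n is allowed and
#'   returns singletons)
#' @param linkage linkage criterion passed to [stats::hclust()]
#' @return integer cluster labels named by patient id
#' @export
agglomerative_cluster <- function(D, k, linkage = "average") {
  n <- nrow(D)
  if (k < 1 || k > n) stopf("k must lie in [1, %d]", n)
  if (k == n) return(setNames(seq_len(n), rownames(D)))
  hc <- hclust(as.dist(D), method = linkage)
  cutree(hc, k = k)
}

#' Silhouette widths from a distance matrix
#'
#' s(i) = (b(i) - a(i)) / max(a(i), b(i)) with a(i) the mean distance to
#' the rest of i's cluster and b(i) the smallest mean distance to another
#' cluster; members of singleton clusters get s(i) = 0.
#'
#' @param D symmetric distance matrix
#' @param labels integer cluster labels aligned with D's rows
#' @return numeric vector of per-point widths
#' @export
silhouette_widths <- function(D, labels) {
  n <- nrow(D)
  labs <- unique(labels)
  if (length(labs) < 2) stopf("silhouette needs at least two clusters")
  idx <- split(seq_len(n), labels)
  sizes <- lengths(idx)
  s <- numeric(n)
  # mean distance from every point to every cluster, via column sums
  md <- vapply(idx, function(ii) colSums(D[ii, , drop = FALSE]), numeric(n))
  for (i in seq_len(n)) {
    ci <- as.character(labels[i])
    if (sizes[[ci]] == 1) { s[i] <- 0; next }
    a <- md[i, ci] / (sizes[[ci]] - 1)
    b <- min(md[i, setdiff(colnames(md), ci)] /
               sizes[setdiff(names(sizes), ci)])
    s[i] <- if (max(a, b) > 0) (b - a) / max(a, b) else 0
  }
  s
}

#' Cluster and select k by mean silhouette width
#'
#' Builds the average-linkage hierarchy once, cuts it at every k in
#' `k_range`, scores each cut by mean silhouette width and returns the
#' labels at the maximising k (ties go to the smallest k).
#'
#' @param D symmetric distance matrix
#' @param k_range candidate cluster counts (subset of 2..n-1)
#' @param linkage linkage criterion
#' @return object of class `clustering_result`: `labels`, `k`,
#'   `silhouette_by_k`, `linkage`
#' @export
silhouette_and_select_k <- function(D, k_range = 2:8, linkage = "average") {
  n <- nrow(D)
  k_range <- sort(unique(as.integer(k_range)))
  if (!length(k_range)) stopf("k_range must be non-empty")
  if (any(k_range < 2 | k_range > n - 1))
    stopf("k_range must lie within [2, n-1]")
  hc <- hclust(as.dist(D), method = linkage)
  cuts <- cutree(hc, k = k_range)
  if (length(k_range) == 1) cuts <- matrix(cuts, ncol = 1)
  sil <- setNames(vapply(seq_along(k_range), function(j)
    mean(silhouette_widths(D, cuts[, j])), 0), k_range)
  best <- k_range[which.max(sil)]
  structure(list(labels = setNames(cuts[, as.character(best)], rownames(D)),
                 k = best, silhouette_by_k = sil, linkage = linkage),
            class = "clustering_result")
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf("Hierarchical clustering (%s linkage): k = %d selected\n",
              x$linkage, x$k))
  cat("  mean silhouette by k:\n")
  for (k in names(x$silhouette_by_k))
    cat(sprintf("    k = %s: %.4f%s\n", k, x$silhouette_by_k[[k]],
                if (as.integer(k) == x$k) "  <- selected" else ""))
  cat("  cluster sizes:", paste(table(x$labels), collapse = ", "), "\n")
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items;
#' 1 = identical partitions, ~0 = chance agreement.
#'
#' @param a,b label vectors of equal length
#' @return numeric ARI
#' @export
adjusted_rand_index <- function(a, b) {
  if (length(a) != length(b)) stopf("label vectors differ in length")
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n2 <- comb2(length(a))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}
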