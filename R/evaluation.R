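#' External cluster validity indices
#'
#' Pair-counting and class-overlap agreement between a clustering and a
#' reference partition. All three indices are invariant to label renaming on
#' either argument.
#'
#' `adjusted_rand` is the chance-corrected Rand index: with `S = sum_ij
#' C(n_ij, 2)` over the contingency table, expectation `E = sum_i C(a_i, 2)
#' * sum_j C(b_j, 2) / C(n, 2)` under the generalized hypergeometric model
#' and maximum `M = (sum_i C(a_i, 2) + sum_j C(b_j, 2)) / 2`, the index is
#' `(S - E) / (M - E)`; it is 0 when `M == E` (degenerate partitions, e.g.
#' all singletons).
#'
#' `fowlkes_mallows` is the geometric mean of pairwise precision and recall:
#' `TP / sqrt((TP + FP) * (TP + FN))` over co-membership pairs, 0 when the
#' denominator vanishes.
#'
#' `purity` is the fraction of points lying in their cluster's majority true
#' class, `(1/N) * sum_clusters max_class overlap`; always in `(0, 1]`. Note
#' that an all-singleton clustering scores a perfect 1 (every cluster is
#' trivially pure), which is why purity is best reported alongside the
#' chance-corrected indices.
#'
#' @param a,b Label vectors of equal length (`clusters` and `truth` for
#'   `purity`).
#' @return Numeric scalar.
#' @export
adjusted_rand <- function(a, b) {
  ct <- unclass(cross_tabulate(a, b))
  choose2 <- function(x) x * (x - 1) / 2
  n <- sum(ct)
  S <- sum(choose2(ct))
  E <- sum(choose2(rowSums(ct))) * sum(choose2(colSums(ct))) / choose2(n)
  M <- (sum(choose2(rowSums(ct))) + sum(choose2(colSums(ct)))) / 2
  if (M == E) return(0)
  (S - E) / (M - E)
}

#' @rdname adjusted_rand
#' @export
fowlkes_mallows <- function(a, b) {
  ct <- unclass(cross_tabulate(a, b))
  choose2 <- function(x) x * (x - 1) / 2
  tp <- sum(choose2(ct))
  pa <- sum(choose2(rowSums(ct)))  # tp + fp
  pb <- sum(choose2(colSums(ct)))  # tp + fn
  if (pa == 0 || pb == 0) return(0)
  tp / sqrt(pa * pb)
}

#' @rdname adjusted_rand
#' @param clusters,truth Label vectors for `purity`.
#' @export
purity <- function(clusters, truth) {
  ct <- unclass(cross_tabulate(clusters, truth))
  sum(apply(ct, 1, max)) / sum(ct)
}

#' Cross-tabulate two label vectors
#'
#' Counts joint label occurrences; rows and columns appear in order of first
#' appearance in each vector.
#'
#' @param a,b Label vectors of equal length.
#' @return A `contingency_table`: an integer matrix with row/column names.
#' @export
cross_tabulate <- function(a, b) {
  if (length(a) != length(b)) {
    stop("label vectors must have equal length (", length(a), " vs ",
         length(b), ")")
  }
  ra <- unique(as.character(a)); rb <- unique(as.character(b))
  ct <- table(factor(as.character(a), levels = ra),
              factor(as.character(b), levels = rb))
  m <- matrix(as.integer(ct), nrow = length(ra),
              dimnames = list(ra, rb))
  structure(m, class = c("contingency_table", class(m)))
}

#' Pearson chi-square statistic of a contingency table
#'
#' The basic test of association, `sum (O - E)^2 / E` with `E = row total *
#' column total / grand total` and `(r - 1)(c - 1)` degrees of freedom; no
#' continuity correction.
#'
#' @param t A `contingency_table` or plain count matrix with all row and
#'   column totals positive.
#' @return List with elements `statistic` and `df`.
#' @export
chi_square <- function(t) {
  m <- unclass(as.matrix(t))
  if (any(rowSums(m) == 0) || any(colSums(m) == 0)) {
    stop("chi-square requires all row and column totals to be positive")
  }
  ht <- suppressWarnings(stats::chisq.test(m, correct = FALSE))
  list(statistic = unname(ht$statistic), df = unname(ht$parameter))
}

#' Average silhouette width for a clustering of a distance matrix
#'
#' For each point, `a` is its mean distance to the other members of its own
#' cluster and `b` the smallest mean distance to any other cluster; the
#' silhouette is `(b - a) / max(a, b)`. Members of singleton clusters score
#' 0 by convention. Requires at least two clusters.
#'
#' @param d A `distance_matrix`.
#' @param labels Cluster labels aligned with the matrix.
#' @return Mean silhouette width over all points.
#' @export
silhouette_avg <- function(d, labels) {
  m <- unclass(as.matrix(d))
  labels <- as.vector(labels)
  if (length(labels) != nrow(m)) stop("labels must align with the matrix")
  cl <- unique(labels)
  if (length(cl) < 2L) stop("silhouette requires at least 2 clusters")
  s <- vapply(seq_along(labels), function(i) {
    own <- which(labels == labels[i])
    if (length(own) == 1L) return(0)  # singleton convention
    a <- mean(m[i, setdiff(own, i)])
    b <- min(vapply(setdiff(cl, labels[i]), function(g) {
      mean(m[i, labels == g])
    }, numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' Dunn index for a clustering of a distance matrix
#'
#' Minimum between-cluster separation (smallest cross-pair distance over all
#' cluster pairs) divided by maximum cluster diameter (largest within-pair
#' distance over all clusters). When every cluster is a singleton the
#' maximum diameter is 0 and `Inf` is returned as a sentinel.
#'
#' @inheritParams silhouette_avg
#' @return Numeric scalar (possibly `Inf`).
#' @export
dunn_index <- function(d, labels) {
  m <- unclass(as.matrix(d))
  labels <- as.vector(labels)
  if (length(labels) != nrow(m)) stop("labels must align with the matrix")
  cl <- unique(labels)
  if (length(cl) < 2L) stop("Dunn index requires at least 2 clusters")
  diam <- max(vapply(cl, function(g) {
    idx <- which(labels == g)
    if (length(idx) < 2L) 0 else max(m[idx, idx])
  }, numeric(1)))
  sep <- min(vapply(seq_len(length(cl) - 1L), function(i) {
    min(vapply((i + 1L):length(cl), function(j) {
      min(m[labels == cl[i], labels == cl[j], drop = FALSE])
    }, numeric(1)))
  }, numeric(1)))
  if (diam == 0) return(Inf)
  sep / diam
}

#' Write a tidy metric CSV
#'
#' Two columns, `metric,value` — the dialect used by the workflow reports.
#'
#' @param metrics Named numeric vector.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_metrics_csv <- function(metrics, path) {
  df <- data.frame(metric = names(metrics), value = as.vector(metrics))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
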