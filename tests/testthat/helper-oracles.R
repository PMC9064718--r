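`%||%` <- function(a, b) if (is.null(a)) b else a

# Independent brute-force oracles used to validate the dynamic-programming
# and contingency-table implementations. These enumerate explicitly and never
# share code with the package internals.

# Exhaustive enumeration over all monotone warping paths / couplings from
# (1,1) to (p,q); feasible for lengths <= ~7.
enum_elastic <- function(x, y, kind = c("dtw", "frechet")) {
  kind <- match.arg(kind)
  p <- length(x); q <- length(y)
  best <- Inf
  rec <- function(i, j, acc) {
    step <- abs(x[i] - y[j])
    acc <- if (kind == "dtw") acc + step else max(acc, step)
    if (acc >= best) return(invisible(NULL))  # bound only, never alters result
    if (i == p && j == q) {
      best <<- acc
      return(invisible(NULL))
    }
    if (i < p && j < q) rec(i + 1, j + 1, acc)
    if (i < p) rec(i + 1, j, acc)
    if (j < q) rec(i, j + 1, acc)
  }
  rec(1, 1, if (kind == "dtw") 0 else -Inf)
  best
}

# Pair-counting indices computed by explicit O(n^2) enumeration of all
# unordered pairs.
paircount_indices <- function(a, b) {
  n <- length(a)
  tp <- fp <- fn <- tn <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) tp <- tp + 1
      else if (sa && !sb) fp <- fp + 1
      else if (!sa && sb) fn <- fn + 1
      else tn <- tn + 1
    }
  }
  total <- tp + fp + fn + tn
  rand <- (tp + tn) / total
  exp_idx <- (tp + fp) * (tp + fn) / total
  max_idx <- ((tp + fp) + (tp + fn)) / 2
  ari <- if (max_idx == exp_idx) 0 else (tp - exp_idx) / (max_idx - exp_idx)
  fm <- if ((tp + fp) == 0 || (tp + fn) == 0) 0 else
    tp / sqrt((tp + fp) * (tp + fn))
  list(tp = tp, rand = rand, ari = ari, fm = fm)
}

purity_oracle <- function(clusters, truth) {
  s <- 0
  for (g in unique(clusters)) {
    s <- s + max(table(truth[clusters == g]))
  }
  s / length(clusters)
}

random_trajectory_values <- function(max_len = 6, min_len = 1) {
  n <- sample(min_len:max_len, 1)
  round(stats::rnorm(n, sd = 2), 3)
}

# a random small ultrametric built from a random hierarchy
random_dendrogram <- function(n) {
  d <- distance_matrix_from_random(n)
  complete_linkage(d)
}

distance_matrix_from_random <- function(n) {
  x <- matrix(stats::rnorm(n * 3), n)
  distance_matrix(as.matrix(stats::dist(x)),
                  labels = paste0("s", seq_len(n)))
}

# tiny profile set of scalar-trend subjects for workflow tests
toy_profiles <- function(values_by_subject, marker = "m") {
  profile_set(lapply(names(values_by_subject), function(id) {
    v <- values_by_subject[[id]]
    trajectory(id, seq_along(v), v, marker = marker)
  }))
}
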