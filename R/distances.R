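#' Elastic and reference distances between trajectories
#'
#' Both elastic distances operate on the ordered value sequences only:
#' timestamps provide ordering, not coordinates, so similarly shaped profiles
#' observed at different times (or at different numbers of visits) compare as
#' close. The local distance between scalar values is the absolute
#' difference. `dtw_distance` returns the classic unnormalized dynamic time
#' warping distance — the minimum over warping paths of the summed local
#' distance, with steps (i-1,j), (i,j-1), (i-1,j-1) and each cell's cost
#' counted once; no window constraint, no path-length normalization.
#' `frechet_distance` returns the discrete Frechet distance — the minimum
#' over couplings of the maximum node distance along the coupling.
#'
#' Ties among equal-cost paths/couplings are broken deterministically during
#' backtracking: diagonal step first, then an advance in the first curve,
#' then an advance in the second.
#'
#' @param p,q `trajectory` objects (or bare numeric value vectors).
#' @return A list with elements `distance` (numeric scalar) and `path` (for
#'   DTW) or `coupling` (for Frechet): a two-column integer matrix of aligned
#'   index pairs into `p` and `q`.
#' @seealso [pairwise_matrix()] for all-pairs matrices.
#' @examples
#' dtw_distance(c(0, 0, 1), c(0, 1))$distance   # 0: warping absorbs the repeat
#' frechet_distance(c(0, 2), c(0, 1, 2))$distance  # 1: middle node is unavoidable
#' @export
dtw_distance <- function(p, q) {
  x <- traj_values(p); y <- traj_values(q)
  acc <- elastic_dp(x, y, kind = "dtw")
  list(distance = acc[length(x), length(y)],
       path = backtrack(acc, x, y, kind = "dtw"))
}

#' @rdname dtw_distance
#' @export
frechet_distance <- function(p, q) {
  x <- traj_values(p); y <- traj_values(q)
  acc <- elastic_dp(x, y, kind = "frechet")
  list(distance = acc[length(x), length(y)],
       coupling = backtrack(acc, x, y, kind = "frechet"))
}

#' Euclidean distance between equal-length trajectories
#'
#' Provided as the non-elastic reference: the L2 norm of the value
#' difference vector. Unlike the elastic distances it requires that all
#' profiles be of the same length.
#'
#' @inheritParams dtw_distance
#' @return Numeric scalar.
#' @export
euclidean_distance <- function(p, q) {
  x <- traj_values(p); y <- traj_values(q)
  if (length(x) != length(y)) {
    stop("euclidean distance requires that all profiles be of the same length (",
         length(x), " vs ", length(y), ")")
  }
  sqrt(sum((x - y)^2))
}

traj_values <- function(p) {
  v <- if (inherits(p, "trajectory")) p$values else as.numeric(p)
  if (length(v) == 0L) stop("empty trajectory")
  v
}

# full accumulated-cost matrix; kind "dtw" sums local costs, "frechet" takes
# the running maximum
elastic_dp <- function(x, y, kind) {
  p <- length(x); q <- length(y)
  local <- abs(outer(x, y, "-"))
  acc <- matrix(NA_real_, p, q)
  comb <- if (kind == "dtw") `+` else pmax
  acc[1, 1] <- local[1, 1]
  for (j in seq_len(q)[-1]) acc[1, j] <- comb(acc[1, j - 1], local[1, j])
  for (i in seq_len(p)[-1]) {
    acc[i, 1] <- comb(acc[i - 1, 1], local[i, 1])
    if (q > 1) {
      for (j in 2:q) {
        acc[i, j] <- comb(min(acc[i - 1, j - 1], acc[i - 1, j], acc[i, j - 1]),
                          local[i, j])
      }
    }
  }
  acc
}

# deterministic backtrack: prefer diagonal, then i-advance, then j-advance
backtrack <- function(acc, x, y, kind) {
  i <- length(x); j <- length(y)
  local <- abs(outer(x, y, "-"))
  comb <- if (kind == "dtw") `+` else pmax
  pairs <- matrix(c(i, j), ncol = 2)
  while (i > 1 || j > 1) {
    cand <- list()
    if (i > 1 && j > 1) cand$diag <- acc[i - 1, j - 1]
    if (i > 1) cand$up <- acc[i - 1, j]
    if (j > 1) cand$left <- acc[i, j - 1]
    pred <- unlist(cand)
    # any predecessor that reproduces this cell's value is optimal
    ok <- names(pred)[comb(pred, local[i, j]) <= acc[i, j] + 1e-12]
    step <- intersect(c("diag", "up", "left"), ok)[1]
    if (step == "diag") { i <- i - 1; j <- j - 1 }
    else if (step == "up") i <- i - 1
    else j <- j - 1
    pairs <- rbind(c(i, j), pairs)
  }
  colnames(pairs) <- c("p", "q")
  pairs
}

#' All-pairs distance matrix over a profile set
#'
#' Computes each off-diagonal entry once with the requested metric and
#' mirrors it; the diagonal is zero. The heavy lifting runs in compiled code.
#'
#' @param set A `profile_set`.
#' @param metric One of `"dtw"`, `"frechet"`, `"euclidean"`.
#' @return A `distance_matrix`: square symmetric numeric matrix with subject
#'   ids as dimnames, in the set's stable subject order.
#' @export
pairwise_matrix <- function(set, metric = c("dtw", "frechet", "euclidean")) {
  stopifnot(inherits(set, "profile_set"))
  metric <- match.arg(metric)
  vals <- unname(values_list(set))
  if (any(lengths(vals) == 0L)) stop("empty trajectory")
  if (metric == "euclidean" && length(unique(lengths(vals))) > 1L) {
    stop("euclidean distance requires that all profiles be of the same length")
  }
  code <- match(metric, c("dtw", "frechet", "euclidean")) - 1L
  m <- cpp_pairwise(vals, code)
  distance_matrix(m, subject_ids(set))
}

#' Construct a labeled distance matrix
#'
#' @param m Square symmetric numeric matrix with zero diagonal and
#'   non-negative entries.
#' @param labels Subject ids for rows/columns.
#' @param tol Symmetry/diagonal tolerance.
#' @return A `distance_matrix` (a numeric matrix with class attribute).
#' @export
distance_matrix <- function(m, labels = rownames(m), tol = 1e-8) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m)) stop("distance matrix must be square")
  if (is.null(labels)) labels <- as.character(seq_len(nrow(m)))
  scale <- max(abs(m), 1)
  if (max(abs(m - t(m))) > tol * scale) stop("distance matrix must be symmetric")
  if (max(abs(diag(m))) > tol * scale) stop("distance matrix must have zero diagonal")
  if (min(m) < -tol * scale) stop("distance matrix entries must be non-negative")
  m <- (m + t(m)) / 2
  diag(m) <- 0
  dimnames(m) <- list(labels, labels)
  class(m) <- c("distance_matrix", class(m))
  m
}

#' Rescale a distance matrix by a positive factor
#'
#' Multiplicative rescaling leaves any linkage-based clustering of the single
#' matrix unchanged (merge order is scale invariant) but changes the weight
#' the view carries in a least-squares consensus. The HIV-style workflow
#' rescales viral-load distances by 300 to bring them onto the CD4 scale.
#'
#' @param m A `distance_matrix`.
#' @param factor Positive multiplier.
#' @return The rescaled `distance_matrix`.
#' @export
rescale <- function(m, factor) {
  stopifnot(inherits(m, "distance_matrix"))
  if (!is.numeric(factor) || length(factor) != 1L || factor <= 0) {
    stop("rescale factor must be a positive number")
  }
  distance_matrix(unclass(m) * factor, rownames(m))
}

#' Suggest a rescaling factor matching two views' distance scales
#'
#' Returns the ratio of the views' median off-diagonal distances, a helper
#' for harmonizing scales before consensus; the choice remains the caller's.
#'
#' @param reference,view `distance_matrix` objects.
#' @return Positive scalar such that `rescale(view, factor)` has the same
#'   median off-diagonal distance as `reference`.
#' @export
suggest_rescale_factor <- function(reference, view) {
  med <- function(m) stats::median(m[upper.tri(m)])
  m1 <- med(reference); m2 <- med(view)
  if (m2 <= 0) stop("view has zero median distance; cannot suggest a factor")
  m1 / m2
}

#' Write / read a distance matrix as CSV
#'
#' Full square matrix with a header row and a leading column of subject ids,
#' 12 significant digits.
#'
#' @param m A `distance_matrix`.
#' @param path File path.
#' @return `write_distance_csv` returns `path` invisibly; `read_distance_csv`
#'   returns a `distance_matrix`.
#' @export
write_distance_csv <- function(m, path) {
  stopifnot(inherits(m, "distance_matrix"))
  df <- as.data.frame(signif(unclass(m), 12))
  df <- cbind(subject_id = rownames(m), df)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_distance_csv
#' @export
read_distance_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = c(subject_id = "character"))
  labels <- df$subject_id
  m <- as.matrix(df[, -1, drop = FALSE])
  distance_matrix(m, labels)
}
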