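#' Agglomerative hierarchical clustering of a distance matrix
#'
#' Thin, label-preserving wrappers around `stats::hclust`. Complete linkage
#' (inter-cluster distance = maximum cross-pair distance) is the default used
#' throughout the pipelines; single linkage is used internally to finalize
#' consensus ultrametrics, and average linkage is provided for sensitivity
#' analyses.
#'
#' @param d A `distance_matrix` with at least two subjects.
#' @param method Linkage: `"complete"`, `"single"`, or `"average"`.
#' @return An `hclust` object whose `labels` are the subject ids; merge
#'   heights are the inter-cluster distances at each merge and are
#'   non-decreasing for complete linkage.
#' @export
linkage <- function(d, method = c("complete", "single", "average")) {
  stopifnot(inherits(d, "distance_matrix"))
  method <- match.arg(method)
  if (nrow(d) < 2L) stop("clustering needs at least 2 subjects")
  stats::hclust(stats::as.dist(unclass(d)), method = method)
}

#' @rdname linkage
#' @export
complete_linkage <- function(d) linkage(d, "complete")

#' Cophenetic distance matrix of a dendrogram
#'
#' Entry (i, j) is the merge height of the lowest internal node joining
#' leaves i and j — the canonical dendrogram descriptor. The result always
#' satisfies the ultrametric inequality.
#'
#' @param h An `hclust` object.
#' @return An `ultrametric_matrix` in leaf-label order.
#' @export
cophenetic_matrix <- function(h) {
  stopifnot(inherits(h, "hclust"))
  m <- as.matrix(stats::cophenetic(h))
  lab <- if (is.null(h$labels)) as.character(seq_len(nrow(m))) else h$labels
  m <- m[lab, lab]
  ultrametric_matrix(m, lab)
}

#' Cluster-membership-divergence matrix of a dendrogram
#'
#' Alternative dendrogram descriptor: entry (i, j) is the number of leaves
#' under the lowest node containing both i and j (the size of the smallest
#' dendrogram cluster holding the pair); the diagonal is zero. Also
#' ultrametric.
#'
#' @param h An `hclust` object.
#' @return An `ultrametric_matrix`.
#' @export
membership_divergence_matrix <- function(h) {
  stopifnot(inherits(h, "hclust"))
  n <- length(h$order)
  lab <- if (is.null(h$labels)) as.character(seq_len(n)) else h$labels
  m <- matrix(0, n, n)
  members <- vector("list", n - 1L)  # leaves under each internal node
  for (s in seq_len(n - 1L)) {
    side <- function(x) if (x < 0) -x else members[[x]]
    a <- side(h$merge[s, 1]); b <- side(h$merge[s, 2])
    m[a, b] <- length(a) + length(b)
    m[b, a] <- length(a) + length(b)
    members[[s]] <- c(a, b)
  }
  ultrametric_matrix(m, lab)
}

#' Cut a dendrogram into k groups
#'
#' Removes the k-1 highest merges. Cluster numbering is deterministic:
#' clusters are numbered by the smallest leaf index they contain (cluster 1
#' holds leaf 1).
#'
#' @param h An `hclust` object.
#' @param k Number of groups, between 1 and the number of leaves.
#' @return Integer vector of cluster labels named by subject id.
#' @export
cut_dendrogram <- function(h, k) {
  stopifnot(inherits(h, "hclust"))
  n <- length(h$order)
  if (k < 1 || k > n) stop("k must be between 1 and ", n)
  stats::cutree(h, k = k)
}

#' Test a matrix for the ultrametric inequality
#'
#' Checks `m[i,k] <= max(m[i,j], m[j,k])` over all triples, up to `tol`,
#' and reports the worst-violating triple.
#'
#' @param m Square symmetric numeric matrix.
#' @param tol Absolute tolerance; defaults to `1e-8 * max(m)`.
#' @return Logical scalar with attributes `violation` (worst excess) and
#'   `triple` (indices `(i, j, k)` with `j` the intermediate).
#' @export
is_ultrametric <- function(m, tol = 1e-8 * max(m, 0)) {
  m <- unclass(as.matrix(m))
  if (nrow(m) != ncol(m)) stop("is_ultrametric needs a square matrix")
  w <- cpp_worst_violation(m)
  ok <- w$violation <= tol
  structure(ok, violation = w$violation, triple = w$triple)
}

#' Construct an ultrametric matrix object
#'
#' @param m Square symmetric non-negative matrix with zero diagonal
#'   satisfying the ultrametric inequality within `tol`.
#' @param labels Subject ids.
#' @param tol Tolerance passed to [is_ultrametric()].
#' @return An `ultrametric_matrix` (also a `distance_matrix`).
#' @export
ultrametric_matrix <- function(m, labels = rownames(m),
                               tol = 1e-8 * max(m, 0)) {
  d <- distance_matrix(m, labels)
  chk <- is_ultrametric(unclass(d), tol = tol)
  if (!chk) {
    tr <- attr(chk, "triple")
    stop("matrix is not ultrametric: triple (", paste(tr, collapse = ", "),
         ") violates the inequality by ", format(attr(chk, "violation")))
  }
  class(d) <- c("ultrametric_matrix", class(d))
  d
}

#' Recover the dendrogram of an ultrametric matrix
#'
#' For an ultrametric, agglomeration at the sorted distinct values is exact
#' and linkage choice is immaterial; single linkage is used, so
#' `cophenetic_matrix(dendrogram_from_ultrametric(u))` reproduces `u` (the
#' hierarchy/ultrametric bijection). Equal heights across disjoint groups
#' yield a binary tree with consecutive merges at the same height.
#'
#' @param u An `ultrametric_matrix`, or a plain matrix that passes
#'   [is_ultrametric()] within `tol`.
#' @param tol Tolerance for the ultrametric check.
#' @return An `hclust` object.
#' @export
dendrogram_from_ultrametric <- function(u, tol = 1e-8 * max(u, 0)) {
  m <- unclass(as.matrix(u))
  chk <- is_ultrametric(m, tol = tol)
  if (!chk) {
    tr <- attr(chk, "triple")
    stop("input is not ultrametric within tolerance: worst triple (",
         paste(tr, collapse = ", "), "), excess ",
         format(attr(chk, "violation")))
  }
  stats::hclust(stats::as.dist(m), method = "single")
}

#' Export / import a dendrogram as Newick
#'
#' Branch lengths follow the usual tree convention in which the root-to-leaf
#' path length equals half the merge height, so the patristic (path) distance
#' between two leaves equals their cophenetic distance. The writer prepends
#' `#`-comment lines stating the convention and the exact merge heights; the
#' reader skips them and rebuilds the `hclust` from the leaf-to-leaf path
#' distances.
#'
#' @param h An `hclust` object.
#' @param path File path.
#' @return `write_newick` returns `path` invisibly; `read_newick` returns an
#'   `hclust`.
#' @export
write_newick <- function(h, path) {
  stopifnot(inherits(h, "hclust"))
  phy <- ape::as.phylo(h)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    "# trajensemble dendrogram; root-to-leaf path length = merge height / 2",
    paste0("# merge heights: ",
           paste(format(h$height, digits = 17), collapse = ","))
  ), con)
  writeLines(ape::write.tree(phy), con)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(trimws(lines), "#")]
  phy <- ape::read.tree(text = paste(lines, collapse = "\n"))
  m <- as.matrix(stats::cophenetic(phy))  # patristic = cophenetic heights
  # snap tiny float asymmetries from branch-length round trips
  m <- (m + t(m)) / 2
  dendrogram_from_ultrametric(
    ultrametric_matrix(m, rownames(m), tol = 1e-6 * max(m, 1)))
}

#' Write cluster labels as CSV
#'
#' Two columns, `subject_id,cluster`.
#'
#' @param labels Named vector as returned by [cut_dendrogram()].
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_labels_csv <- function(labels, path) {
  df <- data.frame(subject_id = names(labels), cluster = as.vector(labels))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
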