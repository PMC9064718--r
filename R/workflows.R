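#' Configuration for the shape-distance benchmark harness
#'
#' Drives the cylinder-bell-funnel comparison of elastic distances under
#' missingness: one base set is generated from `cbf`, optionally thinned to
#' every `sparse_step`-th point, and each nonzero missingness fraction is
#' evaluated on `n_reps` independent MCAR draws from that fixed base set
#' (fraction 0 is a single evaluation of the base set itself). Setting
#' `regenerate_base = TRUE` instead draws a fresh base set per rep, for
#' variance decomposition.
#'
#' @param cbf A [cbf_config()].
#' @param sparse_step `NULL` for the full variant or an integer step for
#'   [sparsify()].
#' @param missing_fractions Numeric vector of MCAR fractions (0 allowed).
#' @param n_reps MCAR draws per nonzero fraction.
#' @param metrics Subset of `c("dtw", "frechet", "euclidean")`; euclidean is
#'   only valid at fraction 0, where profiles still share a common length.
#' @param linkage_method Linkage for the base clusterings.
#' @param k Number of groups to cut (3 = the number of shape classes).
#' @param seed Master seed; all per-rep seeds are derived from it.
#' @param regenerate_base Draw a fresh base set each rep.
#' @return A list of class `benchmark_config`.
#' @export
benchmark_config <- function(cbf = cbf_config(), sparse_step = NULL,
                             missing_fractions = c(0, 0.25, 0.5),
                             n_reps = 500,
                             metrics = c("dtw", "frechet"),
                             linkage_method = "complete", k = 3, seed = 1,
                             regenerate_base = FALSE) {
  stopifnot(n_reps >= 1, k >= 1,
            all(metrics %in% c("dtw", "frechet", "euclidean")))
  if ("euclidean" %in% metrics && any(missing_fractions > 0)) {
    stop("euclidean distance cannot be evaluated under missingness: ",
         "removal leaves profiles of unequal length")
  }
  structure(list(cbf = cbf, sparse_step = sparse_step,
                 missing_fractions = missing_fractions,
                 n_reps = as.integer(n_reps), metrics = metrics,
                 linkage_method = linkage_method, k = as.integer(k),
                 seed = as.integer(seed),
                 regenerate_base = isTRUE(regenerate_base)),
            class = "benchmark_config")
}

score_clustering <- function(d, truth, linkage_method, k) {
  h <- linkage(d, linkage_method)
  lab <- cut_dendrogram(h, k)
  c(adj_rand = adjusted_rand(lab, truth),
    fowlkes_mallows = fowlkes_mallows(lab, truth),
    purity = purity(lab, truth))
}

#' Run the CBF shape-distance benchmark
#'
#' For every (fraction, metric) pair: generate/receive the base set, apply
#' MCAR, compute the pairwise distance matrix, cluster, cut at `k`, and
#' score adjusted Rand, Fowlkes-Mallows and purity against the true shape
#' labels; aggregate across reps as mean and sd.
#'
#' @param config A [benchmark_config()].
#' @return A data frame of class `benchmark_result` with one row per
#'   (variant, fraction, metric, index): columns `variant`, `fraction`,
#'   `metric`, `index`, `mean`, `sd`, `n_reps`. `sd` is 0 for the
#'   single-evaluation fraction-0 rows.
#' @export
run_cbf_benchmark <- function(config = benchmark_config()) {
  stopifnot(inherits(config, "benchmark_config"))
  set.seed(config$seed)
  n_cells <- config$n_reps * length(config$missing_fractions)
  seed_pool <- sample.int(.Machine$integer.max - 1L, n_cells)
  base_seed_pool <- sample.int(.Machine$integer.max - 1L, n_cells)
  variant <- if (is.null(config$sparse_step)) "full" else "sparse"
  make_base <- function(seed) {
    cfg <- config$cbf; cfg$seed <- seed
    base <- generate_cbf(cfg)
    if (!is.null(config$sparse_step)) base <- sparsify(base, config$sparse_step)
    base
  }
  base <- make_base(config$cbf$seed)
  rows <- list()
  si <- 0L
  for (f in config$missing_fractions) {
    if (f == 0) {
      scores <- lapply(config$metrics, function(met) {
        d <- pairwise_matrix(base$profiles, met)
        score_clustering(d, base$labels, config$linkage_method, config$k)
      })
      for (mi in seq_along(config$metrics)) {
        rows[[length(rows) + 1L]] <- data.frame(
          variant = variant, fraction = f, metric = config$metrics[mi],
          index = names(scores[[mi]]), mean = unname(scores[[mi]]),
          sd = 0, n_reps = 1L)
      }
    } else {
      acc <- lapply(config$metrics, function(m) {
        matrix(NA_real_, config$n_reps, 3,
               dimnames = list(NULL, c("adj_rand", "fowlkes_mallows", "purity")))
      })
      names(acc) <- config$metrics
      for (rep in seq_len(config$n_reps)) {
        si <- si + 1L
        this_base <- if (config$regenerate_base) {
          make_base(base_seed_pool[si])
        } else {
          base
        }
        thinned <- apply_mcar(this_base, mcar_config(f, seed = seed_pool[si]))
        for (met in config$metrics) {
          d <- pairwise_matrix(thinned$profiles, met)
          acc[[met]][rep, ] <- score_clustering(d, thinned$labels,
                                                config$linkage_method, config$k)
        }
      }
      for (met in config$metrics) {
        m <- acc[[met]]
        rows[[length(rows) + 1L]] <- data.frame(
          variant = variant, fraction = f, metric = met,
          index = colnames(m), mean = colMeans(m),
          sd = if (config$n_reps > 1) apply(m, 2, stats::sd) else 0,
          n_reps = config$n_reps)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_result", class(out))
  out
}

#' Univariate shape-based clustering pipeline
#'
#' Applies the optional preprocessing (visit filter, quantitation-limit
#' clamping, log10), computes the pairwise elastic distance matrix, clusters
#' by the chosen linkage, cuts at `k`, and reports the internal validity
#' indices.
#'
#' @param profiles A `profile_set`.
#' @param metric Distance metric for [pairwise_matrix()].
#' @param k Number of clusters for the cut (the biomarker workflows use 3).
#' @param min_visits Optional [filter_min_visits()] threshold.
#' @param censor Optional `c(lower, upper)` for [censor_limits()].
#' @param log10_transform Apply [log10_values()] (after censoring).
#' @param linkage_method Linkage method.
#' @return List of class `univariate_fit`: `labels`, `dendrogram`,
#'   `distance` (`distance_matrix`), `profiles` (after preprocessing) and
#'   `report` (named vector with silhouette and Dunn).
#' @export
run_univariate <- function(profiles, metric = "dtw", k = 3,
                           min_visits = NULL, censor = NULL,
                           log10_transform = FALSE,
                           linkage_method = "complete") {
  stopifnot(inherits(profiles, "profile_set"))
  ps <- profiles
  if (!is.null(min_visits)) ps <- filter_min_visits(ps, min_visits)
  if (!is.null(censor)) ps <- censor_limits(ps, censor[1], censor[2])
  if (log10_transform) ps <- log10_values(ps)
  if (length(ps) < 2L) stop("fewer than 2 profiles after filtering")
  d <- pairwise_matrix(ps, metric)
  h <- linkage(d, linkage_method)
  lab <- cut_dendrogram(h, k)
  report <- if (k >= 2) {
    c(silhouette = silhouette_avg(d, lab), dunn = dunn_index(d, lab))
  } else {
    c(silhouette = NA_real_, dunn = NA_real_)
  }
  structure(list(labels = lab, dendrogram = h, distance = d, profiles = ps,
                 report = report),
            class = "univariate_fit")
}

#' Describe one view for the ensemble pipeline
#'
#' @param profiles A `profile_set`.
#' @param metric Distance metric.
#' @param rescale_factor Positive factor applied to the view's distance
#'   matrix before clustering (harmonizes scales across views; does not
#'   change the view's own clustering).
#' @param k Cut level for the view's univariate report.
#' @param min_visits,censor,log10_transform Preprocessing, as in
#'   [run_univariate()].
#' @return A list of class `ensemble_view`.
#' @export
ensemble_view <- function(profiles, metric = "dtw", rescale_factor = 1,
                          k = 3, min_visits = NULL, censor = NULL,
                          log10_transform = FALSE) {
  stopifnot(inherits(profiles, "profile_set"), rescale_factor > 0)
  structure(list(profiles = profiles, metric = metric,
                 rescale_factor = rescale_factor, k = k,
                 min_visits = min_visits, censor = censor,
                 log10_transform = log10_transform),
            class = "ensemble_view")
}

#' Multiview ensemble clustering pipeline
#'
#' Runs the univariate pipeline per view (with its distance matrix rescaled
#' by the view's factor), converts the base dendrograms to cophenetic
#' descriptors, fits the least-squares consensus ultrametric, and cuts the
#' consensus dendrogram at `k`. Also emits the cross-tabulations used to
#' read the result: each view's univariate cut against the consensus cut,
#' and (when there are exactly two views) the view-vs-view cross-tab with
#' its chi-square statistic.
#'
#' @param views List of [ensemble_view()] objects sharing the same subjects.
#' @param k Number of consensus groups (default 4).
#' @param descriptor Descriptor passed to [build_problem()].
#' @param weights View weights for the consensus.
#' @param config A [sumt_config()].
#' @return List of class `ensemble_fit`: `labels` (consensus cut),
#'   `dendrogram`, `consensus` (the `consensus_fit`), `views` (list of
#'   `univariate_fit`), `cross_tabs` (view-vs-consensus tables),
#'   `view_cross_tab` and `view_chi_square` (two-view case only).
#' @export
run_ensemble <- function(views, k = 4, descriptor = "cophenetic",
                         weights = rep(1, length(views)),
                         config = sumt_config()) {
  stopifnot(length(views) >= 1,
            all(vapply(views, inherits, logical(1), "ensemble_view")))
  fits <- lapply(views, function(v) {
    fit <- run_univariate(v$profiles, metric = v$metric, k = v$k,
                          min_visits = v$min_visits, censor = v$censor,
                          log10_transform = v$log10_transform)
    if (v$rescale_factor != 1) {
      d <- rescale(fit$distance, v$rescale_factor)
      fit$distance <- d
      fit$dendrogram <- linkage(d, "complete")
    }
    fit
  })
  ids <- lapply(fits, function(f) names(f$labels))
  for (i in seq_along(ids)[-1]) {
    if (!identical(sort(ids[[i]]), sort(ids[[1]])))  {
      stop("views do not share the same subjects")
    }
  }
  problem <- build_problem(lapply(fits, `[[`, "dendrogram"),
                           descriptor = descriptor, weights = weights)
  cons <- consensus_ultrametric(problem, config)
  labels <- cut_dendrogram(cons$dendrogram, k)
  cross_tabs <- lapply(fits, function(f) {
    cross_tabulate(f$labels[names(labels)], labels)
  })
  view_ct <- NULL; view_chi <- NULL
  if (length(fits) == 2L) {
    ord <- names(labels)
    view_ct <- cross_tabulate(fits[[1]]$labels[ord], fits[[2]]$labels[ord])
    view_chi <- tryCatch(chi_square(view_ct), error = function(e) NULL)
  }
  structure(list(labels = labels, dendrogram = cons$dendrogram,
                 consensus = cons, views = fits, cross_tabs = cross_tabs,
                 view_cross_tab = view_ct, view_chi_square = view_chi),
            class = "ensemble_fit")
}
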