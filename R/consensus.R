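#' Assemble a consensus problem from base dendrograms
#'
#' Each input hierarchy (one per biomarker view) is rendered ultrametric by
#' converting it to a descriptor matrix — by default the cophenetic distance;
#' cluster membership divergence is available as an alternative. All
#' dendrograms must share an identical leaf set; matrices are aligned to the
#' first dendrogram's label order.
#'
#' @param dendrograms List of `hclust` objects over the same subjects.
#' @param descriptor `"cophenetic"` or `"membership_divergence"`.
#' @param weights Positive view weights (default equal).
#' @return A list of class `consensus_problem` with elements `descriptors`
#'   (list of `ultrametric_matrix`), `weights`, `labels`.
#' @export
build_problem <- function(dendrograms,
                          descriptor = c("cophenetic", "membership_divergence"),
                          weights = rep(1, length(dendrograms))) {
  descriptor <- match.arg(descriptor)
  stopifnot(length(dendrograms) >= 1, length(weights) == length(dendrograms),
            all(weights > 0))
  labs <- lapply(dendrograms, function(h) {
    if (is.null(h$labels)) as.character(seq_along(h$order)) else h$labels
  })
  ref <- labs[[1]]
  for (i in seq_along(labs)) {
    if (!setequal(labs[[i]], ref)) {
      diff <- union(setdiff(ref, labs[[i]]), setdiff(labs[[i]], ref))
      stop("dendrograms have mismatched leaf sets; symmetric difference: ",
           paste(diff, collapse = ", "))
    }
  }
  fn <- switch(descriptor, cophenetic = cophenetic_matrix,
               membership_divergence = membership_divergence_matrix)
  descriptors <- lapply(dendrograms, function(h) {
    m <- fn(h)
    ultrametric_matrix(unclass(m)[ref, ref], ref)
  })
  structure(list(descriptors = descriptors, weights = weights, labels = ref),
            class = "consensus_problem")
}

#' SUMT configuration for the consensus fit
#'
#' The constrained least-squares problem (nearest ultrametric to the
#' descriptor collection) is solved by sequential unconstrained
#' minimization: minimize `L(U) + r * Phi(U)` where `Phi` penalizes
#' ultrametric violations, with `r` escalating geometrically across outer
#' iterations.
#'
#' @param initial_penalty Starting penalty weight `r` (> 0).
#' @param penalty_growth Multiplier applied to `r` each outer iteration
#'   (> 1).
#' @param outer_iters Number of outer (penalty-escalation) iterations.
#' @param inner_reltol Relative convergence tolerance of the inner
#'   limited-memory quasi-Newton (L-BFGS) minimization.
#' @param inner_maxit Iteration cap for each inner minimization.
#' @param ultrametric_tol Acceptable worst-violation of the converged matrix
#'   before finalization, as a fraction of its largest entry.
#' @param n_restarts Number of additional perturbed restarts (0 = none).
#' @param restart_sd Relative size of the random perturbation used by
#'   restarts.
#' @param seed Integer seed governing perturbed restarts.
#' @return A list of class `sumt_config`.
#' @export
sumt_config <- function(initial_penalty = 1, penalty_growth = 10,
                        outer_iters = 10, inner_reltol = 1e-12,
                        inner_maxit = 400, ultrametric_tol = 1e-3,
                        n_restarts = 0, restart_sd = 0.05, seed = 1) {
  stopifnot(initial_penalty > 0, penalty_growth > 1, outer_iters >= 1)
  structure(list(initial_penalty = initial_penalty,
                 penalty_growth = penalty_growth,
                 outer_iters = as.integer(outer_iters),
                 inner_reltol = inner_reltol,
                 inner_maxit = as.integer(inner_maxit),
                 ultrametric_tol = ultrametric_tol,
                 n_restarts = as.integer(n_restarts),
                 restart_sd = restart_sd,
                 seed = as.integer(seed)),
            class = "sumt_config")
}

# weighted least-squares objective over upper-triangle entries
consensus_objective <- function(U, descriptors, weights) {
  ut <- upper.tri(U)
  sum(vapply(seq_along(descriptors), function(b) {
    weights[b] * sum((U[ut] - unclass(descriptors[[b]])[ut])^2)
  }, numeric(1)))
}

#' Least-squares ultrametric consensus of several dendrogram descriptors
#'
#' Minimizes `L(U) = sum_b w_b sum_{i<j} (u_ij - d^b_ij)^2` over ultrametric
#' matrices `U` by SUMT: the ultrametric constraint is replaced by the
#' penalty `Phi(U) = sum over triples with u_ik > max(u_ij, u_jk) of
#' (u_ik - max(u_ij, u_jk))^2`, and `L + r * Phi` is minimized by
#' conjugate-gradient descent on the upper-triangle entries for an
#' escalating sequence of `r`. `U` is initialized at the weighted mean of
#' the descriptors — so whenever that mean is itself ultrametric (e.g. a
#' single view, or identical views) the optimum is returned immediately.
#' The converged matrix is snapped to an exact ultrametric by single-linkage
#' (subdominant ultrametric) closure, which is the identity on matrices
#' already ultrametric, and the consensus dendrogram is rebuilt from it.
#'
#' Per-view descriptor scale statistics are recorded and a warning is issued
#' when view maxima differ by more than 10x: scale harmonization (e.g.
#' [rescale()] of a view's distances before clustering) is the caller's
#' responsibility and is never performed silently.
#'
#' @param problem A [build_problem()] result.
#' @param config A [sumt_config()].
#' @return A list of class `consensus_fit`: `ultrametric`
#'   (`ultrametric_matrix`), `dendrogram` (`hclust`), `objective` (`L` at
#'   the finalized consensus), `trace` (per-outer-iteration data frame with
#'   `r`, `L`, `phi`), and `scale_stats`.
#' @export
consensus_ultrametric <- function(problem, config = sumt_config()) {
  stopifnot(inherits(problem, "consensus_problem"))
  if (!inherits(config, "sumt_config")) stop("config must be a sumt_config")
  ds <- lapply(problem$descriptors, unclass)
  w <- problem$weights
  labels <- problem$labels
  n <- length(labels)

  scale_stats <- data.frame(
    view = seq_along(ds),
    max = vapply(ds, max, numeric(1)),
    mean = vapply(ds, function(m) mean(m[upper.tri(m)]), numeric(1)))
  if (max(scale_stats$max) > 10 * min(scale_stats$max)) {
    warning("descriptor scales differ by more than 10x across views ",
            "(max entries: ", paste(signif(scale_stats$max, 3), collapse = ", "),
            "); consider rescaling distances before clustering")
  }

  mean_mat <- Reduce(`+`, Map(`*`, ds, as.list(w / sum(w))))
  ut <- upper.tri(mean_mat)
  scale <- max(mean_mat)

  # least-squares part in expanded form: L = wtot*sum(u^2) - 2*sum(u*sumwd) + cst
  wtot <- sum(w)
  sumwd <- Reduce(`+`, Map(`*`, ds, as.list(w)))[ut]
  cst <- sum(vapply(seq_along(ds), function(b) {
    w[b] * sum(unclass(ds[[b]])[ut]^2)
  }, numeric(1)))

  fit_from <- function(start_vec) {
    x <- start_vec
    trace <- data.frame(r = numeric(0), L = numeric(0), phi = numeric(0))
    r <- config$initial_penalty
    U <- NULL
    for (it in seq_len(config$outer_iters)) {
      res <- stats::optim(
        x,
        fn = function(v) cpp_sumt_obj(v, sumwd, wtot, cst, r, n),
        gr = function(v) cpp_sumt_grad(v, sumwd, wtot, r, n),
        method = "L-BFGS-B",
        control = list(maxit = config$inner_maxit,
                       factr = max(10, config$inner_reltol /
                                         .Machine$double.eps)))
      x <- res$par
      U <- matrix(0, n, n); U[ut] <- x; U <- U + t(U)
      pen <- cpp_ultra_penalty(U)
      trace <- rbind(trace, data.frame(r = r,
                                       L = consensus_objective(U, ds, w),
                                       phi = pen$phi))
      if (pen$phi <= .Machine$double.eps * max(1, max(U)^2)) break
      r <- r * config$penalty_growth
    }
    list(x = x, U = U, trace = trace)
  }

  best <- fit_from(mean_mat[ut])
  if (config$n_restarts > 0) {
    set.seed(config$seed)
    final_obj <- function(f) {
      Uf <- finalize_ultrametric(f$U)
      consensus_objective(Uf, ds, w)
    }
    best_val <- final_obj(best)
    for (rs in seq_len(config$n_restarts)) {
      start <- mean_mat[ut] *
        (1 + stats::rnorm(sum(ut), 0, config$restart_sd))
      cand <- fit_from(pmax(start, 0))
      if (final_obj(cand) < best_val) {
        best <- cand
        best_val <- final_obj(cand)
      }
    }
  }

  worst <- cpp_worst_violation(best$U)$violation
  if (worst > config$ultrametric_tol * max(scale, 1e-12)) {
    cond <- simpleError(paste0(
      "SUMT did not reach an ultrametric within tolerance after ",
      config$outer_iters, " outer iterations (worst violation ",
      format(worst), ")"))
    cond$best_iterate <- best$U
    stop(cond)
  }

  U_final <- finalize_ultrametric(best$U)
  u <- ultrametric_matrix(U_final, labels)
  h <- dendrogram_from_ultrametric(u)
  structure(list(ultrametric = u, dendrogram = h,
                 objective = consensus_objective(U_final, ds, w),
                 trace = best$trace, scale_stats = scale_stats,
                 labels = labels),
            class = "consensus_fit")
}

# subdominant-ultrametric (single-linkage) closure; identity on matrices
# that are already ultrametric
finalize_ultrametric <- function(U) {
  h <- stats::hclust(stats::as.dist(U), method = "single")
  m <- as.matrix(stats::cophenetic(h))
  # cophenetic() returns rows in original order already
  unname(m)
}

#' @export
print.consensus_fit <- function(x, ...) {
  cat("<consensus_fit>", length(x$labels), "subjects; objective L =",
      format(x$objective, digits = 6), "\n")
  cat("  outer iterations:", nrow(x$trace),
      "; final phi =", format(x$trace$phi[nrow(x$trace)], digits = 3), "\n")
  invisible(x)
}

#' Write a consensus run report as JSON
#'
#' Records the objective, the SUMT penalty/violation trace, the per-view
#' scale statistics and the configuration — enough to audit a consensus run.
#'
#' @param fit A `consensus_fit`.
#' @param config The [sumt_config()] used.
#' @param path File path.
#' @return `path`, invisibly.
#' @export
write_consensus_report <- function(fit, config, path) {
  stopifnot(inherits(fit, "consensus_fit"))
  jsonlite::write_json(
    list(objective = fit$objective, trace = fit$trace,
         scale_stats = fit$scale_stats,
         config = unclass(config), n_subjects = length(fit$labels)),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
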