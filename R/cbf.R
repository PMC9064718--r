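#' Configuration for the cylinder-bell-funnel benchmark generator
#'
#' The CBF benchmark is a standard simulated time-series testbed with three
#' shape classes observed on an equispaced grid. The canonical functional
#' forms are used: with plateau start `a` drawn uniformly from the integers
#' 16..32, width `b - a` uniform on 32..96, amplitude perturbation `eta` and
#' pointwise noise `eps(t)` standard normal (both scaled by `noise_sd`),
#'
#' * cylinder: `(6 + eta) * 1[a,b](t) + eps(t)`
#' * bell:     `(6 + eta) * 1[a,b](t) * (t - a)/(b - a) + eps(t)`
#' * funnel:   `(6 + eta) * 1[a,b](t) * (b - t)/(b - a) + eps(t)`
#'
#' @param n_per_class Profiles per shape class (>= 1). The classical
#'   training-set size is 10 per class (n = 30).
#' @param length Number of equispaced points per profile (>= 2); 128 for the
#'   full variant, 32 after every-fourth-point sparsification.
#' @param noise_sd Standard deviation scale applied to both `eta` and
#'   `eps(t)`; 1 is the canonical benchmark noise, 0 gives the noise-free
#'   shapes.
#' @param seed Integer RNG seed; generation is bit-reproducible given the
#'   seed.
#' @return A list of class `cbf_config`.
#' @export
cbf_config <- function(n_per_class = 10, length = 128, noise_sd = 1, seed = 1) {
  stopifnot(n_per_class >= 1, length >= 2, noise_sd >= 0)
  structure(list(n_per_class = as.integer(n_per_class),
                 length = as.integer(length),
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "cbf_config")
}

#' Generate a cylinder-bell-funnel benchmark set
#'
#' @param config A [cbf_config()].
#' @return A [labeled_profile_set()] with `3 * n_per_class` profiles at times
#'   `1..length`, labeled `"cylinder"`, `"bell"`, `"funnel"`.
#' @export
generate_cbf <- function(config = cbf_config()) {
  stopifnot(inherits(config, "cbf_config"))
  set.seed(config$seed)
  n <- config$n_per_class
  T <- config$length
  t <- seq_len(T)
  shapes <- c("cylinder", "bell", "funnel")
  trajs <- list()
  labels <- character(0)
  idx <- 0L
  for (shape in shapes) {
    for (r in seq_len(n)) {
      idx <- idx + 1L
      a <- sample(16:32, 1)
      w <- sample(32:96, 1)
      b <- a + w
      eta <- stats::rnorm(1) * config$noise_sd
      eps <- stats::rnorm(T) * config$noise_sd
      ind <- as.numeric(t >= a & t <= b)
      core <- switch(shape,
        cylinder = (6 + eta) * ind,
        bell     = (6 + eta) * ind * (t - a) / (b - a),
        funnel   = (6 + eta) * ind * (b - t) / (b - a))
      trajs[[idx]] <- trajectory(sprintf("cbf%03d", idx), t, core + eps,
                                 marker = "cbf")
      labels <- c(labels, shape)
    }
  }
  labeled_profile_set(profile_set(trajs), labels)
}

#' Keep every step-th point of each profile
#'
#' Thins equispaced profiles to positions `1, 1+step, 1+2*step, ...` (the
#' sparse benchmark variant uses `step = 4`, turning 128 points into 32).
#' Labels are unchanged.
#'
#' @param set A [labeled_profile_set()] or [profile_set()].
#' @param step Positive integer, at most the shortest profile length.
#' @return Object of the same class with thinned profiles.
#' @export
sparsify <- function(set, step) {
  stopifnot(step >= 1)
  thin_ps <- function(ps) {
    lens <- vapply(ps$trajectories, function(t) length(t$times), integer(1))
    if (any(step > lens)) stop("step exceeds a profile length")
    profile_set(lapply(ps$trajectories, function(tr) {
      keep <- seq(1L, length(tr$times), by = step)
      trajectory(tr$subject_id, tr$times[keep], tr$values[keep],
                 marker = tr$marker, censor_flags = tr$censor_flags[keep])
    }))
  }
  if (inherits(set, "labeled_profile_set")) {
    labeled_profile_set(thin_ps(set$profiles), unname(set$labels))
  } else {
    thin_ps(set)
  }
}

#' Configuration for missing-completely-at-random thinning
#'
#' @param fraction Fraction of value-matrix cells to remove, in `[0, 1)`.
#' @param seed Integer RNG seed.
#' @param min_points_per_profile Minimum surviving points per profile
#'   (default 1); the whole removal set is redrawn if violated, so empty
#'   profiles are the only excluded outcome by default.
#' @return A list of class `mcar_config`.
#' @export
mcar_config <- function(fraction, seed = 1, min_points_per_profile = 1) {
  stopifnot(fraction >= 0, fraction < 1, min_points_per_profile >= 1)
  structure(list(fraction = fraction, seed = as.integer(seed),
                 min_points_per_profile = as.integer(min_points_per_profile)),
            class = "mcar_config")
}

#' Remove cells completely at random from a matrix-shaped profile set
#'
#' All profiles must have the same length (a rectangular value matrix).
#' Exactly `round(fraction * N * T)` cells (ties rounded up) are removed
#' uniformly without replacement from the whole matrix, so per-profile
#' missingness varies: some profiles lose few or no points, others
#' considerably more. Surviving points keep their original time order.
#'
#' @param set A [labeled_profile_set()] or [profile_set()].
#' @param config An [mcar_config()].
#' @return Object of the same class with cells removed.
#' @export
apply_mcar <- function(set, config) {
  stopifnot(inherits(config, "mcar_config"))
  ps <- if (inherits(set, "labeled_profile_set")) set$profiles else set
  lens <- vapply(ps$trajectories, function(t) length(t$times), integer(1))
  if (length(unique(lens)) > 1L) {
    stop("apply_mcar requires all profiles to have the same length")
  }
  n <- length(ps); T <- lens[1]
  n_remove <- floor(config$fraction * n * T + 0.5)  # ties round up
  keep_min <- config$min_points_per_profile
  if (T - ceiling(n_remove / n) < 0 || n * T - n_remove < n * keep_min) {
    stop("fraction too high: cannot keep ", keep_min,
         " point(s) in every profile")
  }
  set.seed(config$seed)
  if (n_remove > 0) {
    for (attempt in seq_len(1000)) {
      cells <- sample.int(n * T, n_remove)
      # cell index -> profile: column-major over an n x T matrix
      per_prof <- tabulate(((cells - 1L) %% n) + 1L, nbins = n)
      if (all(T - per_prof >= keep_min)) break
      if (attempt == 1000) {
        stop("could not satisfy min_points_per_profile after 1000 redraws")
      }
    }
    removed <- matrix(FALSE, n, T)
    removed[cells] <- TRUE
  } else {
    removed <- matrix(FALSE, n, T)
  }
  trajs <- lapply(seq_len(n), function(i) {
    tr <- ps$trajectories[[i]]
    keep <- !removed[i, ]
    trajectory(tr$subject_id, tr$times[keep], tr$values[keep],
               marker = tr$marker, censor_flags = tr$censor_flags[keep])
  })
  out <- profile_set(trajs)
  if (inherits(set, "labeled_profile_set")) {
    labeled_profile_set(out, unname(set$labels))
  } else {
    out
  }
}
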