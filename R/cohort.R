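#' Configuration for the synthetic bivariate CD4 / viral-load cohort
#'
#' Emulates an HIV cohort with scheduled biomarker assessment every 6 months
#' over a 24-month window: visits at months `{0, 6, 12, 18, 24}` with small
#' integer deviations, geometric dropout, and two jointly observed markers —
#' CD4 count and viral load (VL, copies/mL; log10-linear trends, clamped at
#' assay quantitation limits). Each subject belongs to a latent progression
#' group; within a group, a marker follows a linear trend
#' `intercept + slope * month + subject effect + visit noise`.
#'
#' The four default group archetypes mirror the progression subtypes an
#' ensemble analysis of such cohorts distinguishes:
#'
#' 1. `low_cd4_high_vl` — low, declining CD4 with high viremia;
#' 2. `mid_cd4_rising_vl` — intermediate CD4, low but rising VL;
#' 3. `high_cd4_low_vl` — high CD4, VL held near/below the lower
#'    quantitation limit;
#' 4. `high_cd4_high_vl` — a small, recently infected group: CD4 still high
#'    but viremia high.
#'
#' Groups 3 and 4 are deliberately near-indistinguishable in CD4 and
#' separated only by VL, so recovering their split requires combining both
#' markers. Default sizes (41, 21, 19, 6) keep the two small high-CD4
#' subgroups at realistic cohort proportions.
#'
#' @param group_sizes Integer vector of latent group sizes (>= 1 each);
#'   its length selects the first `length(group_sizes)` archetypes of
#'   `groups`.
#' @param groups Data frame of group-level trend parameters with columns
#'   `name`, `cd4_intercept` (cells/uL at month 0), `cd4_slope` (cells/uL
#'   per month), `vl_intercept` (log10 copies at month 0), `vl_slope`
#'   (log10 copies per month).
#' @param scheduled_months Scheduled visit months.
#' @param visit_jitter_months Maximum absolute integer deviation from each
#'   scheduled month; jittered months are clipped to `[0, 25]`.
#' @param dropout_prob_per_visit Probability of dropping out after each
#'   attended visit (geometric truncation of the schedule). The default 0.1
#'   yields a visit distribution (mean about 4.1, median 5, retention of
#'   about 73% at a 4-visit filter) matching a typical 24-month cohort.
#' @param cd4_subject_sd,cd4_noise_sd Between-subject and within-subject
#'   (visit-level) CD4 standard deviations, cells/uL.
#' @param vl_subject_sd,vl_noise_sd Same for log10 VL.
#' @param vl_limits Lower and upper VL quantitation limits (copies);
#'   generated VL is clamped and flagged via [censor_limits()].
#' @param baseline_cd4_min Enrollment criterion: baseline CD4 must be at
#'   least this (cells/uL); the baseline draw is resampled until satisfied.
#' @param seed Integer RNG seed.
#' @return A list of class `cohort_config`.
#' @export
cohort_config <- function(group_sizes = c(41, 21, 19, 6),
                          groups = default_cohort_groups(),
                          scheduled_months = c(0, 6, 12, 18, 24),
                          visit_jitter_months = 1,
                          dropout_prob_per_visit = 0.1,
                          cd4_subject_sd = 60, cd4_noise_sd = 50,
                          vl_subject_sd = 0.3, vl_noise_sd = 0.3,
                          vl_limits = c(400, 750000),
                          baseline_cd4_min = 350,
                          seed = 1) {
  stopifnot(all(group_sizes >= 1),
            length(group_sizes) <= nrow(groups),
            dropout_prob_per_visit >= 0, dropout_prob_per_visit <= 1,
            visit_jitter_months >= 0,
            cd4_subject_sd >= 0, cd4_noise_sd >= 0,
            vl_subject_sd >= 0, vl_noise_sd >= 0,
            length(vl_limits) == 2, vl_limits[1] < vl_limits[2])
  structure(list(group_sizes = as.integer(group_sizes),
                 groups = groups[seq_along(group_sizes), , drop = FALSE],
                 scheduled_months = sort(as.numeric(scheduled_months)),
                 visit_jitter_months = as.integer(visit_jitter_months),
                 dropout_prob_per_visit = dropout_prob_per_visit,
                 cd4_subject_sd = cd4_subject_sd, cd4_noise_sd = cd4_noise_sd,
                 vl_subject_sd = vl_subject_sd, vl_noise_sd = vl_noise_sd,
                 vl_limits = as.numeric(vl_limits),
                 baseline_cd4_min = baseline_cd4_min,
                 seed = as.integer(seed)),
            class = "cohort_config")
}

#' @rdname cohort_config
#' @export
default_cohort_groups <- function() {
  data.frame(
    name = c("low_cd4_high_vl", "mid_cd4_rising_vl",
             "high_cd4_low_vl", "high_cd4_high_vl"),
    cd4_intercept = c(420, 650, 900, 950),
    cd4_slope     = c(-5, -2, -1, -3),
    vl_intercept  = c(4.8, 3.0, 2.5, 5.5),
    vl_slope      = c(0.01, 0.03, 0.0, -0.02),
    stringsAsFactors = FALSE
  )
}

#' Expected fraction of subjects retained by a visit-count filter
#'
#' Under the geometric dropout model, a subject attends at least `m` of the
#' scheduled visits with probability `(1 - p)^(m - 1)` (for `m` at most the
#' number of scheduled visits), independent of jitter.
#'
#' @param config A [cohort_config()].
#' @param min_visits The filter threshold.
#' @return Probability in `[0, 1]`.
#' @export
expected_retention <- function(config, min_visits) {
  stopifnot(inherits(config, "cohort_config"))
  if (min_visits <= 1) return(1)
  if (min_visits > length(config$scheduled_months)) return(0)
  (1 - config$dropout_prob_per_visit)^(min_visits - 1)
}

#' Read a generator configuration from YAML
#'
#' YAML keys mirror the arguments of [cbf_config()] / [cohort_config()];
#' omitted keys take the defaults. For the cohort, `groups` may be given as
#' a list of records with the columns of [default_cohort_groups()].
#'
#' @param path Path to a YAML file.
#' @return A `cbf_config` or `cohort_config`.
#' @export
cbf_config_from_yaml <- function(path) {
  do.call(cbf_config, yaml::read_yaml(path))
}

#' @rdname cbf_config_from_yaml
#' @export
cohort_config_from_yaml <- function(path) {
  spec <- yaml::read_yaml(path)
  if (!is.null(spec$groups)) {
    spec$groups <- do.call(rbind, lapply(spec$groups, as.data.frame))
  }
  if (!is.null(spec$vl_limits)) spec$vl_limits <- unlist(spec$vl_limits)
  do.call(cohort_config, spec)
}

#' Generate a synthetic bivariate CD4 / viral-load cohort
#'
#' @param config A [cohort_config()].
#' @return A list with elements `cd4` and `vl` (each a
#'   [labeled_profile_set()] over the same subjects, labeled by latent
#'   group name) and `labels` (the named true-group vector). VL values are
#'   on the raw copies scale, already clamped at `vl_limits`.
#' @export
generate_cohort <- function(config = cohort_config()) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  sched <- config$scheduled_months
  K <- length(sched)
  j <- config$visit_jitter_months
  p <- config$dropout_prob_per_visit
  cd4_trajs <- list(); vl_trajs <- list(); labels <- character(0)
  idx <- 0L
  for (g in seq_along(config$group_sizes)) {
    pars <- config$groups[g, ]
    for (s in seq_len(config$group_sizes[g])) {
      idx <- idx + 1L
      id <- sprintf("subj%04d", idx)
      n_visits <- if (p > 0) min(K, 1L + stats::rgeom(1, p)) else K
      months <- sched[seq_len(n_visits)]
      if (j > 0) {
        months <- months + sample(seq(-j, j), n_visits, replace = TRUE)
        months <- pmin(pmax(months, 0), 25)
        months <- sort(unique(months))
      }
      u_cd4 <- stats::rnorm(1, 0, config$cd4_subject_sd)
      u_vl <- stats::rnorm(1, 0, config$vl_subject_sd)
      cd4 <- pars$cd4_intercept + pars$cd4_slope * months + u_cd4 +
        stats::rnorm(length(months), 0, config$cd4_noise_sd)
      # enrollment criterion: resample the baseline measurement if needed
      tries <- 0L
      while (cd4[1] < config$baseline_cd4_min) {
        tries <- tries + 1L
        if (tries > 1000L) {
          stop("cannot satisfy baseline_cd4_min for group '", pars$name,
               "'; its CD4 intercept is too low")
        }
        cd4[1] <- pars$cd4_intercept + pars$cd4_slope * months[1] + u_cd4 +
          stats::rnorm(1, 0, config$cd4_noise_sd)
        if (config$cd4_noise_sd == 0 && tries > 1L) {
          stop("baseline_cd4_min unreachable at zero noise for group '",
               pars$name, "'")
        }
      }
      logvl <- pars$vl_intercept + pars$vl_slope * months + u_vl +
        stats::rnorm(length(months), 0, config$vl_noise_sd)
      cd4_trajs[[idx]] <- trajectory(id, months, cd4, marker = "cd4")
      vl_trajs[[idx]] <- trajectory(id, months, 10^logvl, marker = "vl")
      labels <- c(labels, pars$name)
    }
  }
  vl_set <- censor_limits(profile_set(vl_trajs),
                          config$vl_limits[1], config$vl_limits[2])
  cd4_lps <- labeled_profile_set(profile_set(cd4_trajs), labels)
  list(cd4 = cd4_lps,
       vl = labeled_profile_set(vl_set, labels),
       labels = cd4_lps$labels)
}
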