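test_that("CBF generation has the right size, labels and reproducibility", {
  set <- generate_cbf(cbf_config(n_per_class = 10, length = 128, seed = 5))
  expect_equal(length(set$profiles), 30L)
  expect_equal(unname(table(set$labels)[c("cylinder", "bell", "funnel")]),
               rep(10L, 3), ignore_attr = TRUE)
  expect_true(all(vapply(set$profiles$trajectories,
                         function(t) identical(t$times, as.numeric(1:128)),
                         logical(1))))
  again <- generate_cbf(cbf_config(n_per_class = 10, length = 128, seed = 5))
  expect_identical(profile_set_to_df(again$profiles),
                   profile_set_to_df(set$profiles))
  expect_false(identical(
    profile_set_to_df(generate_cbf(cbf_config(seed = 6))$profiles),
    profile_set_to_df(set$profiles)))
})

test_that("noise-free CBF profiles match the closed-form shapes", {
  set <- generate_cbf(cbf_config(n_per_class = 4, length = 128, noise_sd = 0,
                                 seed = 9))
  for (i in seq_along(set$labels)) {
    tr <- set$profiles$trajectories[[i]]
    v <- tr$values
    t <- tr$times
    on <- which(v != 0)
    a <- min(on); b <- max(on)
    expected <- switch(set$labels[i],
      cylinder = 6 * as.numeric(t >= a & t <= b),
      bell     = 6 * as.numeric(t >= a & t <= b) * (t - a) / (b - a),
      funnel   = 6 * as.numeric(t >= a & t <= b) * (b - t) / (b - a))
    if (set$labels[i] == "bell") {
      # support excludes t = a where the ramp is exactly 0; recover a from
      # the linear fit instead
      expect_equal(diff(v[on]), rep(v[on][2] - v[on][1], length(on) - 1),
                   tolerance = 1e-9)
      expect_equal(max(v), 6, tolerance = 1e-9)
      expect_true(all(v[t < a | t > b] == 0))
    } else if (set$labels[i] == "funnel") {
      expect_equal(max(v), 6, tolerance = 1e-9)
      expect_true(all(diff(v[on]) < 0 | abs(diff(v[on])) < 1e-9))
    } else {
      expect_true(all(v[on] == 6))
      expect_identical(v, expected)
    }
    expect_true(a >= 16 && a <= 33)
  }
})

test_that("sparsify keeps positions 1, 1+step, ... and labels", {
  set <- generate_cbf(cbf_config(n_per_class = 2, length = 128, seed = 2))
  sp <- sparsify(set, 4)
  expect_equal(length(sp$profiles$trajectories[[1]]$times), 32L)
  expect_equal(sp$profiles$trajectories[[1]]$times[1:3], c(1, 5, 9))
  expect_identical(unname(sp$labels), unname(set$labels))
  expect_identical(profile_set_to_df(sparsify(set, 1)$profiles),
                   profile_set_to_df(set$profiles))

  ten <- toy_profiles(list(a = (1:10)^2))
  th <- sparsify(ten, 3)
  expect_equal(th$trajectories[["a"]]$times, c(1, 4, 7, 10))
  expect_error(sparsify(toy_profiles(list(a = 1:2)), 3), "step exceeds")
})

test_that("MCAR removes an exact cell count uniformly and preserves time order", {
  set <- sparsify(generate_cbf(cbf_config(seed = 3)), 4)  # 30 x 32
  out <- apply_mcar(set, mcar_config(0.25, seed = 11))
  n_pts <- sum(vapply(out$profiles$trajectories,
                      function(t) length(t$times), integer(1)))
  expect_equal(960 - n_pts, 240L)  # 0.25 * 960
  expect_true(all(vapply(out$profiles$trajectories,
                         function(t) all(diff(t$times) > 0), logical(1))))
  ident <- apply_mcar(set, mcar_config(0, seed = 1))
  expect_identical(profile_set_to_df(ident$profiles),
                   profile_set_to_df(set$profiles))
  expect_error(apply_mcar(set, mcar_config(0.99, seed = 1,
                                           min_points_per_profile = 5)),
               "fraction too high")
})

test_that("per-profile MCAR removal counts are consistent with hypergeometric margins", {
  set <- sparsify(generate_cbf(cbf_config(seed = 4)), 4)  # 30 x 32
  n <- 30; T <- 32; n_remove <- 240
  reps <- 1000
  counts <- matrix(0L, reps, n)
  for (r in seq_len(reps)) {
    out <- apply_mcar(set, mcar_config(0.25, seed = 20000 + r))
    counts[r, ] <- T - vapply(out$profiles$trajectories,
                              function(t) length(t$times), integer(1))
  }
  # each draw removes exactly 240 cells
  expect_true(all(rowSums(counts) == n_remove))
  # goodness of fit: total removals per profile should be uniform across
  # profiles (hypergeometric margins are exchangeable)
  tot <- colSums(counts)
  gof <- suppressWarnings(chisq.test(tot, p = rep(1 / n, n)))
  expect_gt(gof$p.value, 0.01)
  # per-profile counts genuinely vary (some profiles nearly intact, others not)
  expect_gt(max(counts[1, ]) - min(counts[1, ]), 0)
})

test_that("cohort generator produces the configured structure", {
  cfg <- cohort_config(group_sizes = c(10, 10, 10, 10), seed = 8)
  coh <- generate_cohort(cfg)
  expect_equal(length(coh$cd4$profiles), 40L)
  expect_equal(length(coh$vl$profiles), 40L)
  expect_equal(length(unique(coh$labels)), 4L)
  expect_identical(subject_ids(coh$cd4$profiles), subject_ids(coh$vl$profiles))
  # VL clamped within limits
  vl_vals <- unlist(lapply(coh$vl$profiles$trajectories, function(t) t$values))
  expect_true(all(vl_vals >= 400 & vl_vals <= 750000))
  # enrollment criterion on baseline CD4
  first_cd4 <- vapply(coh$cd4$profiles$trajectories,
                      function(t) t$values[1], numeric(1))
  expect_true(all(first_cd4 >= cfg$baseline_cd4_min))
})

test_that("no dropout and no jitter yields the exact visit schedule", {
  cfg <- cohort_config(group_sizes = c(5, 5), visit_jitter_months = 0,
                       dropout_prob_per_visit = 0, seed = 3)
  coh <- generate_cohort(cfg)
  for (tr in coh$cd4$profiles$trajectories) {
    expect_equal(tr$times, c(0, 6, 12, 18, 24))
  }
})

test_that("visit-filter retention matches the dropout model within binomial noise", {
  # cohort of 875 with the default visit distribution, filtered at 4 visits
  cfg <- cohort_config(group_sizes = c(557, 283, 26, 9), seed = 21)  # n = 875
  coh <- generate_cohort(cfg)
  kept <- length(filter_min_visits(coh$cd4$profiles, 4))
  p <- expected_retention(cfg, 4)
  n <- sum(cfg$group_sizes)
  se <- sqrt(n * p * (1 - p))
  expect_lt(abs(kept - n * p), 4 * se)
})

test_that("generator configurations round-trip through YAML", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_class: 4", "length: 32", "noise_sd: 0.5", "seed: 9"), f)
  cfg <- cbf_config_from_yaml(f)
  expect_identical(cfg, cbf_config(n_per_class = 4, length = 32,
                                   noise_sd = 0.5, seed = 9))
  g <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("group_sizes: [5, 5]", "dropout_prob_per_visit: 0.0",
               "visit_jitter_months: 0", "seed: 2"), g)
  ccfg <- cohort_config_from_yaml(g)
  expect_equal(ccfg$group_sizes, c(5L, 5L))
  expect_equal(ccfg$dropout_prob_per_visit, 0)
  expect_equal(nrow(ccfg$groups), 2L)
  coh <- generate_cohort(ccfg)
  expect_equal(length(coh$labels), 10L)
})
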