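test_that("benchmark bookkeeping: single-rep and fraction-0 rows have zero sd", {
  cfg <- benchmark_config(cbf = cbf_config(n_per_class = 4, length = 32, seed = 2),
                          missing_fractions = c(0, 0.25), n_reps = 1,
                          metrics = "dtw", seed = 5)
  res <- run_cbf_benchmark(cfg)
  expect_true(all(res$sd == 0))
  expect_setequal(unique(res$index), c("adj_rand", "fowlkes_mallows", "purity"))
})

test_that("noise-free CBF classes are perfectly separable by DTW", {
  cfg <- benchmark_config(cbf = cbf_config(n_per_class = 5, length = 64,
                                           noise_sd = 0, seed = 3),
                          missing_fractions = 0, n_reps = 1,
                          metrics = "dtw", seed = 7)
  res <- run_cbf_benchmark(cfg)
  expect_equal(res$mean, rep(1, 3))
})

test_that("euclidean under missingness is rejected at configuration time", {
  expect_error(benchmark_config(missing_fractions = c(0, 0.25),
                                metrics = c("dtw", "euclidean")),
               "euclidean.*missing")
})

test_that("the benchmark is bit-reproducible under a fixed master seed", {
  cfg <- benchmark_config(cbf = cbf_config(n_per_class = 4, length = 32, seed = 9),
                          missing_fractions = 0.25, n_reps = 10,
                          metrics = c("dtw", "frechet"), seed = 13)
  r1 <- run_cbf_benchmark(cfg)
  r2 <- run_cbf_benchmark(cfg)
  expect_identical(r1, r2)
})

test_that("univariate pipeline wires preprocessing, clustering and reports together", {
  coh <- generate_cohort(cohort_config(group_sizes = c(8, 8, 8),
                                       cd4_subject_sd = 0, cd4_noise_sd = 0,
                                       vl_subject_sd = 0, vl_noise_sd = 0,
                                       visit_jitter_months = 0,
                                       dropout_prob_per_visit = 0, seed = 17))
  fit <- run_univariate(coh$cd4$profiles, metric = "dtw", k = 3)
  expect_equal(adjusted_rand(fit$labels, coh$labels), 1)
  expect_true(fit$report["silhouette"] > 0.5)
  expect_error(run_univariate(coh$cd4$profiles, k = 1), NA)
  expect_true(is.na(run_univariate(coh$cd4$profiles, k = 1)$report["silhouette"]))

  # VL preprocessing: censor then log10
  fitv <- run_univariate(coh$vl$profiles, metric = "dtw", k = 3,
                         censor = c(400, 750000), log10_transform = TRUE)
  expect_true(all(unlist(lapply(fitv$profiles$trajectories,
                                function(t) t$values)) <= log10(750000)))

  # duplicated subjects co-cluster at every k
  dup <- toy_profiles(list(a = c(1, 2, 3), b = c(1, 2, 3),
                           c = c(9, 9, 9), d = c(5, 6, 9)))
  for (k in 2:3) {
    lab <- run_univariate(dup, metric = "dtw", k = k)$labels
    expect_equal(lab[["a"]], lab[["b"]])
  }
})

test_that("min-visit filtering inside the pipeline drops short profiles", {
  set <- toy_profiles(list(a = 1:3, b = 1:5, c = 2:6, d = c(1, 2)))
  fit <- run_univariate(set, metric = "dtw", k = 2, min_visits = 4)
  expect_setequal(names(fit$labels), c("b", "c"))
})

test_that("a single-view ensemble reproduces the univariate result exactly", {
  coh <- generate_cohort(cohort_config(group_sizes = c(6, 6, 6), seed = 19))
  uni <- run_univariate(coh$cd4$profiles, metric = "dtw", k = 3)
  ens <- run_ensemble(list(ensemble_view(coh$cd4$profiles, metric = "dtw")),
                      k = 3)
  expect_equal(adjusted_rand(ens$labels[names(uni$labels)], uni$labels), 1)
  expect_equal(unclass(cophenetic_matrix(ens$dendrogram)),
               unclass(cophenetic_matrix(uni$dendrogram)), tolerance = 1e-6)
})

test_that("two identical views give back the univariate cut and a diagonal self cross-tab", {
  coh <- generate_cohort(cohort_config(group_sizes = c(6, 6), seed = 23))
  v <- ensemble_view(coh$cd4$profiles, metric = "dtw", k = 2)
  ens <- run_ensemble(list(v, v), k = 2)
  uni <- run_univariate(coh$cd4$profiles, metric = "dtw", k = 2)
  expect_equal(adjusted_rand(ens$labels[names(uni$labels)], uni$labels), 1)
  ct <- ens$view_cross_tab
  expect_equal(sum(diag(unclass(ct))), sum(unclass(ct)))
})

test_that("rescaling one view keeps its own labels but shifts the consensus weight", {
  # view A separates {s1,s2} from {s3,s4}; view B separates {s1,s3} from {s2,s4}
  # at 1/100 the scale. At factor 1 the consensus follows A; at 1000 it
  # follows B.
  A <- toy_profiles(list(s1 = c(0, 0), s2 = c(0.5, 0.5),
                         s3 = c(10, 10), s4 = c(10.5, 10.5)), marker = "A")
  B <- toy_profiles(list(s1 = c(0, 0), s2 = c(0.1, 0.1),
                         s3 = c(0.005, 0.005), s4 = c(0.105, 0.105)),
                    marker = "B")
  base_B <- run_univariate(B, metric = "dtw", k = 2)$labels
  for (f in c(1, 1000)) {
    ens <- suppressWarnings(
      run_ensemble(list(ensemble_view(A, metric = "dtw", k = 2),
                        ensemble_view(B, metric = "dtw", k = 2,
                                      rescale_factor = f)),
                   k = 2))
    v2 <- ens$views[[2]]
    expect_equal(adjusted_rand(cut_dendrogram(v2$dendrogram, 2), base_B), 1)
    ref <- if (f == 1) c(s1 = 1, s2 = 1, s3 = 2, s4 = 2)
           else c(s1 = 1, s2 = 2, s3 = 1, s4 = 2)
    expect_equal(adjusted_rand(ens$labels[names(ref)], ref), 1,
                 info = paste("factor", f))
  }
})

test_that("views over different subject sets are rejected", {
  a <- toy_profiles(list(s1 = 1:3, s2 = 2:4))
  b <- toy_profiles(list(s1 = 1:3, s9 = 2:4))
  expect_error(run_ensemble(list(ensemble_view(a, k = 2),
                                 ensemble_view(b, k = 2)), k = 2),
               "same subjects")
})

test_that("the CLI round-trips simulate, distance, cluster and evaluate", {
  tmp <- withr::local_tempdir()
  prof <- file.path(tmp, "cbf.csv"); labs <- file.path(tmp, "labs.csv")
  out <- file.path(tmp, "labels.csv"); met <- file.path(tmp, "metrics.csv")
  dmat <- file.path(tmp, "d.csv")
  expect_equal(suppressMessages(cli_main(c(
    "simulate-cbf", "--seed", "5", "--out", prof, "--labels", labs,
    "--n-per-class", "4", "--length", "32"))), 0L)
  expect_equal(suppressMessages(cli_main(c(
    "distance", "--in", prof, "--metric", "dtw", "--out", dmat))), 0L)
  expect_equal(nrow(read_distance_csv(dmat)), 12L)
  expect_equal(suppressMessages(cli_main(c(
    "cluster", "--in", prof, "--k", "3", "--out-labels", out))), 0L)
  expect_equal(suppressMessages(cli_main(c(
    "evaluate", "--labels", out, "--truth", labs, "--out", met))), 0L)
  m <- read.csv(met)
  expect_setequal(m$metric, c("adj_rand", "fowlkes_mallows", "purity"))
  expect_true(all(is.finite(m$value)))
})
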