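test_that("external indices handle the canonical and degenerate cases", {
  a <- c(1, 1, 2, 2)
  expect_equal(adjusted_rand(a, a), 1)
  expect_equal(fowlkes_mallows(a, a), 1)
  expect_equal(purity(a, a), 1)
  # any partition against all-singletons: S = 0 and E = 0
  expect_equal(adjusted_rand(a, 1:4), 0)
  # crossed pairs: oracle by direct enumeration of the 6 pairs
  b <- c(1, 2, 1, 2)
  o <- paircount_indices(a, b)
  expect_equal(adjusted_rand(a, b), o$ari)
  expect_equal(fowlkes_mallows(a, b), o$fm)
  # no pair co-clustered in both partitions
  expect_equal(fowlkes_mallows(c(1, 1, 2, 2), c(1, 2, 1, 2)), 0)
  expect_equal(purity(c(1, 1, 1, 2, 2), c("a", "a", "b", "b", "b")), 0.8)
  # all-singleton clusters are each pure
  expect_equal(purity(1:5, c(1, 1, 2, 2, 2)), 1)
  expect_error(adjusted_rand(1:3, 1:4), "equal length")
})

test_that("external indices are invariant to label renaming", {
  set.seed(37)
  for (i in 1:20) {
    a <- sample(letters[1:4], 30, replace = TRUE)
    b <- sample(1:3, 30, replace = TRUE)
    a2 <- c(a = "w", b = "x", c = "y", d = "z")[a]
    b2 <- c("9", "7", "8")[b]
    expect_equal(adjusted_rand(a, b), adjusted_rand(a2, b2))
    expect_equal(fowlkes_mallows(a, b), fowlkes_mallows(a2, b2))
    expect_equal(purity(a, b), purity(a2, b2))
    expect_equal(fowlkes_mallows(a, a2), 1)  # pure relabeling
  }
})

test_that("indices match independent references on 100 random label pairs", {
  skip_if_not_installed("mclust")
  set.seed(41)
  for (i in 1:100) {
    n <- sample(10:60, 1)
    a <- sample(1:4, n, replace = TRUE)
    b <- sample(letters[1:3], n, replace = TRUE)
    expect_equal(adjusted_rand(a, b), mclust::adjustedRandIndex(a, b),
                 tolerance = 1e-10)
    o <- paircount_indices(a, b)
    expect_equal(adjusted_rand(a, b), o$ari, tolerance = 1e-10)
    expect_equal(fowlkes_mallows(a, b), o$fm, tolerance = 1e-10)
    expect_equal(purity(a, b), purity_oracle(a, b), tolerance = 1e-10)
  }
})

test_that("chance-level behavior of ARI and FM on independent partitions", {
  set.seed(43)
  n <- 200; reps <- 1000
  ari <- fm <- numeric(reps)
  base <- rep(1:3, length.out = n)
  for (r in seq_len(reps)) {
    a <- sample(base); b <- sample(base)
    ari[r] <- adjusted_rand(a, b)
    fm[r] <- fowlkes_mallows(a, b)
  }
  expect_lt(abs(mean(ari)), 3 * sd(ari) / sqrt(reps))
  # analytic chance value of FM: E[TP]/sqrt(pa*pb) = sqrt(pa*pb)/C(n,2)
  sizes <- tabulate(base)
  pa <- sum(choose(sizes, 2))
  chance_fm <- sqrt(pa * pa) / choose(n, 2)
  expect_lt(abs(mean(fm) - chance_fm), 3 * sd(fm) / sqrt(reps))
})

test_that("cross-tabulation counts joint labels in first-appearance order", {
  ct <- cross_tabulate(c(1, 1, 2), c("a", "b", "b"))
  expect_equal(unclass(ct), matrix(c(1L, 0L, 1L, 1L), 2,
                                   dimnames = list(c("1", "2"), c("a", "b"))),
               ignore_attr = TRUE)
  expect_equal(rownames(cross_tabulate(c("z", "a"), c("q", "p"))), c("z", "a"))
  a <- sample(1:3, 20, replace = TRUE)
  b <- sample(1:2, 20, replace = TRUE)
  ct2 <- cross_tabulate(a, b)
  expect_equal(unname(rowSums(ct2)), unname(as.integer(table(a)[rownames(ct2)])))
  expect_equal(unname(colSums(ct2)), unname(as.integer(table(b)[colnames(ct2)])))
  d <- cross_tabulate(c(1, 2, 3), c(1, 2, 3))
  expect_equal(unname(diag(d)), rep(1L, 3))
})

test_that("chi-square matches closed forms and rejects zero margins", {
  # exact independence: outer-product table
  t0 <- outer(c(2, 3), c(4, 6)) / 5
  expect_equal(chi_square(round(t0 * 5))$statistic, 0, tolerance = 1e-12)
  # 2x2 closed form n (ad - bc)^2 / (r1 r2 c1 c2)
  r <- chi_square(matrix(c(10, 0, 0, 10), 2))
  expect_equal(r$statistic, 20)
  expect_equal(r$df, 1)
  expect_error(chi_square(matrix(c(1, 0, 2, 0), 2)), "positive")
})

test_that("silhouette follows the distance-matrix formula with the singleton convention", {
  # two tight clusters: a = 0, b = 10 for every point
  m <- matrix(10, 4, 4); diag(m) <- 0
  m[1, 2] <- m[2, 1] <- 0; m[3, 4] <- m[4, 3] <- 0
  d <- distance_matrix(m, letters[1:4])
  expect_equal(silhouette_avg(d, c(1, 1, 2, 2)), 1)
  # equidistant points: any 2-way split scores 0 (a = b)
  eq <- matrix(3, 4, 4); diag(eq) <- 0
  expect_equal(silhouette_avg(distance_matrix(eq), c(1, 1, 2, 2)), 0)
  # singleton contributes 0
  expect_equal(silhouette_avg(d, c(1, 1, 2, 3)),
               mean(c(1, 1, 0, 0)))
  expect_error(silhouette_avg(d, rep(1, 4)), "at least 2")
})

test_that("silhouette agrees with the cluster package on random inputs", {
  skip_if_not_installed("cluster")
  set.seed(47)
  for (i in 1:20) {
    n <- sample(6:20, 1)
    d <- distance_matrix_from_random(n)
    lab <- sample(1:3, n, replace = TRUE)
    if (length(unique(lab)) < 2) next
    ours <- silhouette_avg(d, lab)
    ref <- mean(cluster::silhouette(lab, stats::as.dist(unclass(d)))[, "sil_width"])
    expect_equal(ours, ref, tolerance = 1e-10)
  }
})

test_that("Dunn index is separation over diameter with the singleton sentinel", {
  m <- matrix(0, 4, 4)
  m[1, 2] <- m[2, 1] <- 1   # cluster {1,2} diameter 1
  m[3, 4] <- m[4, 3] <- 2   # cluster {3,4} diameter 2
  m[1, 3] <- m[3, 1] <- m[1, 4] <- m[4, 1] <- 10
  m[2, 3] <- m[3, 2] <- m[2, 4] <- m[4, 2] <- 11
  d <- distance_matrix(m)
  expect_equal(dunn_index(d, c(1, 1, 2, 2)), 5)  # 10 / 2
  expect_equal(dunn_index(d, 1:4), Inf)          # all singletons
  # monotone in separation
  d2 <- distance_matrix(m + 100 * (m >= 10))
  expect_gt(dunn_index(d2, c(1, 1, 2, 2)), dunn_index(d, c(1, 1, 2, 2)))
  expect_error(dunn_index(d, rep(1, 4)), "at least 2")
})
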