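---
title: "Shape-based ensemble clustering of longitudinal biomarker trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Shape-based ensemble clustering of longitudinal biomarker trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trajensemble)
```

## The problem

Longitudinal biomarker measurements from observational cohorts are irregular:
subjects miss visits, drop out, and are measured at shifted times. In
infectious-disease cohorts with unknown infection times (the motivating case
is HIV monitoring with CD4 counts and viral load), even the time origin is
not comparable across subjects. Parametric trajectory models (mixed effects,
growth mixtures) require distributional and smoothness assumptions that such
data rarely meet, and latent subgroups violate them further.

`trajensemble` takes a distance-based route instead:

1. compare each pair of subjects' profiles with an **elastic,
   shape-respecting distance** that tolerates unequal lengths and phase
   shifts while preserving measurement order;
2. build a per-biomarker hierarchy with agglomerative linkage;
3. **ensemble** the per-biomarker hierarchies into a single consensus
   hierarchy via least-squares ultrametric fitting, and cut it to obtain
   joint progression groups.

## Elastic distances

Both distances operate on the ordered value sequences only; timestamps
provide ordering, not coordinates. This is deliberate: when infection times
are unknown, two subjects on the same disease course at different calendar
offsets should compare as similar. A profile is a polygonal curve
`P = (u_1, ..., u_p)`; a *coupling* (or warping path) pairs indices of `P`
and `Q` monotonically, starting at `(1, 1)` and ending at `(p, q)`, each
index advancing by at most one per step.

* **Dynamic time warping** (`dtw_distance`):
  `delta_DTW(P, Q) = min over paths W of sum_m d(w_m)`,
  the minimal *summed* local distance along a path. We use the classic
  symmetric unit-weight step pattern — steps `(i-1,j)`, `(i,j-1)`,
  `(i-1,j-1)`, each cell's cost counted once — with no window constraint and
  no path-length normalization, and `d` the absolute difference of values.
  DTW is not a metric (the triangle inequality can fail), which matters for
  the ensemble step below.
* **Discrete Fréchet** (`frechet_distance`):
  `delta_discF(P, Q) = min over couplings L of max over L of d(u_a, v_b)`,
  the minimax counterpart. It is a metric on node sequences and an upper
  bound for the continuous Fréchet distance. Because it depends on a single
  extreme pair, it uses far less of the alignment information than DTW's
  sum — the benchmark below shows the practical consequence.

Both are computed by `O(pq)` dynamic programming; ties among equal-cost
paths are broken deterministically in the backtrack (diagonal step first,
then an advance in the first curve, then the second). The compiled kernels
are validated in the test suite against exhaustive enumeration of all paths
for curves of length up to 6, and the law `delta_discF <= delta_DTW`
(a sum dominates a maximum along the same path) is asserted on random pairs.

`euclidean_distance` is provided purely as the non-elastic reference; it
requires equal lengths and is sensitive to misalignment.

## Hierarchies, ultrametrics, and the consensus

Per-marker distance matrices are clustered with complete linkage
(`stats::hclust` behind `complete_linkage()`). A dendrogram is equivalent to
an **ultrametric** — a distance obeying
`delta(i,k) <= max(delta(i,j), delta(j,k))` — via the cophenetic map (entry
`(i,j)` = height of the lowest merge joining `i` and `j`). This bijection is
what makes dendrogram-level ensembling well-posed: descriptor matrices can
be averaged in ultrametric space and mapped back to a unique hierarchy,
with no need to cut the base dendrograms first. `cluster membership
divergence` (smallest cluster size containing a pair) is available as an
alternative descriptor.

The consensus (`consensus_ultrametric`) minimizes

    L(U) = sum_b w_b sum_{i<j} (u_ij - d^b_ij)^2

over ultrametric matrices `U`, where `d^b` are the per-view descriptor
matrices. The ultrametric constraint is handled by sequential unconstrained
minimization (SUMT): minimize `L + r * Phi` with penalty
`Phi(U) = sum over violating triples of (u_ik - max(u_ij, u_jk))^2` and `r`
escalating tenfold per outer iteration (defaults: `r = 1`, growth 10, 10
outer iterations). Numerical choices, made once and kept:

* **Initialization** at the weighted mean of the descriptors. Whenever the
  mean is itself ultrametric, it is the unconstrained optimum and feasible,
  so the fit returns it immediately — this gives the exact fixed-point
  behavior for a single view or identical views, which the tests assert.
* **Inner minimizer**: limited-memory quasi-Newton (L-BFGS-B through
  `stats::optim`) with an analytic gradient computed in compiled code. A
  conjugate-gradient inner loop was profiled first; L-BFGS-B reached equal
  or better optima in roughly a sixth of the time on cohort-sized problems
  (n near 90, about 3 900 free entries), and is equally deterministic.
* **Finalization**: the converged matrix has tiny residual violations, so
  it is snapped to an exact ultrametric by single-linkage (subdominant
  ultrametric) closure, which is the identity on already-ultrametric
  matrices, then mapped back to a dendrogram. If the worst violation before
  finalization exceeds `ultrametric_tol` (default 0.1% of the largest
  entry) the fit errors and carries the best iterate.
* **Tie-breaks**: equal merge heights are resolved by `hclust`'s
  deterministic internal order; dendrograms and cuts are reproducible
  run-to-run. Reconstruction from an ultrametric resolves implied polytomies
  as consecutive binary merges at equal heights.
* **Scale harmonization is explicit**: views measured on different scales
  (CD4 counts vs log10 viral load) contribute to the least-squares fit in
  proportion to their squared distance scales, so the workflow rescales the
  VL distance matrix before clustering (rescaling never changes a single
  view's own dendrogram cuts). `suggest_rescale_factor()` proposes the
  ratio of median off-diagonal distances; the HIV-style analyses this
  mirrors used a factor of 300. The consensus never rescales silently; it
  warns when view maxima differ by more than tenfold.
* `k` is always an explicit parameter (3 for univariate marker cuts, 4 for
  the consensus in the cohort workflow); the package never auto-selects the
  number of clusters.

## What the synthetic generators emulate

**CBF benchmark** (`generate_cbf`). The canonical cylinder/bell/funnel
simulated time-series classes: 128 equispaced points, plateau start
`a ~ U{16..32}`, width `b - a ~ U{32..96}`, amplitude `6 + eta`,
`eta, eps(t) ~ N(0, noise_sd^2)` with `noise_sd = 1` as the standard
benchmark noise. The three classes differ only in shape (flat plateau,
rising ramp, falling ramp), which is exactly what an elastic distance
should detect. `sparsify(step = 4)` gives the 32-point sparse variant;
`apply_mcar` removes an exact count of value-matrix cells uniformly without
replacement (rounding ties upward), so per-profile missingness varies
naturally; draws violating a minimum-points-per-profile floor (default 1)
are redrawn wholesale. The benchmark harness (`run_cbf_benchmark`) holds
one base set fixed across the 500 missingness draws of each condition —
matching the design in which missingness, not the training set, is the
random quantity — and the validation analyses repeat the harness over 20
regenerated base sets to bracket base-set variability. Because every run
regenerates its training set rather than loading a fixed archival instance,
comparisons against reference values obtained from any single
instantiation are stochastic reproductions: grand means and orderings are
comparable, individual values are not. The validation suite therefore
scores grand means over the 20 base sets against reference values with a
band of two between-base-set standard deviations (the spread across base
sets is substantial, especially for full-length profiles), and
additionally requires the qualitative orderings — DTW above discrete
Fréchet at every condition, and degradation from 25% to 50% missingness —
to hold strictly.

**CD4/VL cohort** (`generate_cohort`). Scheduled visits at months
0/6/12/18/24 with ±1 month jitter, geometric dropout (default 0.1 per
visit, giving a mean of about 4.1 visits, median 5, and about 73% retention
at a 4-or-more-visits filter — typical of a 24-month cohort), group-linear
log10-VL and CD4 trends with subject-level intercepts and visit-level
noise, VL clamped at quantitation limits 400 and 750 000 copies
(clamp-and-flag, never dropped: the censored value is what the assay
reports), and a baseline CD4 >= 350 enrollment criterion enforced by
resampling the baseline draw. The four default archetypes encode the
progression subtypes a bivariate analysis should separate, with the two
small high-CD4 groups (sizes 19 and 6) nearly indistinguishable in CD4 and
separated only by VL — so the ensemble's defining ability (splitting a
univariate cluster using the other marker) is testable structurally.
Default noise values (CD4 subject/visit sd 60/50 cells, VL 0.3/0.3 log10)
reflect realistic assay and biological variability; the validation suite
uses documented low-noise settings (25/25 and 0.12/0.12) for parameter
recovery, and a fully deterministic setting (all sds, jitter and dropout
zero) where exact recovery is provable by construction.

What the generators do **not** emulate: informative (non-MCAR) missingness,
treatment effects or interventions, nonlinear within-group trajectories,
measurement-batch effects, and the heavy-tailed VL excursions of real
cohorts. Passing tests therefore demonstrate correctness of the machinery
and recoverability under the stated generative assumptions — not clinical
performance on real data.

## Validity indices

External indices (`adjusted_rand`, `fowlkes_mallows`, `purity`) score
simulated clusterings against truth; all are label-permutation invariant
and cross-checked against independent references. Purity of an
all-singleton clustering is 1 by definition — a known overstatement, which
is why the three indices are reported together. Internal indices
(`silhouette_avg` with the singleton-scores-zero convention, `dunn_index`
in its min-separation/max-diameter form with an `Inf` sentinel for
all-singleton partitions) describe unlabeled fits. `chi_square` is the
plain Pearson statistic without continuity correction.

## Problem sizes and runtime

The distance kernels and the SUMT objective/gradient run in compiled code.
The shipped analyses use: 500 MCAR draws per condition over 20 regenerated
CBF base sets (30 profiles of 128 or 32 points) for the benchmark; an
87-subject 4-group cohort for the ensemble validation. On one CPU core the
full benchmark sweep takes a few minutes and a cohort ensemble a few
seconds.

## Known limitations

* DTW's triangle-inequality failures mean base *distance matrices* are not
  metric; the ensemble sidesteps this by operating on cophenetic
  descriptors, but base dendrograms themselves inherit whatever
  chaining/inversion behavior the linkage has on non-metric inputs.
* The SUMT consensus solves a non-convex problem; the mean-initialized
  deterministic fit is reproducible but only locally optimal. Perturbed
  restarts (`n_restarts`) are available when robustness matters more than
  speed.
* Newick round trips store heights as branch lengths; exact merge heights
  are preserved in a comment block, and reconstruction is tolerance-based.
* With very short profiles (1-2 points) elastic distances degenerate toward
  absolute value differences; the visit filter exists precisely to keep
  shape information in the retained cohort.
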