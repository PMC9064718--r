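# trajensemble

Ensemble clustering of longitudinal biomarker trajectories with
shape-respecting distances.

## The problem

Cohort studies record biomarkers (CD4 count, viral load, ...) at irregular,
subject-specific visit times, with dropout and detection limits — and, for
infections with unknown onset, no comparable time origin. `trajensemble`
groups subjects by the *shape* of their trajectories rather than by
time-anchored values, and combines several biomarkers ("views") into one
joint grouping:

1. **Elastic distances.** For profiles `P = (u_1..u_p)`, `Q = (v_1..v_q)`
   compared along monotone index couplings:
   - dynamic time warping, `δ_DTW(P,Q) = min_W Σ_m d(w_m)` (minimal summed
     local distance along a warping path; classic unit-weight symmetric
     step pattern, no window, no normalization);
   - discrete Fréchet, `δ_dF(P,Q) = min_L ‖L‖` with `‖L‖` the largest
     node distance in the coupling (a metric, and an upper bound for the
     continuous Fréchet distance).

   Both tolerate unequal lengths and phase shifts while preserving
   measurement order; both run in `O(pq)` compiled dynamic programs.
2. **Per-marker hierarchies.** Complete-linkage agglomerative clustering of
   the pairwise distance matrix.
3. **Ultrametric consensus.** Each dendrogram is converted to its
   cophenetic descriptor matrix; the consensus ultrametric minimizes
   `L(U) = Σ_b w_b Σ_{i<j} (u_ij − d^b_ij)²` subject to the ultrametric
   inequality, solved by SUMT (escalating-penalty sequential unconstrained
   minimization) and mapped back to a unique consensus dendrogram.

Simulation harnesses are included: the cylinder–bell–funnel (CBF) benchmark
with exact-count MCAR missingness, and a synthetic bivariate CD4/viral-load
cohort with latent progression groups, scheduled-visit jitter, geometric
dropout and quantitation-limit censoring.

## Worked example

Cluster a sparse CBF training set under 25% missingness and score against
the true shape labels:

```r
library(trajensemble)

cbf     <- generate_cbf(cbf_config(n_per_class = 10, length = 128, seed = 2))
sparse  <- sparsify(cbf, 4)                              # 32 points/profile
thinned <- apply_mcar(sparse, mcar_config(0.25, seed = 7))  # exactly 240 cells removed

d    <- pairwise_matrix(thinned$profiles, "dtw")
labs <- cut_dendrogram(complete_linkage(d), 3)

adjusted_rand(labs, thinned$labels)    #> 0.8028846
fowlkes_mallows(labs, thinned$labels)  #> 0.8649364
purity(labs, thinned$labels)           #> 0.9333333
```

An adjusted Rand of 0.80 means the three shape classes are recovered nearly
perfectly despite a quarter of all measurements being deleted; purity 0.93
says each recovered cluster is dominated by one true shape. Values vary
substantially across generated base sets (that spread is quantified by the
benchmark harness, `run_cbf_benchmark`).

Bivariate ensemble on the synthetic cohort (41/21/19/6 subjects in four
progression groups; viral load censored at 400 and 750 000 copies and
log10-transformed; its distance matrix rescaled onto the CD4 scale):

```r
coh   <- generate_cohort(cohort_config(seed = 1))
cd4_d <- pairwise_matrix(coh$cd4$profiles, "dtw")
vl_d  <- run_univariate(coh$vl$profiles, metric = "dtw", k = 3,
                        censor = c(400, 750000), log10_transform = TRUE)$distance
fac   <- suggest_rescale_factor(cd4_d, vl_d)   #> 245.9

ens <- run_ensemble(list(
  ensemble_view(coh$cd4$profiles, metric = "dtw", k = 3),
  ensemble_view(coh$vl$profiles,  metric = "dtw", k = 3,
                censor = c(400, 750000), log10_transform = TRUE,
                rescale_factor = fac)), k = 4)

adjusted_rand(ens$labels, coh$labels[names(ens$labels)])  #> 0.7358786
cross_tabulate(coh$labels[names(ens$labels)], ens$labels)
#>                    1 2  3 4
#> low_cd4_high_vl   40 1  0 0
#> mid_cd4_rising_vl  0 2 18 1
#> high_cd4_low_vl    0 0 19 0
#> high_cd4_high_vl   0 6  0 0
ens$view_chi_square                    #> statistic 55.7 on 4 df
```

At the cohort's default (moderate) noise the consensus recovers the four
groups imperfectly (ARI 0.74) but — the point of ensembling — the small
"recently infected" group (`high_cd4_high_vl`, n = 6) is cleanly pulled out
of the high-CD4 cluster by its viral-load behavior (all 6 in consensus
group 2), something no single-marker clustering achieves. The chi-square of
the CD4-cut vs VL-cut cross-tab (55.7 on 4 df) shows the strong association
between the two markers' groupings. At the documented low-noise validation
settings recovery is exact (see the tests and the vignette).

A thin command-line interface wraps the same functions; see `?cli_main`.

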