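# mcsm — multi-view clustering of omics samples on Stiefel manifolds

Patients in modern cancer cohorts are profiled on several omics platforms
at once (gene expression, miRNA, DNA methylation), and the platforms need
not agree on the patient groups: subtypes can be consistent across views,
view-specific, or both. `mcsm` is for analysts who want a joint clustering
that reinforces shared structure across views *without* forcing the views
to agree — each view keeps its own labelling, and a final integration step
reconciles them.

## The method

Each view `m` contributes a patient similarity graph with unnormalized
Laplacian `L_m = D_m − W_m` (heat-kernel KNN affinity for real matrices,
raw adjacency for simulated networks). The per-view spectral relaxations
are coupled through the block matrix

    L = diag(L_1, …, L_M) − β · (off-diagonal identity blocks),

and the joint objective

    min trace(UᵀLU)   s.t.  U_mᵀU_m = I_K  for every view,

is minimised over the product of Stiefel manifolds by projected gradient
descent: negative gradient `Z = −2LU`, blockwise tangent projection
`η_m = Z_m − U_m·sym(U_mᵀZ_m)`, Armijo backtracking line search evaluated
after retraction, and an SVD (polar) retraction back to the manifold. The
per-view blocks `U_m` are clustered by k-means, labels are aligned across
views by Hungarian matching, and a k-nearest-neighbour vote resolves the
samples on which the views disagree. `K` can be fixed or chosen by the
Calinski–Harabasz score. A multi-view stochastic-block-model simulator and
Rand-index / NMI evaluation over replicate simulations are included, along
with a preprocessing chain for real matrices (missing-data filters, KNN
imputation, log transform, feature standardization).

The methods vignette (`vignettes/mcsm-methods.Rmd`) documents the model,
every tunable parameter, and the numerical design choices.

## Worked example

Simulate three 150-node networks whose planted clusters differ between
views — sizes (50,50,50), (30,90,30), (40,60,50) — fit the model, and
compare each view's labelling with that view's own ground truth:

```r
library(mcsm)

spec <- sbm_setting(1, pmatrix = 2, seed = 42)   # preset three-view design
sim  <- simulate_multiview(spec)
fit  <- mcsm_fit(sim$adjacencies, K = 3, seed = 42)
fit
#> mcsm_fit: M = 3 views, N = 150 samples, K = 3
#> opt_trace: 20 iterations, objective -9.74311 -> -14.3009, converged: FALSE
#> integrated_clustering: N = 150 samples, K = 3, cluster sizes: 40, 50, 60

sapply(1:3, function(m) rand_index(fit$per_view$labels[[m]], sim$truth[[m]]))
#> [1] 1.000 0.989 1.000
```

The objective trace decreases monotonically (the line search guarantees
it); `converged: FALSE` only means the 20-iteration budget ended before
the relative-change tolerance fired. Per-view Rand indices near 1 say each
view's own planted partition was recovered, even though the three views
disagree on 40+ node assignments. Averaging over replicate simulations:

```r
evaluate_runs(spec, n_runs = 10, seed = 1)
#> eval_report: 10 runs (0 failed)
#>   mean RI  0.9962  per view: 0.993 0.997 0.998
#>   mean NMI 0.9870  per view: 0.977 0.990 0.994
```

For real data, point the same pipeline at features-by-samples matrices:

```r
fit <- mcsm_from_omics(list(expr, mirna, methyl), K = NULL)  # K chosen by CH score
fit$final_labels
```

A thin command-line wrapper over the same functions is installed at
`system.file("cli/mcsm", package = "mcsm")`, with subcommands `simulate`,
`preprocess`, `cluster`, `evaluate` and `run`.

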