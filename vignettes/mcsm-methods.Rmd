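---
title: "Multi-view clustering on Stiefel manifolds: model, algorithm and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Multi-view clustering on Stiefel manifolds: model, algorithm and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mcsm)
```

## The problem

Cancer cohorts are routinely profiled on several omics platforms at once —
gene expression, miRNA expression, DNA methylation — over the same patients.
Joint clustering of such data must face the fact that the platforms need
*not* agree: a subtype visible in methylation may be invisible in
expression, and patient groups can genuinely differ between views. `mcsm`
clusters each view in a shared optimization so that consistent structure is
reinforced across views while view-specific structure survives, and only
afterwards reconciles the per-view labellings into one final clustering.

## Model

Each view $m = 1, \dots, M$ contributes a patient similarity graph over the
same $N$ samples with symmetric non-negative adjacency $W^{(m)}$, degree
matrix $D^{(m)}$ and unnormalized Laplacian
$L_m = D^{(m)} - W^{(m)}$. For real omics matrices the graph is a
heat-kernel affinity
$S_{ij} = \exp\!\left(-\lVert x_i - x_j \rVert^2 / 2t^2\right)$
restricted to $k$ nearest neighbours (union symmetrization); simulated
networks enter as binary adjacencies directly.

Spectral clustering of one view relaxes the cut problem to

$$\min_{U_m \in \mathbb{R}^{N \times K}} \operatorname{trace}(U_m^\top L_m U_m)
\quad \text{s.t.} \quad U_m^\top U_m = I_K,$$

whose solution is the span of the $K$ bottom eigenvectors of $L_m$. The
multi-view objective stacks the per-view blocks $U = (U_1; \dots; U_M)$ and
couples them:

$$\min_U \operatorname{trace}(U^\top L U), \qquad
L = \begin{pmatrix} L_1 & & \\ & \ddots & \\ & & L_M \end{pmatrix}
  - \beta \begin{pmatrix} 0 & I_N & \cdots \\ I_N & 0 & \\ \vdots & & \ddots \end{pmatrix},$$

subject to $U_m^\top U_m = I_K$ for every view separately — a product of
Stiefel manifolds, *not* a single orthogonality constraint on $U$. The
coupling term $-\beta \sum_{l \neq m} \operatorname{trace}(U_m^\top U_l)$
rewards agreement between the per-view embeddings; $\beta$ balances
within-view cut quality against cross-view consensus. When the view graphs
are built at comparable edge densities there is no reason to prefer one
view, and the default is $\beta = 1$. Note that the coupling makes the
joint matrix $L$ indefinite for $\beta > 0$; only the diagonal blocks are
positive semidefinite.

## Optimization

The objective is minimised by projected gradient descent on the manifold:

1. **Gradient.** $Z = -2LU$ (the Euclidean negative gradient of the trace
   form for symmetric $L$), split into per-view blocks $Z_m$.
2. **Tangent projection.** Each block is projected onto the tangent space
   of its Stiefel manifold at $U_m$,
   $\eta_m = Z_m - U_m \,\mathrm{sym}(U_m^\top Z_m)$ with
   $\mathrm{sym}(A) = (A + A^\top)/2$, so that $U_m^\top \eta_m$ is
   skew-symmetric.
3. **Backtracking line search.** A step $\alpha$ is accepted when the
   *retracted* candidate satisfies the sufficient-decrease condition
   $f(R(U + \alpha\eta)) \le f(U) - \alpha\, \hat c\, \langle \eta, Z\rangle$,
   where $\langle\cdot,\cdot\rangle$ is the trace inner product; otherwise
   $\alpha \leftarrow \tau \alpha$. The test is evaluated after retraction
   because $U + \alpha\eta$ leaves the manifold.
4. **SVD retraction.** Each block is mapped back to the manifold by the
   polar factor of its thin SVD, $R(Y) = W V^\top$ for $Y = W\Sigma V^\top$ —
   the orthonormal matrix closest to $Y$ in Frobenius norm.

Iterations stop after `max_iter` (default 20) or when the relative
objective change falls below `tol` (default $10^{-6}$). The accepted-step
sequence is monotone by construction, and the trace is exposed
(`opt_trace`) for convergence inspection.

### Line-search parameters

The conventional control parameter is kept at `c = 6` with `tau = 0.1` and
`alpha0 = 0.01`, but any sufficient-decrease coefficient $\ge 1$ demands at
least the full first-order decrease and is unattainable as
$\alpha \to 0$; the effective Armijo coefficient is therefore clamped to
`c_max = 1e-4`, the classical choice for gradient methods. Two further
points matter in practice:

* **Warm-started steps.** `alpha0` seeds only the first search. Each later
  search starts from the previously accepted step multiplied by
  `growth = 2` (and still shrinks by `tau` on rejection). A fixed initial
  step of 0.01 is too small for the problem scale of the larger study
  designs: the objective is then still descending visibly at iteration 20.
  Warm starting lets the step find the curvature scale and the trace
  flatten within the default iteration budget, and is standard practice in
  manifold optimization software.
* **Degenerate directions.** A direction with non-positive slope
  $\langle \eta, Z\rangle$ is refused (no movement, `accepted = FALSE` for
  a genuine ascent direction), and a slope at numerical zero — e.g. at a
  critical point — is accepted in place, so the loop terminates cleanly at
  stationary points.

### Initialization

The blocks are initialised from the $K$ bottom eigenvectors of the *pooled*
Laplacian $\sum_m L_m$, replicated across views (deterministic sign
convention; a seeded random orthonormal start is available). Two reasons:

* For a single view this is exactly the spectral optimum, so the $M = 1$
  case reduces to classical spectral clustering by construction.
* At the edge densities of the simulation designs below (mean within-block
  degree around 5) the bottom eigenvectors of a *single* sparse
  unnormalized Laplacian are frequently localized on isolated nodes or
  small components and carry no cluster information, which cannot be
  repaired within a 20-iteration budget. Pooling the views multiplies the
  effective degree by $M$ and yields a clean consensus subspace; the
  coupled descent then differentiates the per-view blocks toward their own
  Laplacians. This choice is measurably what makes the sparse simulation
  regimes recoverable (see `scripts/acceptance.R`).

## From embedding to labels

* **Per-view k-means.** Rows of each $U_m$ are normalized to unit length
  (direction, not magnitude, carries the cluster information in spectral
  embeddings; disable with `row_norm = FALSE`) and clustered by
  `stats::kmeans` with 50 restarts under a per-view seed, so results are
  deterministic given the seed.
* **Choosing K.** When `K` is not given, candidates `k_min..k_max`
  (default 2–10) are scored by the Calinski–Harabasz index on the
  row-concatenated embedding and the maximiser is taken, ties toward the
  smaller `K`.
* **Label alignment.** k-means labels are arbitrary per view, so views
  2..M are relabelled against view 1 by Hungarian assignment on the
  cross-view contingency table. This correspondence step is package
  plumbing: any cross-view vote needs it, whatever integration rule is
  used.
* **KNN integration.** Samples on which all aligned views agree keep that
  label unconditionally — integration only adjudicates disagreement. (A
  pure majority vote over neighbourhoods could overturn unanimous samples
  near cluster boundaries or, for large neighbourhoods, absorb minority
  clusters wholesale, which would violate the natural requirement that a
  unanimous labelling pass through unchanged for any neighbourhood size.)
  A disputed sample takes the majority over the $M(k+1)$ labels of itself
  and its $k$ nearest neighbours in the concatenated embedding
  $[U_1 | \dots | U_M]$; ties break to the sample's own majority view
  label, then to the smallest label index. `k_integrate` defaults to the
  graph neighbourhood size $\max(10, N/10)$.

## Preprocessing of real omics matrices

The chain, in order: (1) drop samples missing more than 20% of features in
*any* view (strict inequality — exactly 20% is kept); (2) drop features
missing in more than 20% of samples; (3) KNN imputation with $k = 20$,
using the root-mean-square difference over mutually observed features so
pairs with different overlap are comparable; (4) natural-log transform
with offset 1; (5) per-feature standardization to mean 0, variance 1
(population denominator $N$ by default, `unbiased = TRUE` for $N-1$).
Zero-variance features are dropped with a warning rather than producing
NaN. Batch correction and platform-specific normalizations are out of
scope; inputs are assumed to be comparable intensity matrices.

## The simulator

`simulate_multiview()` draws $M$ independent stochastic-block-model
networks over the same $N$ nodes. Each view has its own cluster-size
distribution; node-to-cluster assignment is contiguous
(`assign_clusters()`), so core nodes keep their cluster identity across
views and only boundary nodes switch — the controlled sense in which the
views disagree. Edges within and between clusters are Bernoulli with
probabilities from a $K \times K$ matrix; the four presets
(`sbm_pmatrix(1..4)`, scaled by $1/N$) share the within-cluster counts
(16, 18, 17) and raise between-cluster connectivity from zero, blurring
the boundaries. Two study designs are preset: three views of 150 nodes
with distributions (50,50,50), (30,90,30), (40,60,50), and six views of
1000 nodes. Per-view edge seeds derive from the base seed, so identical
specifications reproduce bit-identical networks.

What the simulator does *not* emulate: weighted or degree-heterogeneous
graphs, feature-level noise (simulation feeds adjacencies straight into
the Laplacian, bypassing the heat kernel), overlapping clusters, and
cross-view correlation of edge noise. Tests passing on these simulations
therefore certify the optimization and integration machinery under clean
block structure, not robustness to the full messiness of real cohorts.

## Evaluation protocol

`evaluate_runs()` repeats: fresh simulation, full fit, then per-view Rand
index and normalized mutual information *against that view's own planted
labels* — the views have different truths by design, so there is no single
reference partition — and averages over views and replicates (50
replicates for the small design, 10 for the large one, in the package's
tests and acceptance script). The Rand index is the standard
pair-agreement fraction; NMI uses natural-log entropies,
$2\,\mathrm{MI}/(H(U) + H(V))$, with $0\log 0 = 0$ and NMI $= 1$ when both
partitions are trivial. Views with identical cluster-size distributions
are statistically exchangeable under this generator, so their expected
scores coincide by symmetry.

## Numerical choices and degenerate inputs

* Neighbour and k-th-similarity ties break by node index; all pipelines
  are deterministic given their seed.
* `svd_retract()` refuses numerically rank-deficient inputs rather than
  silently returning an arbitrary completion.
* `knn_impute()` errors on samples with no observed features and on
  features unobservable in all neighbours; `k` is clamped to $N-1$ with a
  warning.
* Self-similarities never enter the graphs: `diag(W) = 0` before degrees
  are computed (self-loops cancel in $D - W$ regardless; zeroing keeps `W`
  interpretable).
* The literal tangent-direction formula with a $(U_m^\top U_m)$ term does
  not produce a tangent vector (on the manifold that factor is the
  identity); the implemented projection is the standard one stated above,
  which is the unique reading satisfying the tangency condition.

## Known limitations

* The convergence budget of 20 iterations flattens the objective to below
  1% relative change over the final five iterations on typical draws of
  both study designs, but occasional harder draws of the small design with
  the strongest between-cluster blur are still in a slow transit at
  iteration 20; `max_iter` is exposed and a larger budget removes this.
* Unnormalized Laplacians are sensitive to very sparse, fragmented graphs;
  the pooled initialization mitigates this for multi-view inputs, but a
  single extremely sparse view ($M = 1$, mean degree well below
  $\log N$) inherits the classical failure modes of unnormalized spectral
  clustering.
* `select_k` scores the concatenated embedding; views that disagree
  strongly on the *number* of clusters (not just their boundaries) are
  outside the model's assumptions.
* Survival-based validation of clusterings on real cohorts is outside the
  package's scope.
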