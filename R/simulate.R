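#' Connection-count matrices for the simulation study
#'
#' Four 3x3 symmetric matrices of connection counts; dividing by the node
#' count `N` yields the block connection probabilities. The diagonal
#' (within-cluster) entries are identical across the four, while the
#' off-diagonal (between-cluster) entries grow from zero, so the sequence
#' probes increasingly blurred cluster boundaries.
#'
#' @param which integer 1..4.
#' @return 3x3 numeric matrix of counts (multiply by `1/N` for
#'   probabilities).
#' @export
sbm_pmatrix <- function(which) {
  stopifnot(which %in% 1:4)
  off <- list(c(0, 0, 0), c(0.4, 0.6, 0.55), c(0.8, 1.2, 1.1), c(1.2, 1.8, 1.65))[[which]]
  P <- diag(c(16, 18, 17))
  P[1, 2] <- P[2, 1] <- off[1]
  P[1, 3] <- P[3, 1] <- off[2]
  P[2, 3] <- P[3, 2] <- off[3]
  P
}

#' Specification of a multi-view stochastic block model
#'
#' @param P K x K symmetric matrix of connection probabilities (entries in
#'   `[0, 1]`, i.e. already divided by `N`).
#' @param distributions list of `M` integer vectors of `K` cluster sizes,
#'   each summing to `N`.
#' @param N node count.
#' @param seed integer base seed; view `m` draws its edges with
#'   `seed + m`.
#' @return object of class `sbm_spec`.
#' @export
sbm_spec <- function(P, distributions, N, seed = 1L) {
  P <- as.matrix(P)
  if (!isSymmetric(unname(P))) stop("`P` must be symmetric")
  if (any(P < 0 | P > 1)) stop("`P` entries must be probabilities in [0, 1]")
  K <- nrow(P)
  stopifnot(is.list(distributions), length(distributions) >= 1)
  for (d in distributions) {
    if (length(d) != K) stop("each distribution must have K cluster sizes")
    if (sum(d) != N) stop("cluster sizes must sum to N")
  }
  structure(list(P = P, distributions = lapply(distributions, as.integer),
                 N = as.integer(N), M = length(distributions),
                 K = as.integer(K), seed = as.integer(seed)),
            class = "sbm_spec")
}

#' @export
print.sbm_spec <- function(x, ...) {
  cat(sprintf("sbm_spec: M = %d views, N = %d nodes, K = %d clusters, seed = %d\n",
              x$M, x$N, x$K, x$seed))
  invisible(x)
}

#' Preset simulation settings
#'
#' Setting 1: `M = 3` views of `N = 150` nodes with cluster distributions
#' (50,50,50), (30,90,30), (40,60,50). Setting 2: `M = 6` views of
#' `N = 1000` nodes with distributions (300,300,400), (300,300,400),
#' (400,300,300), (300,350,350), (300,400,300), (450,250,300). Connection
#' probabilities come from [sbm_pmatrix()] divided by `N`.
#'
#' @param setting 1 or 2.
#' @param pmatrix which connection matrix, 1..4.
#' @param seed integer base seed.
#' @return an [sbm_spec()].
#' @export
sbm_setting <- function(setting, pmatrix = 1, seed = 1L) {
  stopifnot(setting %in% 1:2)
  if (setting == 1) {
    N <- 150L
    dists <- list(c(50, 50, 50), c(30, 90, 30), c(40, 60, 50))
  } else {
    N <- 1000L
    dists <- list(c(300, 300, 400), c(300, 300, 400), c(400, 300, 300),
                  c(300, 350, 350), c(300, 400, 300), c(450, 250, 300))
  }
  sbm_spec(sbm_pmatrix(pmatrix) / N, dists, N, seed = seed)
}

#' Deterministic contiguous cluster assignment
#'
#' Nodes `1..n1` go to cluster 1, the next `n2` to cluster 2, and so on.
#' Using contiguous blocks in every view keeps cluster identity for core
#' nodes and makes only boundary nodes switch clusters across views with
#' different size distributions.
#'
#' @param distribution integer vector of cluster sizes.
#' @param N total node count; must equal `sum(distribution)`.
#' @return integer label vector of length `N` with values in
#'   `1..length(distribution)`.
#' @export
assign_clusters <- function(distribution, N = sum(distribution)) {
  if (sum(distribution) != N) stop("cluster sizes must sum to N")
  rep(seq_along(distribution), distribution)
}

#' Sample one stochastic-block-model network
#'
#' Each unordered node pair `(i, j)`, `i != j`, receives an edge with
#' probability `P[c_i, c_j]`, independently; the adjacency is symmetric,
#' binary, with zero diagonal.
#'
#' @param labels integer cluster labels.
#' @param P symmetric matrix of block connection probabilities.
#' @param seed integer seed.
#' @return sparse symmetric binary adjacency matrix (`Matrix::dgCMatrix`).
#' @export
sample_network <- function(labels, P, seed = 1L) {
  P <- as.matrix(P)
  if (any(P < 0 | P > 1)) stop("`P` entries must be in [0, 1]")
  n <- length(labels)
  pair <- which(upper.tri(matrix(0, n, n)))
  prob <- P[cbind(labels[((pair - 1) %% n) + 1], labels[((pair - 1) %/% n) + 1])]
  edges <- with_seed(seed, pair[stats::runif(length(pair)) < prob])
  i <- ((edges - 1) %% n) + 1
  j <- ((edges - 1) %/% n) + 1
  Matrix::sparseMatrix(i = c(i, j), j = c(j, i), x = rep(1, 2 * length(i)),
                       dims = c(n, n))
}

#' Simulate a multi-view network
#'
#' Draws `M` independent networks from an [sbm_spec()]: view `m` assigns
#' nodes by its own cluster-size distribution ([assign_clusters()]) and
#' samples edges with seed `spec$seed + m`, so the output is bit-identical
#' for identical spec and seed.
#'
#' @param spec an [sbm_spec()].
#' @return object of class `sim_multiview`: list with `adjacencies` (list of
#'   M sparse binary matrices), `truth` (list of M planted label vectors)
#'   and `spec`.
#' @export
simulate_multiview <- function(spec) {
  stopifnot(inherits(spec, "sbm_spec"))
  truth <- lapply(spec$distributions, assign_clusters, N = spec$N)
  adjacencies <- lapply(seq_len(spec$M), function(m) {
    sample_network(truth[[m]], spec$P, seed = spec$seed + m)
  })
  structure(list(adjacencies = adjacencies, truth = truth, spec = spec),
            class = "sim_multiview")
}

#' @export
print.sim_multiview <- function(x, ...) {
  cat(sprintf("sim_multiview: M = %d networks of %d nodes (seed %d)\n",
              x$spec$M, x$spec$N, x$spec$seed))
  invisible(x)
}
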