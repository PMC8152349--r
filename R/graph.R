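#' Heat-kernel similarity between samples
#'
#' Gaussian affinity `S_ij = exp(-||x_i - x_j||^2 / (2 t^2))` between sample
#' profiles (columns). With the default `t = NULL` the bandwidth is the
#' median off-diagonal pairwise Euclidean distance, a standard self-tuning
#' heuristic.
#'
#' @param X complete [omics_matrix()] (features x samples), typically the
#'   standardized output of [preprocess_views()].
#' @param t positive bandwidth, or `NULL` for the median-distance heuristic.
#' @return N x N symmetric similarity matrix with unit diagonal, entries in
#'   (0, 1]. The bandwidth used is attached as attribute `"t"`.
#' @export
heat_kernel <- function(X, t = NULL) {
  X <- as_omics(X)
  if (anyNA(X)) stop("heat_kernel() requires a complete matrix")
  d <- as.matrix(stats::dist(t(unclass(X))))
  if (is.null(t)) {
    t <- stats::median(d[upper.tri(d)])
    if (!is.finite(t) || t <= 0) stop("median-distance bandwidth is not positive")
  }
  if (!is.numeric(t) || length(t) != 1 || t <= 0) stop("`t` must be a positive scalar")
  S <- exp(-d^2 / (2 * t^2))
  diag(S) <- 1
  dimnames(S) <- list(colnames(X), colnames(X))
  attr(S, "t") <- t
  S
}

#' Default neighbourhood size for a sample graph
#'
#' `max(10, round(N / 10))`, capped at `N - 1`.
#'
#' @param n number of samples.
#' @return integer neighbourhood size.
#' @export
default_knn <- function(n) {
  as.integer(min(n - 1, max(10, round(n / 10))))
}

#' Sparsify a similarity matrix into a k-nearest-neighbour graph
#'
#' Keeps `W_ij = S_ij` when `j` is among the `k_neighbors` most similar
#' nodes of `i` or vice versa (union symmetrization; set `mode = "mutual"`
#' to require both directions). Ties at the k-th neighbour are broken by
#' node index. The diagonal of `W` is zero: a node's self-similarity never
#' contributes to the Laplacian `D - W`.
#'
#' @param S symmetric similarity matrix.
#' @param k_neighbors neighbourhood size, `1 <= k < N`; `NULL` for
#'   [default_knn()].
#' @param mode `"union"` (default) or `"mutual"` symmetrization.
#' @return a `view_graph`: list with sparse adjacency `W`, degree matrix `D`
#'   and Laplacian `L = D - W`.
#' @export
knn_graph <- function(S, k_neighbors = NULL, mode = c("union", "mutual")) {
  mode <- match.arg(mode)
  S <- as.matrix(S)
  n <- nrow(S)
  if (!isSymmetric(unname(S), tol = 1e-10)) stop("`S` must be symmetric")
  if (is.null(k_neighbors)) k_neighbors <- default_knn(n)
  if (k_neighbors < 1 || k_neighbors >= n) stop("`k_neighbors` must be in [1, N-1]")
  keep <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    ord <- order(-S[i, ], seq_len(n))   # ties broken by node index
    ord <- ord[ord != i]
    keep[i, ord[seq_len(k_neighbors)]] <- TRUE
  }
  keep <- if (mode == "union") keep | t(keep) else keep & t(keep)
  W <- ifelse(keep, S, 0)
  diag(W) <- 0
  view_graph(W)
}

#' Construct a view graph from an adjacency matrix
#'
#' Wraps a symmetric non-negative adjacency (weighted or binary, e.g. a
#' simulated network from [simulate_multiview()]) with its degree matrix and
#' unnormalized Laplacian `L = D - W`.
#'
#' @param W symmetric non-negative N x N matrix; the diagonal is zeroed.
#' @return object of class `view_graph`: list with sparse `W`, `D`, `L` and
#'   node count `n`.
#' @export
view_graph <- function(W) {
  W <- Matrix::Matrix(W, sparse = TRUE) * 1   # pattern/logical -> numeric
  W <- methods::as(methods::as(W, "generalMatrix"), "CsparseMatrix")
  if (nrow(W) != ncol(W)) stop("adjacency must be square")
  if (!Matrix::isSymmetric(W, tol = 1e-10)) stop("adjacency must be symmetric")
  if (any(W@x < 0)) stop("adjacency must be non-negative")
  Matrix::diag(W) <- 0
  W <- Matrix::drop0(W)
  deg <- Matrix::rowSums(W)
  D <- Matrix::Diagonal(x = deg)
  structure(list(W = W, D = D, L = D - W, n = nrow(W)), class = "view_graph")
}

#' @export
print.view_graph <- function(x, ...) {
  cat(sprintf("view_graph: %d nodes, %d edges, mean degree %.2f\n",
              x$n, Matrix::nnzero(x$W) / 2, mean(Matrix::rowSums(x$W != 0))))
  invisible(x)
}

#' Unnormalized graph Laplacian
#'
#' `L = D - W` for a symmetric non-negative adjacency `W`, so that
#' `x' L x = 1/2 * sum_ij W_ij (x_i - x_j)^2 >= 0` and `L 1 = 0`.
#'
#' @param W symmetric non-negative adjacency matrix.
#' @return sparse Laplacian matrix.
#' @export
graph_laplacian <- function(W) {
  view_graph(W)$L
}

#' Joint block Laplacian over M views
#'
#' Assembles the MN x MN matrix with the per-view Laplacians `L_m` on the
#' diagonal blocks and `-beta * I_N` on every off-diagonal block. The
#' coupling rewards agreement of the per-view embeddings; for `beta > 0` the
#' joint matrix is symmetric but in general indefinite.
#'
#' @param views list of `view_graph` objects sharing the same node count (a
#'   list of adjacency matrices is also accepted).
#' @param beta coupling weight (default 1).
#' @return object of class `joint_laplacian`: list with the sparse `L`, the
#'   per-view Laplacian list `blocks`, `beta`, view count `M` and node count
#'   `n`.
#' @export
joint_laplacian <- function(views, beta = 1) {
  if (!is.list(views) || length(views) < 1) stop("`views` must be a non-empty list")
  views <- lapply(views, function(v) if (inherits(v, "view_graph")) v else view_graph(v))
  n <- views[[1]]$n
  if (!all(vapply(views, function(v) v$n, 0L) == n)) {
    stop("all views must have the same number of nodes")
  }
  M <- length(views)
  blocks <- lapply(views, `[[`, "L")
  L <- Matrix::bdiag(blocks)
  if (M > 1 && beta != 0) {
    coupling <- Matrix::kronecker(matrix(1, M, M) - diag(M), Matrix::Diagonal(n))
    L <- L - beta * coupling
  }
  structure(list(L = methods::as(L, "CsparseMatrix"), blocks = blocks,
                 beta = beta, M = M, n = n),
            class = "joint_laplacian")
}

#' @export
print.joint_laplacian <- function(x, ...) {
  cat(sprintf("joint_laplacian: M = %d views, N = %d nodes, beta = %g\n",
              x$M, x$n, x$beta))
  invisible(x)
}

#' Write / read an adjacency matrix in MatrixMarket format
#'
#' @param g a `view_graph` or adjacency matrix.
#' @param path file path (conventionally `.mtx`).
#' @return `read_graph_mtx` returns a `view_graph`.
#' @export
write_graph_mtx <- function(g, path) {
  W <- if (inherits(g, "view_graph")) g$W else view_graph(g)$W
  Matrix::writeMM(W, path)
  invisible(path)
}

#' @rdname write_graph_mtx
#' @export
read_graph_mtx <- function(path) {
  view_graph(Matrix::readMM(path))
}
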